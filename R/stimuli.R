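## Stimulus and experimental-design generation: Gabor conjunction cues,
## search displays, De Bruijn counterbalanced task order, log-spaced
## duration jitter, and the behavioral inverse-efficiency score.

CUE_ORIENTATIONS <- c(15, 75, 135)         # degrees
CUE_SFS <- c(1, 2, 3)                      # cycles/degree
DISPLAY_ORIENTATIONS <- seq(15, 175, by = 20)
DISPLAY_SFS <- sort(c(CUE_SFS, 0.7, 1.3, 1.5, 3.8, 4.3))
SEARCH_RADIUS_DEG <- 8.37
SEARCH_DURATION_S <- 4

#' Gabor grating specification
#'
#' @param orientation grating orientation in degrees; normalized to
#'   `[0, 180)`.
#' @param spatial_frequency cycles per degree of visual angle, > 0.
#' @param diameter stimulus diameter in degrees of visual angle, > 0.
#' @param phase carrier phase in degrees.
#' @param contrast Michelson contrast in `(0, 1]`.
#' @return An object of class `gabor_spec`.
#' @export
gabor_spec <- function(orientation, spatial_frequency, diameter = 5,
                       phase = 0, contrast = 1) {
  if (!is.finite(spatial_frequency) || spatial_frequency <= 0)
    stop_invalid("spatial_frequency must be > 0")
  if (!is.finite(diameter) || diameter <= 0)
    stop_invalid("diameter must be > 0")
  if (contrast <= 0 || contrast > 1)
    stop_invalid("contrast must be in (0, 1]")
  structure(list(orientation = orientation %% 180,
                 spatial_frequency = spatial_frequency,
                 diameter = diameter, phase = phase %% 360,
                 contrast = contrast),
            class = "gabor_spec")
}

#' @export
print.gabor_spec <- function(x, ...) {
  cat(sprintf("Gabor: %.0f deg, %.1f cpd, %.1f deg diameter\n",
              x$orientation, x$spatial_frequency, x$diameter))
  invisible(x)
}

#' Render a Gabor grating as a luminance image
#'
#' Even-symmetric (cosine) sinusoidal carrier under a Gaussian envelope with
#' sigma = diameter/6, on a mid-gray background of 0.5 so mean luminance far
#' from the envelope equals the background.
#'
#' @param spec a [gabor_spec()].
#' @param pixels_per_degree rendering resolution; `diameter *
#'   pixels_per_degree` must be at least 16 pixels.
#' @return An object of class `stimulus_image`: list with `pixels` (square
#'   matrix of luminances in `[0, 1]`, rows = vertical) and
#'   `pixels_per_degree`.
#' @export
render_gabor <- function(spec, pixels_per_degree = 32) {
  stopifnot(inherits(spec, "gabor_spec"))
  n <- round(spec$diameter * pixels_per_degree)
  if (n < 16)
    stop_invalid("diameter x pixels_per_degree must be >= 16 pixels, got %d", n)
  ax <- (seq_len(n) - (n + 1) / 2) / pixels_per_degree  # degrees
  x <- matrix(ax, n, n, byrow = TRUE)
  y <- matrix(ax, n, n)
  th <- spec$orientation * pi / 180
  ## carrier modulates along the axis at `orientation`; stripes run orthogonal
  u <- x * cos(th) + y * sin(th)
  carrier <- cos(2 * pi * spec$spatial_frequency * u + spec$phase * pi / 180)
  sigma <- spec$diameter / 6
  envelope <- exp(-(x^2 + y^2) / (2 * sigma^2))
  px <- 0.5 + 0.5 * spec$contrast * carrier * envelope
  structure(list(pixels = px, pixels_per_degree = pixels_per_degree),
            class = "stimulus_image")
}

#' The nine cue Gabors
#'
#' Full factorial crossing of the three cue orientations (15, 75, 135
#' degrees) with the three cue spatial frequencies (1, 2, 3 cycles/degree),
#' all 5 degrees in diameter.  Cue id `k` is `(SF index - 1) * 3 +
#' orientation index` with orientation varying fastest.
#'
#' @return List of 9 [gabor_spec()] objects named `cue1..cue9`.
#' @export
cue_set <- function() {
  grid <- expand.grid(orientation = CUE_ORIENTATIONS, sf = CUE_SFS)
  out <- lapply(seq_len(nrow(grid)), function(i)
    gabor_spec(grid$orientation[i], grid$sf[i], diameter = 5))
  names(out) <- paste0("cue", seq_len(9))
  out
}

#' Generate a search display for a cued trial
#'
#' Six Gabors equally spaced on a circle of radius 8.37 degrees.  In the SF
#' task all items share one orientation drawn from the six orientations that
#' are never cued, and carry six distinct spatial frequencies of which
#' exactly one equals the cue's; the ORIENTATION task is the converse, with
#' the shared SF drawn from the five never-cued SFs.  Display positions are
#' offset from the vertical meridian so every item has a defined side.
#'
#' @param task `"SF"` or `"ORIENTATION"`; the `"EXACT"` image task is not
#'   implemented (excluded from analysis).
#' @param cue the trial's cue [gabor_spec()].
#' @param seed RNG seed.
#' @return An object of class `search_display`: items, angular positions
#'   (degrees), radius, target index and target side.
#' @export
search_display <- function(task, cue, seed = 1) {
  if (identical(task, "EXACT"))
    stop_invalid("EXACT-image search displays are not implemented (task excluded from analysis)")
  if (!task %in% c("SF", "ORIENTATION"))
    stop_invalid("task must be 'SF' or 'ORIENTATION'")
  set.seed(seed)
  if (task == "SF") {
    shared_ori <- sample(setdiff(DISPLAY_ORIENTATIONS, CUE_ORIENTATIONS), 1)
    sfs <- c(cue$spatial_frequency,
             sample(setdiff(DISPLAY_SFS, cue$spatial_frequency), 5))
    items <- lapply(sfs, function(f) gabor_spec(shared_ori, f, diameter = 5))
    target_feature <- cue$spatial_frequency
  } else {
    shared_sf <- sample(setdiff(DISPLAY_SFS, CUE_SFS), 1)
    oris <- c(cue$orientation,
              sample(setdiff(DISPLAY_ORIENTATIONS, cue$orientation), 5))
    items <- lapply(oris, function(o) gabor_spec(o, shared_sf, diameter = 5))
    target_feature <- cue$orientation
  }
  ## shuffle item positions; angles avoid the vertical meridian (x = 0)
  ord <- sample(6)
  items <- items[ord]
  target_index <- which(ord == 1)
  angles <- seq(0, 300, by = 60)
  x <- SEARCH_RADIUS_DEG * cos(angles * pi / 180)
  structure(list(items = items, angles = angles, radius = SEARCH_RADIUS_DEG,
                 task = task, target_index = target_index,
                 target_feature = target_feature,
                 target_side = if (x[target_index] > 0) "right" else "left"),
            class = "search_display")
}

#' De Bruijn counterbalanced instruction order
#'
#' A cyclic De Bruijn sequence of order `n` over the given symbols: every
#' length-`n` subsequence occurs exactly once cyclically, so each symbol
#' occurs `k^(n-1)` times.  For the three task instructions at order 3 this
#' yields the 27-trial block order.  The canonical (lexicographically least)
#' sequence is randomized by a random symbol relabeling and cyclic rotation.
#'
#' @param symbols vector of symbols (default the three task instructions).
#' @param order subsequence length counterbalanced, default 3.
#' @param seed RNG seed.
#' @return Vector of length `length(symbols)^order`.
#' @export
de_bruijn_order <- function(symbols = c("SF", "ORIENTATION", "EXACT"),
                            order = 3, seed = 1) {
  k <- length(symbols)
  stopifnot(k >= 2, order >= 1)
  idx <- de_bruijn_sequence(k, order)  # 0-based, canonical
  set.seed(seed)
  relabel <- sample(k)
  rot <- sample(length(idx), 1)
  idx <- c(idx[rot:length(idx)], idx[seq_len(rot - 1)])
  symbols[relabel[idx + 1L]]
}

## canonical De Bruijn sequence B(k, n) by the FKM (Lyndon word) algorithm
de_bruijn_sequence <- function(k, n) {
  a <- integer(k * n + 1)
  out <- integer(0)
  db <- function(t, p) {
    if (t > n) {
      if (n %% p == 0) out <<- c(out, a[2:(p + 1)])
    } else {
      a[t + 1] <<- a[t - p + 1]
      db(t + 1, p)
      j <- a[t - p + 1] + 1L
      while (j <= k - 1L) {
        a[t + 1] <<- j
        db(t + 1, t)
        j <- j + 1L
      }
    }
  }
  db(1L, 1L)
  out
}

#' Log-spaced jitter values
#'
#' `n` durations spaced uniformly in log time between `lo` and `hi`
#' inclusive (a geometric progression), so consecutive-value ratios are
#' constant and offsets are hard to anticipate.
#'
#' @param lo,hi endpoints in seconds, `0 < lo < hi`.
#' @param n number of values, default 9.
#' @return Strictly increasing vector of length `n` with `min = lo`,
#'   `max = hi`.
#' @export
jitter_values <- function(lo, hi, n = 9) {
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || lo >= hi)
    stop_invalid("need 0 < lo < hi, got lo = %g, hi = %g", lo, hi)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' One counterbalanced, jittered block of 27 trials
#'
#' Task instructions follow a randomized De Bruijn order (9 trials per
#' instruction); each of the 9 cue conjunctions appears once per
#' instruction, in shuffled order.  Cue durations are the 9 log-spaced
#' values between 1 and 2.5 s each repeated 3 times, and delay (fixation)
#' durations the 9 values between 2.5 and 6.5 s each repeated 3 times; the
#' two assignments are shuffled independently ("orthogonally") so cue and
#' delay durations are uncorrelated across trials.
#'
#' @param seed RNG seed.
#' @param t0 block start time in seconds.
#' @param iti inter-trial interval in seconds appended after each search
#'   display (the exact inter-trial timing is not critical and defaults
#'   to 1 s).
#' @return A `trial_schedule` data frame (one row per trial) with phase
#'   onsets and durations in seconds.
#' @export
block_schedule <- function(seed = 1, t0 = 0, iti = 1) {
  tasks <- de_bruijn_order(seed = derive_seed(seed, 1))
  set.seed(derive_seed(seed, 2))
  cue_ids <- integer(27)
  for (task in unique(tasks))
    cue_ids[tasks == task] <- sample(9)
  cue_dur <- sample(rep(jitter_values(1, 2.5), 3))
  set.seed(derive_seed(seed, 3))
  delay_dur <- sample(rep(jitter_values(2.5, 6.5), 3))

  cues <- cue_set()
  n <- 27
  instr_on <- cue_on <- delay_on <- search_on <- numeric(n)
  t <- t0
  for (i in seq_len(n)) {
    instr_on[i] <- t
    cue_on[i] <- t + 1
    delay_on[i] <- cue_on[i] + cue_dur[i]
    search_on[i] <- delay_on[i] + delay_dur[i]
    t <- search_on[i] + SEARCH_DURATION_S + iti
  }
  out <- data.frame(
    block = 1L, trial = seq_len(n), task = tasks, cue_id = cue_ids,
    orientation = vapply(cues[cue_ids], `[[`, numeric(1), "orientation"),
    sf = vapply(cues[cue_ids], `[[`, numeric(1), "spatial_frequency"),
    instruction_onset = instr_on, instruction_duration = 1,
    cue_onset = cue_on, cue_duration = cue_dur,
    delay_onset = delay_on, delay_duration = delay_dur,
    search_onset = search_on, search_duration = SEARCH_DURATION_S,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("trial_schedule", "data.frame"),
            iti = iti, seed = seed)
}

#' Multi-block session schedule
#'
#' Concatenates [block_schedule()]s with cumulative onsets.  The full
#' design is 8 blocks of 27 trials (72 trials per single-feature search
#' task).
#'
#' @param n_blocks number of blocks, >= 1.
#' @param seed RNG seed (per-block seeds are derived from it).
#' @param iti inter-trial interval in seconds.
#' @return A `trial_schedule` data frame.
#' @export
session_schedule <- function(n_blocks = 8, seed = 1, iti = 1) {
  stopifnot(n_blocks >= 1)
  t0 <- 0
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    blk <- block_schedule(seed = derive_seed(seed, 10 + b), t0 = t0, iti = iti)
    blk$block <- as.integer(b)
    blk$trial <- blk$trial + (b - 1L) * 27L
    t0 <- max(blk$search_onset) + SEARCH_DURATION_S + iti
    blocks[[b]] <- as.data.frame(blk)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out, class = c("trial_schedule", "data.frame"),
            iti = iti, seed = seed)
}

#' Long-format event table for a schedule
#'
#' One row per trial phase (instruction, cue, delay, search) with onset,
#' duration and condition label, following BIDS events.tsv conventions.
#' Cue and delay events of the two single-feature search tasks carry the
#' 18 analysis condition labels; EXACT-task and non-condition phases are
#' labeled by their phase/task for use as nuisance regressors.
#'
#' @param schedule a `trial_schedule`.
#' @return Data frame with columns `onset`, `duration`, `phase`,
#'   `trial_type`, `task`, `cue_id`, `block`, `trial`.
#' @export
schedule_events <- function(schedule) {
  s <- as.data.frame(schedule)
  cond_label <- ifelse(s$task %in% c("SF", "ORIENTATION"),
                       sprintf("%s_cue%d", s$task, s$cue_id), "EXACT")
  phase_row <- function(phase, onset, duration, label) {
    data.frame(onset = onset, duration = duration, phase = phase,
               trial_type = label, task = s$task, cue_id = s$cue_id,
               block = s$block, trial = s$trial, stringsAsFactors = FALSE)
  }
  out <- rbind(
    phase_row("instruction", s$instruction_onset, s$instruction_duration, "instruction"),
    phase_row("cue", s$cue_onset, s$cue_duration, cond_label),
    phase_row("delay", s$delay_onset, s$delay_duration, cond_label),
    phase_row("search", s$search_onset, s$search_duration, "search")
  )
  out <- out[order(out$onset), ]
  rownames(out) <- NULL
  out
}

#' Inverse efficiency score
#'
#' Accuracy-weighted reaction time, `mean RT / accuracy`, controlling for
#' speed-accuracy tradeoffs.
#'
#' @param mean_rt mean correct-trial reaction time in seconds.
#' @param accuracy proportion correct in `(0, 1]`.
#' @return IES in seconds.
#' @examples
#' inverse_efficiency(1.97, 0.814)  # ~2.42 s
#' @export
inverse_efficiency <- function(mean_rt, accuracy) {
  if (any(!is.finite(accuracy)) || any(accuracy <= 0) || any(accuracy > 1))
    stop_invalid("accuracy must be in (0, 1]; IES is undefined at accuracy 0")
  mean_rt / accuracy
}
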