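## Synthetic multi-subject BOLD forward model: voxel patterns realizing a
## target RDM are planted in ROIs and driven by the design's HRF-convolved
## condition regressors, plus Gaussian noise.  Everything downstream of the
## scanner is testable against this ground truth.

#' Realize voxel patterns with a target correlation structure
#'
#' Draws an `n_conditions x n_voxels` pattern matrix whose expected
#' between-condition Pearson correlation matrix (across voxels) is
#' `C = 1 - target`, via the factor decomposition `X = E sqrt(L) Z` of the
#' eigendecomposition `C = E L E'` with i.i.d. standard normal `Z`.  The
#' empirical RDM of the sampled patterns converges to the target as the
#' voxel count grows.
#'
#' @param target an `rdm`; `1 - target` must be positive semi-definite.
#' @param n_voxels number of voxels (>= 50).
#' @param seed RNG seed.
#' @param tol eigenvalues below `-tol` are rejected, negatives above it
#'   truncated to zero.
#' @return Matrix `n_conditions x n_voxels` with condition labels as row
#'   names.
#' @export
condition_patterns <- function(target, n_voxels, seed = 1, tol = 1e-10) {
  C <- 1 - as.matrix(target)
  if (n_voxels < 50) stop_invalid("n_voxels must be >= 50")
  eg <- eigen(C, symmetric = TRUE)
  if (any(eg$values < -tol))
    stop_invalid("1 - target is not positive semi-definite (eigenvalue %.3g)",
                 min(eg$values))
  ev <- pmax(eg$values, 0)
  A <- eg$vectors %*% diag(sqrt(ev), nrow = length(ev))
  set.seed(seed)
  Z <- matrix(rnorm(nrow(C) * n_voxels), nrow(C), n_voxels)
  X <- A %*% Z
  rownames(X) <- attr(target, "labels") %||% rownames(C)
  X
}

#' Planted representational effect
#'
#' Describes ground truth to embed in simulated data: voxel patterns in an
#' ROI realizing a target RDM, driven by the HRF response to the chosen
#' trial phase(s), at a given amplitude relative to the noise sd.
#'
#' @param roi logical 3D array (ROI mask).
#' @param target 18-condition target `rdm`.
#' @param amplitude signal scale (in units of the noise sd).
#' @param phase trial phase(s) the patterns respond to: subset of
#'   `c("cue", "delay")`.
#' @param name optional label used in reports.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(roi, target, amplitude = 0.5, phase = "cue",
                        name = "effect") {
  stopifnot(is.array(roi), length(dim(roi)) == 3)
  if (!all(phase %in% c("cue", "delay")))
    stop_invalid("effect phase must be 'cue' and/or 'delay'")
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  validate_rdm(as.matrix(target))
  structure(list(roi = array(as.logical(roi), dim(roi)), target = target,
                 amplitude = amplitude, phase = phase, name = name),
            class = "effect_spec")
}

#' Simulate one subject's 4D BOLD run
#'
#' The voxel time series is the sum over planted effects and conditions of
#' `amplitude x pattern(condition, voxel) x regressor(condition, t)` (the
#' condition's phase boxcars convolved with the HRF) plus white Gaussian
#' noise of sd `noise_sigma` (optionally AR(1)-filtered).  Voxels outside
#' all ROIs carry only noise.
#'
#' @param schedule a `trial_schedule` from [session_schedule()].
#' @param effects list of [effect_spec()]s (ROI dims must match `grid`).
#' @param noise_sigma noise standard deviation.
#' @param grid 3D grid dimensions in voxels.
#' @param voxel_size voxel size in mm.
#' @param TR repetition time in seconds.
#' @param seed RNG seed.
#' @param rest trailing rest in seconds appended after the last trial.
#' @param ar1 AR(1) coefficient for temporally correlated noise (0 = white).
#' @param mask brain mask (defaults to the full grid).
#' @param hrf hemodynamic response function.
#' @param subject_id identifier stored with the dataset.
#' @return Object of class `bold_dataset`: 4D `data`, `TR`, `mask`,
#'   `events`, `voxel_size`, `affine`, `ground_truth`.
#' @export
simulate_subject <- function(schedule, effects = list(), noise_sigma = 1,
                             grid = c(24, 24, 24), voxel_size = 3, TR = 2,
                             seed = 1, rest = 16, ar1 = 0, mask = NULL,
                             hrf = double_gamma_hrf, subject_id = "sub-01") {
  events <- schedule_events(schedule)
  n_scans <- as.integer(ceiling((max(events$onset + events$duration) + rest) / TR))
  V <- prod(grid)
  if (is.null(mask)) mask <- array(TRUE, grid)
  if (!all(dim(mask) == grid))
    stop_invalid("mask shape must equal the simulation grid")

  set.seed(derive_seed(seed, 1))
  dat <- matrix(rnorm(V * n_scans, sd = noise_sigma), V, n_scans)
  if (ar1 != 0 && noise_sigma > 0)
    dat <- t(apply(dat, 1, function(x)
      as.numeric(stats::filter(x, ar1, method = "recursive")))) * sqrt(1 - ar1^2)

  conds <- condition_set()
  truth <- list()
  for (e in seq_along(effects)) {
    ef <- effects[[e]]
    if (!identical(dim(ef$roi), dim(mask)))
      stop_invalid("effect '%s': ROI dimensions do not match the grid", ef$name)
    if (any(ef$roi & !mask))
      stop_invalid("effect '%s': ROI extends outside the brain mask", ef$name)
    roi_idx <- which(ef$roi)
    ## pattern seed depends on the effect's name, not its list position, so
    ## simulating effects separately or together yields identical signal
    patt <- condition_patterns(ef$target, length(roi_idx),
                               seed = derive_seed(seed, sum(utf8ToInt(ef$name))))
    for (ph in ef$phase) {
      R <- condition_regressors(events, ph, conds$label, TR, n_scans, hrf)
      dat[roi_idx, ] <- dat[roi_idx, ] +
        ef$amplitude * t(patt) %*% t(R)
    }
    truth[[ef$name]] <- list(roi = ef$roi, target = ef$target,
                             amplitude = ef$amplitude, phase = ef$phase)
  }
  structure(list(data = array(dat, c(grid, n_scans)), TR = TR, mask = mask,
                 events = events, voxel_size = voxel_size,
                 affine = default_affine(grid, voxel_size),
                 ground_truth = truth, seed = seed, subject_id = subject_id),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD dataset %s: %d x %d x %d voxels, %d scans (TR %gs), %d events\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$TR, nrow(x$events)))
  invisible(x)
}

#' Simulate a multi-subject cohort
#'
#' Independent schedules and noise per subject on identical ROI geometry (a
#' stand-in for a common registered space).  Between-subject variability in
#' effect size is modeled as a multiplicative amplitude factor
#' `max(0.1, 1 + amplitude_jitter * N(0,1))`; jitter 0 gives identical
#' expected effect sizes.
#'
#' @param n_subjects cohort size (the study cohort is 11).
#' @param effects list of [effect_spec()]s shared across subjects.
#' @param n_blocks blocks per subject session.
#' @param noise_sigma noise sd.
#' @param amplitude_jitter between-subject amplitude sd (fraction).
#' @param seed RNG seed.
#' @param ... passed to [simulate_subject()] (`grid`, `TR`, ...).
#' @return List of `bold_dataset`s with attributes `effects` and `seed`.
#' @export
simulate_cohort <- function(n_subjects = 11, effects = list(), n_blocks = 2,
                            noise_sigma = 1, amplitude_jitter = 0, seed = 1,
                            ...) {
  stopifnot(n_subjects >= 2)
  set.seed(derive_seed(seed, 99))
  fac <- if (amplitude_jitter > 0)
    pmax(0.1, 1 + amplitude_jitter * rnorm(n_subjects)) else rep(1, n_subjects)
  subs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    ef_s <- lapply(effects, function(ef) {
      ef$amplitude <- ef$amplitude * fac[s]
      ef
    })
    sched <- session_schedule(n_blocks, seed = derive_seed(seed, 100 + s))
    subs[[s]] <- simulate_subject(sched, ef_s, noise_sigma = noise_sigma,
                                  seed = derive_seed(seed, 300 + s),
                                  subject_id = sprintf("sub-%02d", s), ...)
  }
  structure(subs, effects = effects, seed = seed, class = "bold_cohort")
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("BOLD cohort: %d subjects, %d planted effect(s)\n",
              length(x), length(attr(x, "effects"))))
  invisible(x)
}
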