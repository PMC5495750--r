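## End-to-end runner: simulate -> GLM -> searchlight -> group inference,
## with ground-truth recovery diagnostics and a reproducibility manifest.

#' Default planted effects for a synthetic recovery study
#'
#' Two disjoint spherical ROIs near opposite corners of the grid: ROI A
#' carries dimension-weighted representational structure and ROI B the
#' HMAX-C1-derived stimulus structure, both driven by the chosen trial
#' phase.
#'
#' @param grid 3D grid dimensions.
#' @param hmax_rdm9 9 x 9 stimulus RDM (computed from the rendered cues
#'   when not supplied).
#' @param amplitude signal amplitude relative to noise sd.
#' @param phase trial phase(s) driving the effects.
#' @param roi_radius ROI sphere radius in voxels.
#' @return List of two [effect_spec()]s named `dimension` and `hmax`.
#' @export
default_effects <- function(grid = c(24, 24, 24), hmax_rdm9 = NULL,
                            amplitude = 0.5, phase = "cue",
                            roi_radius = 6) {
  if (is.null(hmax_rdm9))
    hmax_rdm9 <- hmax_c1_rdm(pixels_per_degree = 16)
  lo <- round(0.27 * (grid - 1))
  hi <- round(0.73 * (grid - 1))
  list(
    dimension = effect_spec(ball_mask(grid, lo, roi_radius),
                            dimension_weighted_rdm(), amplitude, phase,
                            name = "dimension"),
    hmax = effect_spec(ball_mask(grid, hi, roi_radius),
                       expand_stimulus_rdm(hmax_rdm9), amplitude, phase,
                       name = "hmax")
  )
}

#' Pipeline configuration
#'
#' Desk-scale defaults for the synthetic end-to-end run: a 24^3 voxel grid
#' (3 mm), 6 subjects with 2-block sessions, planted effects at amplitude
#' 0.5 (noise sd 1), unsmoothed data analyzed with a 6 mm searchlight, 50
#' permutations and 1000 bootstrap samples.  Every argument can be
#' overridden.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_subjects,n_blocks cohort size and blocks per session.
#' @param grid,voxel_size grid geometry.
#' @param amplitude,noise_sigma,amplitude_jitter effect and noise scales.
#' @param roi_radius planted ROI radius in voxels.
#' @param period analyzed trial period, `"cue"` or `"delay"`.
#' @param effect_phase phase(s) the planted patterns respond to.
#' @param fwhm_mm spatial smoothing FWHM in mm (0 = none).
#' @param radius_mm searchlight radius in mm.
#' @param K,B,p_voxel,alpha,connectivity,null_type inference settings.
#' @param models which model RDMs to fit.
#' @param pixels_per_degree rendering resolution for the HMAX stage.
#' @return Named list of class `templight_config`.
#' @export
templight_config <- function(seed = 1, n_subjects = 6, n_blocks = 2,
                             grid = c(24, 24, 24), voxel_size = 3,
                             amplitude = 0.5, noise_sigma = 1,
                             amplitude_jitter = 0, roi_radius = 6,
                             period = "cue", effect_phase = period,
                             fwhm_mm = 0, radius_mm = 6, K = 50, B = 1000,
                             p_voxel = 0.01, alpha = 0.01,
                             connectivity = 26, null_type = "max",
                             models = c("dimension", "hmax"),
                             pixels_per_degree = 16) {
  cfg <- as.list(environment())
  class(cfg) <- "templight_config"
  cfg
}

#' Run the full synthetic RSA pipeline
#'
#' Simulates a cohort with the configured planted effects, fits the
#' period GLM per subject (with optional smoothing and voxelwise
#' z-scoring), and runs group searchlight RSA with bootstrapped cluster
#' inference for each requested model RDM.  When ground truth is present,
#' the Dice overlap between each model's significant clusters and its
#' planted ROI is reported.
#'
#' @param config a [templight_config()].
#' @param hmax_rdm9 optional precomputed 9 x 9 HMAX C1 RDM (avoids
#'   re-rendering the cue images across repeated runs).
#' @return Object of class `templight_run`: per-model `rsa_group` fits,
#'   Dice diagnostics, ground truth, config and manifest.
#' @export
templight_run <- function(config = templight_config(), hmax_rdm9 = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(hmax_rdm9) && "hmax" %in% config$models)
    hmax_rdm9 <- hmax_c1_rdm(pixels_per_degree = config$pixels_per_degree)
  effects <- default_effects(config$grid, hmax_rdm9 = hmax_rdm9,
                             amplitude = config$amplitude,
                             phase = config$effect_phase,
                             roi_radius = config$roi_radius)
  effects <- effects[intersect(names(effects), config$models)]
  cohort <- simulate_cohort(config$n_subjects, effects,
                            n_blocks = config$n_blocks,
                            noise_sigma = config$noise_sigma,
                            amplitude_jitter = config$amplitude_jitter,
                            seed = derive_seed(config$seed, 1),
                            grid = config$grid,
                            voxel_size = config$voxel_size)
  betas <- lapply(cohort, function(d) {
    if (config$fwhm_mm > 0) d <- smooth_dataset(d, config$fwhm_mm)
    des <- build_design(d$events, config$period, d$TR, dim(d$data)[4])
    zscore_conditions(fit_glm(d, des))
  })
  models <- list()
  if ("dimension" %in% config$models)
    models$dimension <- dimension_weighted_rdm()
  if ("hmax" %in% config$models)
    models$hmax <- expand_stimulus_rdm(hmax_rdm9)

  fits <- list(); dice_tab <- list()
  for (mn in names(models)) {
    fit <- rsa_group(betas, models[[mn]], radius_mm = config$radius_mm,
                     K = config$K, B = config$B, p_voxel = config$p_voxel,
                     alpha = config$alpha,
                     connectivity = config$connectivity,
                     null_type = config$null_type,
                     seed = derive_seed(config$seed, 2), model_name = mn)
    fits[[mn]] <- fit
    if (mn %in% names(effects)) {
      roi <- effects[[mn]]$roi
      tab <- fit$clusters
      best <- 0
      if (any(tab$significant)) {
        labs <- attr(tab, "labels")
        best <- max(vapply(tab$label[tab$significant], function(l)
          dice(labs == l, roi), numeric(1)))
      }
      dice_tab[[mn]] <- data.frame(model = mn,
                                   n_significant = sum(tab$significant),
                                   best_dice = best)
    }
  }
  manifest <- list(
    seed = config$seed,
    n_scans = dim(cohort[[1]]$data)[4],
    n_mask_voxels = sum(cohort[[1]]$mask),
    elapsed_s = proc.time()[["elapsed"]] - t0,
    version = as.character(utils::packageVersion("templight"))
  )
  structure(list(fits = fits, dice = do.call(rbind, dice_tab),
                 effects = effects, config = config, manifest = manifest),
            class = "templight_run")
}

#' @export
print.templight_run <- function(x, ...) {
  cat(sprintf("templight pipeline run (seed %d): %d subjects, grid %s, period %s\n",
              x$config$seed, x$config$n_subjects,
              paste(x$config$grid, collapse = "x"), x$config$period))
  for (mn in names(x$fits)) {
    tab <- x$fits[[mn]]$clusters
    cat(sprintf("  %s model: %d cluster(s), %d significant\n",
                mn, nrow(tab), sum(tab$significant)))
  }
  if (!is.null(x$dice)) {
    cat("  ground-truth recovery (Dice of best significant cluster vs planted ROI):\n")
    print.data.frame(x$dice, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Validate a dataset against the pipeline's input contract
#'
#' Checks grid/mask consistency, repetition time, event-table schema,
#' onset bounds, and completeness of the 18 analysis condition labels in
#' both the cue and the delay period.
#'
#' @param data a `bold_dataset` (or a directory written by
#'   [write_bold_dataset()]).
#' @return Character vector of problems (length 0 when the dataset is
#'   valid).
#' @export
validate_inputs <- function(data) {
  if (is.character(data)) data <- read_bold_dataset(data)
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))
  d <- dim(data$data)
  if (length(d) != 4) note("data must be 4D, got %d dims", length(d))
  if (!all(dim(data$mask) == d[1:3])) note("mask shape does not match data grid")
  if (!is.finite(data$TR) || data$TR <= 0) note("invalid TR: %s", data$TR)
  ev <- data$events
  req <- c("onset", "duration", "phase", "trial_type")
  miss <- setdiff(req, names(ev))
  if (length(miss)) {
    note("events table missing column(s): %s", paste(miss, collapse = ", "))
    return(problems)
  }
  if (any(ev$onset + ev$duration > d[4] * data$TR))
    note("event(s) extend beyond the scan duration")
  if (!all(ev$phase %in% c("instruction", "cue", "delay", "search")))
    note("unknown phase value(s): %s",
         paste(setdiff(unique(ev$phase), c("instruction", "cue", "delay", "search")),
               collapse = ", "))
  labels <- condition_set()$label
  for (ph in c("cue", "delay")) {
    miss <- setdiff(labels, ev$trial_type[ev$phase == ph])
    if (length(miss))
      note("missing %s-period events for condition(s): %s", ph,
           paste(miss, collapse = ", "))
  }
  problems
}
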