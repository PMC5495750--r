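## Condition-wise GLM estimation: event-related design matrices with exact
## per-trial onsets/offsets, mass-univariate OLS, optional Gaussian
## smoothing, and voxelwise z-scoring of the condition images.

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing of a 3D volume (or each volume of a 4D
#' array) with the kernel full width at half maximum given in mm and
#' converted to voxels via the voxel size (`sigma = FWHM / 2.3548`).
#' `fwhm_mm = 0` returns the input unchanged.  The kernel is normalized so
#' mass is conserved away from the array edges.
#'
#' @param volume 3D or 4D numeric array.
#' @param fwhm_mm kernel FWHM in mm (>= 0).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @return Smoothed array of the same shape.
#' @export
smooth_volume <- function(volume, fwhm_mm, voxel_size_mm = 3) {
  if (fwhm_mm < 0) stop_invalid("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(volume)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(volume)
  out <- volume
  for (axis in 1:3) {
    K <- gauss_band_matrix(d[axis], sigma)
    perm <- c(axis, setdiff(seq_along(d), axis))
    m <- matrix(aperm(out, perm), d[axis])
    m <- K %*% m
    out <- aperm(array(m, d[perm]), order(perm))
  }
  out
}

gauss_band_matrix <- function(n, sigma) {
  h <- min(n - 1, ceiling(4 * sigma))
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (o in -h:h) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + k[o + h + 1]
  }
  K
}

#' Smooth a BOLD dataset
#'
#' @param data a `bold_dataset`.
#' @param fwhm_mm kernel FWHM in mm.
#' @return The dataset with smoothed 4D data.
#' @export
smooth_dataset <- function(data, fwhm_mm) {
  data$data <- smooth_volume(data$data, fwhm_mm, data$voxel_size)
  data
}

#' Build an event-related design matrix for one trial period
#'
#' One HRF-convolved regressor per analysis condition for the requested
#' period (`cue` or `delay`), built from the exact per-trial onsets and
#' durations.  The other period's condition events are absorbed as
#' nuisance: either one regressor per condition (`other_period =
#' "conditions"`, the default, so condition-specific signal from the other
#' period cannot leak into the period of interest) or a single shared
#' regressor (`"shared"`).  Search and instruction periods and any
#' EXACT-task events always enter as shared nuisance regressors, and a
#' polynomial drift basis (including the intercept) is appended.
#'
#' @param events long-format event table from [schedule_events()].
#' @param period `"cue"` or `"delay"`.
#' @param TR repetition time in seconds.
#' @param n_scans number of scans.
#' @param hrf hemodynamic response function.
#' @param drift_order polynomial drift order (default 2).
#' @param other_period `"conditions"` or `"shared"` (see above).
#' @param conditions the [condition_set()].
#' @param dt regressor oversampling step in seconds.
#' @return Object of class `design_matrix`: `X` (`n_scans x p`),
#'   `condition_idx` (columns of the 18 period-of-interest regressors),
#'   `labels`, `period`, `TR`.
#' @export
build_design <- function(events, period = c("cue", "delay"), TR, n_scans,
                         hrf = double_gamma_hrf, drift_order = 2,
                         other_period = c("conditions", "shared"),
                         conditions = condition_set(), dt = 0.1) {
  period <- match.arg(period)
  other_period <- match.arg(other_period)
  other <- setdiff(c("cue", "delay"), period)
  trials <- unique(events$trial)
  have <- unique(events$trial[events$phase == period])
  if (!all(trials %in% have))
    stop_invalid("events are missing '%s'-period rows for %d trial(s)",
                 period, length(setdiff(trials, have)))

  labels <- conditions$label
  Xc <- condition_regressors(events, period, labels, TR, n_scans, hrf, dt)

  nuis <- list()
  if (other_period == "conditions") {
    Xo <- condition_regressors(events, other, labels, TR, n_scans, hrf, dt)
    colnames(Xo) <- paste0("nuis_", other, "_", labels)
    nuis$other <- Xo
  } else {
    ev <- events[events$phase == other & events$trial_type != "EXACT", , drop = FALSE]
    nuis$other <- matrix(make_regressor(ev$onset, ev$duration, TR, n_scans, hrf, dt),
                         ncol = 1, dimnames = list(NULL, paste0("nuis_", other)))
  }
  for (ph in c(period, other)) {
    ev <- events[events$phase == ph & events$trial_type == "EXACT", , drop = FALSE]
    if (nrow(ev))
      nuis[[paste0("exact_", ph)]] <-
        matrix(make_regressor(ev$onset, ev$duration, TR, n_scans, hrf, dt),
               ncol = 1, dimnames = list(NULL, paste0("nuis_exact_", ph)))
  }
  for (ph in c("search", "instruction")) {
    ev <- events[events$phase == ph, , drop = FALSE]
    if (nrow(ev))
      nuis[[ph]] <- matrix(make_regressor(ev$onset, ev$duration, TR, n_scans, hrf, dt),
                           ncol = 1, dimnames = list(NULL, paste0("nuis_", ph)))
  }
  drift <- cbind(intercept = 1,
                 if (drift_order > 0) stats::poly(seq_len(n_scans), drift_order))
  if (drift_order > 0)
    colnames(drift)[-1] <- paste0("drift", seq_len(drift_order))

  X <- do.call(cbind, c(list(Xc), nuis, list(drift)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_invalid("degenerate design: collinear column(s) %s",
                 paste(bad, collapse = ", "))
  }
  structure(list(X = X, condition_idx = seq_along(labels), labels = labels,
                 period = period, TR = TR, n_scans = n_scans),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design matrix (%s period): %d scans x %d regressors (%d conditions)\n",
              x$period, nrow(x$X), ncol(x$X), length(x$condition_idx)))
  invisible(x)
}

#' Fit the condition GLM to a 4D dataset
#'
#' Mass-univariate ordinary least squares of every in-mask voxel time
#' series on the design, returning the 18 condition beta images for the
#' design's period plus residual variance for diagnostics.
#'
#' @param data a `bold_dataset`.
#' @param design a [build_design()] design matrix.
#' @return Object of class `beta_maps`: `betas` (`18 x n_mask_voxels`),
#'   `labels`, `mask`, `dim`, `period`, `sigma2`, geometry fields.
#' @export
fit_glm <- function(data, design) {
  X <- design$X
  d <- dim(data$data)
  if (d[4] != nrow(X))
    stop_invalid("scan count mismatch: data has %d scans, design %d", d[4], nrow(X))
  mask_idx <- which(data$mask)
  Y <- t(matrix(data$data, prod(d[1:3]), d[4])[mask_idx, , drop = FALSE])
  qrX <- qr(X)
  coefs <- qr.coef(qrX, Y)
  res <- Y - X %*% coefs
  sigma2 <- colSums(res^2) / (nrow(X) - ncol(X))
  structure(list(betas = coefs[design$condition_idx, , drop = FALSE],
                 labels = design$labels, mask = data$mask, dim = d[1:3],
                 period = design$period, sigma2 = sigma2,
                 voxel_size = data$voxel_size, affine = data$affine,
                 TR = data$TR, subject_id = data$subject_id,
                 zscored = FALSE),
            class = "beta_maps")
}

#' @export
print.beta_maps <- function(x, ...) {
  cat(sprintf("beta maps (%s period%s): %d conditions x %d voxels [%s]\n",
              x$period, if (isTRUE(x$zscored)) ", z-scored" else "",
              nrow(x$betas), ncol(x$betas), x$subject_id %||% "?"))
  invisible(x)
}

#' Voxelwise z-scoring across condition images
#'
#' At every in-mask voxel, centers and scales the vector of condition betas
#' to mean 0 and sd 1 (across the 18 conditions), the normalization applied
#' before group-level RSA.  Voxels with zero variance across conditions are
#' set to 0 and flagged.
#'
#' @param betas a `beta_maps`.
#' @return The z-scored `beta_maps`; flagged voxel indices in attribute
#'   `"flagged"`.
#' @export
zscore_conditions <- function(betas) {
  b <- betas$betas
  if (nrow(b) < 2) stop_invalid("need at least 2 condition images to z-score")
  mu <- colMeans(b)
  b <- sweep(b, 2, mu)
  s <- sqrt(colSums(b^2) / (nrow(b) - 1))
  zero <- s == 0
  s[zero] <- 1
  b <- sweep(b, 2, s, "/")
  b[, zero] <- 0
  betas$betas <- b
  betas$zscored <- TRUE
  attr(betas, "flagged") <- which(zero)
  betas
}

#' Extract one condition's beta image as a 3D array
#'
#' @param betas a `beta_maps`.
#' @param condition condition label or index.
#' @return 3D array (NA outside the mask).
#' @export
beta_volume <- function(betas, condition) {
  if (is.character(condition)) condition <- match(condition, betas$labels)
  v <- array(NA_real_, betas$dim)
  v[which(betas$mask)] <- betas$betas[condition, ]
  v
}
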