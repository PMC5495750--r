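## Canonical double-gamma hemodynamic response function and event
## regressor construction shared by the simulator (forward model) and the
## GLM (inverse model).

#' Double-gamma hemodynamic response function
#'
#' Canonical BOLD impulse response: a gamma-shaped peak minus a scaled
#' gamma-shaped undershoot, normalized to unit peak.  With the defaults the
#' response peaks near 6 s, undershoots around 16 s and has returned to
#' baseline by ~30 s.
#'
#' @param t time(s) in seconds since event onset (>= 0).
#' @param peak_delay time to peak in seconds.
#' @param undershoot_delay time to undershoot minimum in seconds; must
#'   exceed `peak_delay`.
#' @param peak_dispersion,undershoot_dispersion width parameters in seconds.
#' @param ratio peak:undershoot amplitude ratio.
#' @return HRF amplitude(s), unit peak.
#' @export
double_gamma_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_dispersion = 1, undershoot_dispersion = 1,
                             ratio = 6) {
  if (peak_delay <= 0 || undershoot_delay <= 0 || peak_delay >= undershoot_delay)
    stop_invalid("need 0 < peak_delay < undershoot_delay")
  g <- function(t, d, b) {
    a <- d / b
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- exp(a * log(t[pos] / d) - (t[pos] - d) / b)
    out
  }
  h <- function(t) g(t, peak_delay, peak_dispersion) -
    g(t, undershoot_delay, undershoot_dispersion) / ratio
  peak <- max(h(seq(max(0.1, peak_delay - 2), peak_delay + 2, by = 0.001)))
  out <- h(pmax(t, 0)) / peak
  out[t < 0] <- 0
  out
}

## boxcar(onsets, durations) convolved with the HRF, sampled at scan times.
## dt is the oversampling grid; onsets/durations are rounded to it.
make_regressor <- function(onsets, durations, TR, n_scans,
                           hrf = double_gamma_hrf, dt = 0.1,
                           hrf_length = 32) {
  total <- n_scans * TR
  L <- ceiling(total / dt) + 1L
  box <- numeric(L)
  if (length(durations) == 1) durations <- rep(durations, length(onsets))
  for (e in seq_along(onsets)) {
    i0 <- round(onsets[e] / dt) + 1L
    len <- max(1L, round(durations[e] / dt))
    i1 <- min(L, i0 + len - 1L)
    if (i0 <= L) box[i0:i1] <- box[i0:i1] + 1
  }
  hk <- hrf(seq(0, hrf_length, by = dt)) * dt
  ## linear convolution via zero-padded FFT at a 2-3-5-smooth length
  N <- stats::nextn(L + length(hk) - 1L, c(2, 3, 5))
  full <- Re(stats::fft(stats::fft(c(box, numeric(N - L))) *
                          stats::fft(c(hk, numeric(N - length(hk)))),
                        inverse = TRUE))[seq_len(L)] / N
  full[round((seq_len(n_scans) - 1) * TR / dt) + 1L]
}

## n_scans x length(labels) matrix of per-condition regressors for a phase
condition_regressors <- function(events, phase, labels, TR, n_scans,
                                 hrf = double_gamma_hrf, dt = 0.1) {
  ev <- events[events$phase == phase, , drop = FALSE]
  out <- matrix(0, n_scans, length(labels),
                dimnames = list(NULL, labels))
  for (j in seq_along(labels)) {
    e <- ev[ev$trial_type == labels[j], , drop = FALSE]
    if (nrow(e))
      out[, j] <- make_regressor(e$onset, e$duration, TR, n_scans, hrf, dt)
  }
  out
}
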