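#' Representational dissimilarity matrices
#'
#' An `rdm` is a square symmetric matrix of representational distances (RD)
#' between labeled conditions, with zero diagonal and entries on the 0-2
#' correlation-distance scale (0 = perfectly correlated, 1 = uncorrelated,
#' 2 = perfectly anti-correlated).
#'
#' @param mat square numeric matrix.
#' @param labels character vector of condition labels (defaults to the
#'   matrix dimnames or `cond1..condN`).
#' @param type provenance tag, e.g. `"model"` or `"neural"`.
#' @return An object of class `rdm` (a matrix with `labels` and `type`
#'   attributes).
#' @export
rdm <- function(mat, labels = NULL, type = "model") {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat))
    stop_invalid("an RDM must be square, got %d x %d", nrow(mat), ncol(mat))
  if (is.null(labels)) labels <- rownames(mat) %||% paste0("cond", seq_len(nrow(mat)))
  if (length(labels) != nrow(mat))
    stop_invalid("label length (%d) does not match RDM size (%d)",
                 length(labels), nrow(mat))
  validate_rdm(mat)
  dimnames(mat) <- list(labels, labels)
  structure(mat, class = c("rdm", "matrix", "array"),
            labels = labels, type = type)
}

validate_rdm <- function(mat, tol = 1e-8) {
  if (any(!is.finite(mat))) stop_invalid("RDM contains non-finite entries")
  if (max(abs(mat - t(mat))) > tol) stop_invalid("RDM is not symmetric")
  if (max(abs(diag(mat))) > tol) stop_invalid("RDM diagonal is not zero")
  if (min(mat) < -tol || max(mat) > 2 + tol)
    stop_invalid("RDM entries outside [0, 2]")
  invisible(TRUE)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM (%s): %d conditions, RD range [%.3f, %.3f]\n",
              attr(x, "type"), nrow(x), min(x[upper.tri(x)] %||% 0), max(x)))
  invisible(x)
}

#' @export
plot.rdm <- function(x, main = NULL, ...) {
  n <- nrow(x)
  image(seq_len(n), seq_len(n), t(unclass(x))[, n:1],
        col = hcl.colors(64, "viridis"), axes = FALSE,
        xlab = "", ylab = "", main = main %||% attr(x, "type"), ...)
  axis(1, at = seq_len(n), labels = attr(x, "labels"), las = 2, cex.axis = 0.5)
  axis(2, at = seq_len(n), labels = rev(attr(x, "labels")), las = 2, cex.axis = 0.5)
  invisible(x)
}

#' Correlation distance between two pattern vectors
#'
#' Representational distance of the analysis: `1 - Pearson r`, ranging from
#' 0 (identical up to positive affine scaling) through 1 (uncorrelated) to
#' 2 (sign-flipped).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return scalar RD in `[0, 2]`.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_invalid("pattern vectors must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop_invalid("undefined correlation: constant pattern vector")
  1 - cor(x, y)
}

#' Fisher z transform of a correlation
#'
#' `atanh(r)`, the variance-stabilizing transform used for all reported RSA
#' correlations.  Correlations at or beyond +/-1 are clipped to `1 - eps`
#' in magnitude (with a warning) so the transform stays finite.
#'
#' @param r correlation(s).
#' @param eps clipping margin, default `1e-7`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r, eps = 1e-7) {
  clip <- abs(r) >= 1 - eps
  if (any(clip, na.rm = TRUE)) {
    warning("correlation(s) clipped to +/-(1 - eps) before Fisher z")
    r[which(clip)] <- sign(r[which(clip)]) * (1 - eps)
  }
  atanh(r)
}

#' Vectorize the upper triangle of an RDM
#'
#' Returns the above-diagonal entries in row-major order (row 1 against
#' columns 2..n, then row 2 against 3..n, ...).  This fixed ordering is what
#' every model-neural comparison in the package uses.
#'
#' @param x an `rdm` or square matrix.
#' @return numeric vector of length `n(n-1)/2`.
#' @export
vectorize_upper <- function(x) {
  x <- as.matrix(x)
  t(x)[lower.tri(x)]  # row-major upper triangle
}

## inverse of vectorize_upper (used in tests and permutation plumbing)
unvectorize_upper <- function(v, n, labels = NULL, type = "model") {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  rdm(m, labels = labels, type = type)
}

#' Dimension-weighted model RDM
#'
#' Hypothesis model for task-relevance weighting of feature dimensions: cue
#' conjunctions are represented maximally similarly when the same feature
#' dimension is task relevant (RD = 0 for any two conditions of the same
#' search task) and maximally differently across tasks (RD = `d_max`).
#'
#' Pearson model correlations are invariant to the positive scale of
#' `d_max`; the default 2 matches the end point of the correlation-distance
#' scale.
#'
#' @param conditions the full 18-row [condition_set()].
#' @param d_max cross-task distance, default 2.
#' @return 18 x 18 `rdm`.
#' @export
dimension_weighted_rdm <- function(conditions = condition_set(), d_max = 2) {
  check_condition_set(conditions)
  same_task <- outer(conditions$task, conditions$task, `==`)
  m <- ifelse(same_task, 0, d_max)
  diag(m) <- 0
  rdm(m, labels = conditions$label, type = "model")
}

#' Expand a 9-cue stimulus RDM to the 18 conditions
#'
#' A stimulus-similarity model (e.g. the HMAX C1 RDM over the nine cue
#' images) is sensory only: the distance between `(cue i, task a)` and
#' `(cue j, task b)` is the 9 x 9 distance between cues i and j, and the
#' same cue under the two tasks is assigned RD 0.
#'
#' @param rdm9 9 x 9 `rdm` indexed by cue id.
#' @param conditions the full 18-row [condition_set()].
#' @return 18 x 18 `rdm`.
#' @export
expand_stimulus_rdm <- function(rdm9, conditions = condition_set()) {
  rdm9 <- as.matrix(rdm9)
  if (!all(dim(rdm9) == c(9, 9)))
    stop_invalid("stimulus RDM must be 9 x 9, got %d x %d", nrow(rdm9), ncol(rdm9))
  check_condition_set(conditions)
  m <- rdm9[conditions$cue_id, conditions$cue_id]
  rdm(m, labels = conditions$label, type = "model")
}

check_condition_set <- function(conditions) {
  if (!is.data.frame(conditions) || nrow(conditions) != 18 ||
      !all(c("label", "task", "cue_id") %in% names(conditions)) ||
      anyDuplicated(conditions$label) ||
      !all(table(conditions$task, conditions$cue_id) == 1))
    stop_invalid("need the complete 18-condition set (9 cues x 2 tasks)")
  invisible(TRUE)
}

#' Fisher-z correlation between a neural and a model RDM
#'
#' Pearson correlation between the vectorized upper triangles of the two
#' RDMs (which must share condition set and ordering), Fisher z transformed.
#'
#' @param neural,model `rdm` objects of identical size and labels.
#' @return scalar Fisher z.
#' @export
rdm_model_correlation <- function(neural, model) {
  if (!identical(dim(as.matrix(neural)), dim(as.matrix(model))))
    stop_invalid("neural and model RDM sizes differ")
  ln <- attr(neural, "labels"); lm_ <- attr(model, "labels")
  if (!is.null(ln) && !is.null(lm_) && !identical(ln, lm_))
    stop_invalid("neural and model RDM condition labels differ")
  vn <- vectorize_upper(neural)
  vm <- vectorize_upper(model)
  if (sd(vm) == 0) stop_invalid("undefined correlation: constant model RDM")
  if (sd(vn) == 0) stop_invalid("undefined correlation: constant neural RDM")
  fisher_z(cor(vn, vm))
}

#' Write / read an RDM as labeled CSV
#'
#' @param x an `rdm`.
#' @param path output file.
#' @return `write_rdm_csv` returns `path` invisibly; `read_rdm_csv` returns
#'   an `rdm`.
#' @export
write_rdm_csv <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @param type provenance tag for the read RDM.
#' @export
read_rdm_csv <- function(path, type = "model") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  rdm(as.matrix(df), labels = rownames(df), type = type)
}
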