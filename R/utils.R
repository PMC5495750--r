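## small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical arrays (or vectors) of identical shape.
#' @return Dice coefficient `2|A & B| / (|A| + |B|)`; `NA` if both masks are
#'   empty.
#' @export
dice <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

## Derive per-stage seeds from one master seed via a MINSTD-style LCG hash,
## so nested derivations stay distinct and below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  m <- 2147483647
  x <- ((abs(as.numeric(seed)) %% m) * 48271) %% m
  x <- (x + abs(as.numeric(offset)) + 1) %% m
  as.integer((x * 48271) %% m)
}

## index <-> (i,j,k) conversions for 0-based voxel coordinates
voxel_coords <- function(idx, dim) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(i, j, k)
}

## default affine for a synthetic 3 mm isotropic MNI-like grid, centered
default_affine <- function(dim, voxel_size = 3) {
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -voxel_size * (dim - 1) / 2
  aff
}

grid_to_mm <- function(ijk, affine) {
  ## ijk: n x 3 matrix of 0-based voxel indices
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

## spherical ROI mask on a grid (voxel units)
ball_mask <- function(dim, center, radius) {
  i <- seq_len(dim[1]) - 1
  j <- seq_len(dim[2]) - 1
  k <- seq_len(dim[3]) - 1
  d2 <- outer(outer((i - center[1])^2, (j - center[2])^2, `+`),
              (k - center[3])^2, `+`)
  array(d2 <= radius^2, dim = dim)
}
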