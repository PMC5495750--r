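## Spherical searchlight RSA: per-voxel neural RDMs from local beta
## patterns, correlated (Fisher z) with a model RDM.

#' Spherical searchlight neighborhoods
#'
#' For every in-mask voxel, the set of in-mask voxels whose centers lie
#' within `radius_mm` (Euclidean).  Stored in compressed form (one member
#' vector plus per-center offsets) for fast traversal.
#'
#' @param mask logical 3D array.
#' @param radius_mm searchlight radius in mm (>= half a voxel).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @return Object of class `neighborhoods`: `starts` (0-based offsets,
#'   length `V + 1`), `members` (mask-voxel indices), `counts`, `vox_lin`
#'   (linear grid index of each mask voxel), `dim`, `radius_mm`.
#' @export
sphere_neighborhoods <- function(mask, radius_mm, voxel_size_mm = 3) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (radius_mm < voxel_size_mm / 2)
    stop_invalid("radius (%g mm) must be at least half a voxel", radius_mm)
  V <- sum(mask)
  if (V == 0) stop_invalid("empty mask")
  d <- dim(mask)
  r <- floor(radius_mm / voxel_size_mm)
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  off <- off[rowSums(off^2) * voxel_size_mm^2 <= radius_mm^2, , drop = FALSE]
  ## put the zero offset first so the center is always a member
  off <- off[order(rowSums(off^2) != 0), , drop = FALSE]

  mask_index <- array(0L, d)
  mask_index[mask] <- seq_len(V)
  co <- which(mask, arr.ind = TRUE)  # V x 3, 1-based
  M <- matrix(0L, V, nrow(off))
  for (o in seq_len(nrow(off))) {
    i <- co[, 1] + off[o, 1]; j <- co[, 2] + off[o, 2]; k <- co[, 3] + off[o, 3]
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    lin <- (i - 1L) + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2] + 1L
    M[ok, o] <- mask_index[lin[ok]]
  }
  tm <- t(M)
  members <- tm[tm > 0L]
  counts <- colSums(tm > 0L)
  structure(list(starts = c(0L, cumsum(counts)), members = members,
                 counts = counts, vox_lin = which(mask), dim = d,
                 radius_mm = radius_mm, voxel_size_mm = voxel_size_mm),
            class = "neighborhoods")
}

#' @export
print.neighborhoods <- function(x, ...) {
  cat(sprintf("searchlight neighborhoods: %d centers, radius %g mm, %.1f voxels/sphere mean\n",
              length(x$counts), x$radius_mm, mean(x$counts)))
  invisible(x)
}

#' Members of one searchlight sphere
#'
#' @param nb a [sphere_neighborhoods()] object.
#' @param i center index (mask-voxel numbering).
#' @return Integer vector of member mask-voxel indices (center first).
#' @export
neighborhood <- function(nb, i) {
  nb$members[(nb$starts[i] + 1L):nb$starts[i + 1L]]
}

#' Neural RDM of a voxel neighborhood
#'
#' Correlation-distance RDM between all condition pairs of the local beta
#' patterns.
#'
#' @param betas a `beta_maps`.
#' @param members integer vector of mask-voxel indices (>= 3).
#' @return An 18 x 18 `rdm` of type `"neural"`.
#' @export
neural_rdm <- function(betas, members) {
  if (length(members) < 3) stop_invalid("neighborhood must contain >= 3 voxels")
  B <- betas$betas[, members, drop = FALSE]
  if (any(apply(B, 1, sd) == 0))
    stop_invalid("undefined correlation: constant pattern for a condition")
  m <- 1 - cor(t(B))
  m <- pmin(pmax(m, 0), 2)
  diag(m) <- 0
  rdm((m + t(m)) / 2, labels = betas$labels, type = "neural")
}

## per-center RDM vectors (upper triangle, row-major), standardized for
## fast correlation with (permuted) model vectors: rows have mean 0 and
## unit norm; degenerate spheres are NA rows.
subject_rdm_vectors <- function(betas, nb, min_voxels = 10) {
  R <- cpp_rdm_vectors(betas$betas, nb$starts, nb$members - 1L,
                       as.integer(min_voxels))
  mu <- rowMeans(R)
  R <- R - mu
  nrm <- sqrt(rowSums(R^2))
  bad <- !is.finite(nrm) | nrm == 0
  R <- R / ifelse(bad, 1, nrm)
  R[bad, ] <- NA_real_
  R
}

std_model_vector <- function(model) {
  v <- vectorize_upper(model)
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n == 0) stop_invalid("degenerate model RDM: constant off-diagonal")
  v / n
}

zmap_from_vectors <- function(RV, model_vec, eps = 1e-7) {
  r <- as.vector(RV %*% model_vec)
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Searchlight RSA map for one subject
#'
#' At every mask voxel with at least `min_voxels` sphere members, the
#' Fisher-z Pearson correlation between the local neural RDM and the model
#' RDM (both vectorized over the 153 condition pairs).  Degenerate spheres
#' yield NA and are counted as flagged.
#'
#' @param betas a `beta_maps` (ideally z-scored).
#' @param model an 18-condition model `rdm`.
#' @param radius_mm searchlight radius in mm.
#' @param nb optional precomputed [sphere_neighborhoods()].
#' @param min_voxels minimum sphere size retained near mask edges.
#' @return Object of class `searchlight_map`: `values` (3D array, NA off
#'   mask), `z` (vector over mask voxels), `mask`, provenance fields.
#' @export
run_searchlight <- function(betas, model, radius_mm = 9, nb = NULL,
                            min_voxels = 10) {
  if (!identical(attr(model, "labels"), betas$labels))
    stop_invalid("model and betas condition labels differ")
  if (is.null(nb))
    nb <- sphere_neighborhoods(betas$mask, radius_mm, betas$voxel_size)
  RV <- subject_rdm_vectors(betas, nb, min_voxels)
  z <- zmap_from_vectors(RV, std_model_vector(model))
  vol <- array(NA_real_, nb$dim)
  vol[nb$vox_lin] <- z
  structure(list(values = vol, z = z, mask = betas$mask,
                 radius_mm = nb$radius_mm, period = betas$period,
                 subject_id = betas$subject_id,
                 model = attr(model, "type"),
                 n_flagged = sum(!is.finite(z))),
            class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  cat(sprintf("searchlight map [%s, %s period]: radius %g mm, z range [%.3f, %.3f], %d flagged\n",
              x$subject_id %||% "group", x$period %||% "?", x$radius_mm,
              min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE), x$n_flagged))
  invisible(x)
}
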