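## Group-level inference: bootstrapped permutation cluster-size FWE on
## group-mean searchlight maps, and cluster reporting.

#' Permute the condition labels of a model RDM
#'
#' Applies one uniformly random simultaneous row/column permutation of the
#' condition labels, preserving the multiset of entries.
#'
#' @param model an `rdm`.
#' @param seed RNG seed (ignored when `perm` is given).
#' @param perm optional explicit permutation vector.
#' @return The relabeled `rdm`.
#' @export
permute_model <- function(model, seed = NULL, perm = NULL) {
  n <- nrow(model)
  if (is.null(perm)) {
    if (!is.null(seed)) set.seed(seed)
    perm <- sample(n)
  }
  m <- unclass(model)[perm, perm]
  rdm(m, labels = attr(model, "labels"), type = attr(model, "type"))
}

#' Permutation searchlight maps for every subject
#'
#' For each subject, `K` searchlight correlation maps computed under
#' independently permuted model condition labels (a fresh permutation per
#' subject and iteration).  The neural RDM vectors are computed once per
#' subject and reused, so only the model side is recomputed.
#'
#' @param betas_list list of per-subject `beta_maps`.
#' @param model the model `rdm`.
#' @param K permutations per subject (study default 150; >= 10).
#' @param radius_mm searchlight radius in mm.
#' @param seed RNG seed.
#' @param nb optional precomputed neighborhoods.
#' @param min_voxels minimum sphere size.
#' @param vectors optional precomputed list of subject RDM-vector matrices.
#' @return Object of class `permutation_maps`: `maps` (list of `V x K`
#'   Fisher-z matrices), `K`, `nb`, `seed`.
#' @export
permutation_maps <- function(betas_list, model, K = 150, radius_mm = 9,
                             seed = 1, nb = NULL, min_voxels = 10,
                             vectors = NULL) {
  if (K < 10) stop_invalid("K must be >= 10")
  if (is.null(nb))
    nb <- sphere_neighborhoods(betas_list[[1]]$mask, radius_mm,
                               betas_list[[1]]$voxel_size)
  if (is.null(vectors))
    vectors <- lapply(betas_list, subject_rdm_vectors, nb = nb,
                      min_voxels = min_voxels)
  n <- nrow(model)
  maps <- vector("list", length(vectors))
  for (s in seq_along(vectors)) {
    set.seed(derive_seed(seed, s))
    PM <- vapply(seq_len(K), function(k)
      std_model_vector(permute_model(model, perm = sample(n))),
      numeric(n * (n - 1) / 2))
    r <- vectors[[s]] %*% PM
    maps[[s]] <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  }
  structure(list(maps = maps, K = K, nb = nb, seed = seed,
                 radius_mm = nb$radius_mm),
            class = "permutation_maps")
}

#' Bootstrap null distribution of group-mean maps
#'
#' Each of `B` null group maps is the across-subject mean of one uniformly
#' chosen permutation map per subject (every subject contributes exactly
#' once to every bootstrap sample; sampling is with replacement across
#' samples).
#'
#' @param perms a [permutation_maps()] object (>= 2 subjects).
#' @param B number of bootstrap samples (study default 10000; >= 100).
#' @param seed RNG seed.
#' @return Object of class `bootstrap_distribution`: `null` (`V x B`
#'   matrix), `B`, `n_subjects`.
#' @export
bootstrap_group <- function(perms, B = 10000, seed = 1) {
  ns <- length(perms$maps)
  if (ns < 2) stop_invalid("bootstrap needs >= 2 subjects")
  if (B < 100) stop_invalid("B must be >= 100")
  set.seed(derive_seed(seed, 555))
  idx <- matrix(sample.int(perms$K, B * ns, replace = TRUE), B, ns)
  null <- matrix(0, nrow(perms$maps[[1]]), B)
  for (s in seq_len(ns))
    null <- null + perms$maps[[s]][, idx[, s], drop = FALSE]
  structure(list(null = null / ns, B = B, n_subjects = ns,
                 nb = perms$nb, K = perms$K),
            class = "bootstrap_distribution")
}

#' Per-voxel cluster-forming threshold from the bootstrap null
#'
#' The `1 - p_voxel` empirical quantile of the `B` null group-mean values
#' at each voxel.
#'
#' @param boot a [bootstrap_group()] distribution.
#' @param p_voxel voxelwise tail probability in `(0, 0.5]`;
#'   `B * p_voxel` must be at least 10.
#' @return Numeric vector of thresholds over mask voxels (attribute
#'   `p_voxel`).
#' @export
voxel_threshold <- function(boot, p_voxel = 0.01) {
  if (p_voxel <= 0 || p_voxel > 0.5)
    stop_invalid("p_voxel must be in (0, 0.5]")
  if (boot$B * p_voxel < 10)
    stop_invalid("B * p_voxel must be >= 10 for a stable tail quantile")
  thr <- cpp_row_quantile(boot$null, 1 - p_voxel)
  attr(thr, "p_voxel") <- p_voxel
  thr
}

#' Supra-threshold clusters of a z map
#'
#' Connected components of `{z > threshold}` under the configured
#' connectivity.
#'
#' @param zmap a `searchlight_map`, or a 3D array of z values (NA off
#'   mask).
#' @param threshold scalar, per-mask-voxel vector, or 3D array.
#' @param connectivity 6, 18 or 26 (voxel face/edge/vertex adjacency).
#' @param mask logical 3D array (needed when `threshold` is a mask-voxel
#'   vector and `zmap` is a plain array).
#' @return List with `labels` (3D integer array, 0 = background), `sizes`,
#'   `n_clusters`.
#' @export
extract_clusters <- function(zmap, threshold, connectivity = 26, mask = NULL) {
  if (inherits(zmap, "searchlight_map")) {
    mask <- zmap$mask
    zmap <- zmap$values
  }
  d <- dim(zmap)
  thr_arr <- array(Inf, d)
  if (length(threshold) == 1) {
    thr_arr[] <- threshold
  } else if (is.array(threshold) && length(dim(threshold)) == 3) {
    thr_arr <- threshold
  } else {
    if (is.null(mask)) stop_invalid("mask required for vector thresholds")
    thr_arr[which(mask)] <- threshold
  }
  supra <- !is.na(zmap) & !is.na(thr_arr) & zmap > thr_arr
  labels <- array(cpp_label_clusters(as.logical(supra), as.integer(d),
                                     as.integer(connectivity)), d)
  sizes <- if (max(labels) > 0) tabulate(labels[labels > 0]) else integer(0)
  list(labels = labels, sizes = sizes, n_clusters = length(sizes))
}

#' Cluster-size FWE correction via the bootstrap null
#'
#' Thresholds every bootstrap map with the per-voxel threshold, records the
#' null distribution of (by default, per-map maximum) cluster sizes, and
#' assigns each observed supra-threshold cluster the corrected p-value
#' `(1 + #{null >= size}) / (B + 1)`.
#'
#' @param zmap observed group-mean map (`searchlight_map` or 3D array).
#' @param boot a [bootstrap_group()] distribution.
#' @param threshold output of [voxel_threshold()].
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param alpha familywise error level for the `significant` flag.
#' @param null_type `"max"` (familywise control via the per-map maximum
#'   cluster size) or `"pooled"` (all null cluster sizes pooled).
#' @param affine 4x4 voxel-to-mm affine for reported coordinates.
#' @return A `cluster_table` data frame (one row per observed cluster,
#'   largest first) with size, max/mean/sd Fisher z, peak and
#'   center-of-mass coordinates (grid and mm), corrected p and
#'   significance; cluster label array in attribute `"labels"`.
#' @export
cluster_fwe <- function(zmap, boot, threshold, connectivity = 26,
                        alpha = 0.01, null_type = c("max", "pooled"),
                        affine = NULL) {
  null_type <- match.arg(null_type)
  if (inherits(zmap, "searchlight_map")) {
    mask <- zmap$mask
    vol <- zmap$values
  } else {
    mask <- array(FALSE, dim(zmap)); mask[boot$nb$vox_lin] <- TRUE
    vol <- zmap
  }
  d <- dim(vol)
  if (is.null(affine)) affine <- default_affine(d)
  nulls <- cpp_null_cluster_sizes(boot$null, as.numeric(threshold),
                                  boot$nb$vox_lin - 1L, as.integer(d),
                                  as.integer(connectivity),
                                  null_type == "pooled")
  null_sizes <- if (null_type == "max") nulls$max_sizes else nulls$all_sizes
  n_null <- if (null_type == "max") boot$B else length(null_sizes)

  cl <- extract_clusters(vol, threshold, connectivity, mask = mask)
  rows <- list()
  if (cl$n_clusters > 0) {
    ord <- order(cl$sizes, decreasing = TRUE)
    for (ci in seq_along(ord)) {
      lab <- ord[ci]
      vox <- which(cl$labels == lab)
      zs <- vol[vox]
      co <- voxel_coords(vox, d)           # 0-based
      peak <- which.max(zs)
      com <- colMeans(co)
      peak_mm <- grid_to_mm(co[peak, , drop = FALSE], affine)
      com_mm <- grid_to_mm(matrix(com, 1), affine)
      p <- (1 + sum(null_sizes >= length(vox))) / (n_null + 1)
      rows[[ci]] <- data.frame(
        cluster = ci, label = lab, size = length(vox),
        max_z = max(zs),
        max_i = co[peak, 1], max_j = co[peak, 2], max_k = co[peak, 3],
        max_x_mm = peak_mm[1], max_y_mm = peak_mm[2], max_z_mm = peak_mm[3],
        mean_z = mean(zs), sd_z = sd(zs),
        com_i = com[1], com_j = com[2], com_k = com[3],
        com_x_mm = com_mm[1], com_y_mm = com_mm[2], com_z_mm = com_mm[3],
        p_corr = p, significant = p < alpha)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    cluster = integer(0), label = integer(0), size = integer(0), max_z = numeric(0),
    max_i = numeric(0), max_j = numeric(0), max_k = numeric(0),
    max_x_mm = numeric(0), max_y_mm = numeric(0), max_z_mm = numeric(0),
    mean_z = numeric(0), sd_z = numeric(0),
    com_i = numeric(0), com_j = numeric(0), com_k = numeric(0),
    com_x_mm = numeric(0), com_y_mm = numeric(0), com_z_mm = numeric(0),
    p_corr = numeric(0), significant = logical(0))
  structure(out, class = c("cluster_table", "data.frame"),
            labels = cl$labels, alpha = alpha, connectivity = connectivity,
            null_type = null_type, B = boot$B, K = boot$K,
            null_max_sizes = nulls$max_sizes)
}

#' Format and optionally write a cluster table
#'
#' Emits the reporting schema (size, max Fisher z, peak location, mean
#' Fisher z, sd, center of mass, corrected p) with configuration
#' provenance, as CSV or JSON.
#'
#' @param table a `cluster_table`.
#' @param path optional output file (`.csv` or `.json`).
#' @param provenance named list echoed into the output (radius, K, B,
#'   seeds, ...).
#' @return The formatted data frame, invisibly when writing.
#' @export
cluster_report <- function(table, path = NULL, provenance = list()) {
  prov <- c(list(alpha = attr(table, "alpha"),
                 connectivity = attr(table, "connectivity"),
                 null_type = attr(table, "null_type"),
                 B = attr(table, "B"), K = attr(table, "K")),
            provenance)
  df <- as.data.frame(table)
  if (!is.null(path)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(list(provenance = prov, clusters = df), path,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      con <- file(path, "w")
      writeLines(paste0("# ", names(prov), " = ",
                        vapply(prov, function(x) paste(x, collapse = ","), "")),
                 con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    return(invisible(df))
  }
  df
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("cluster table: %d cluster(s), %d significant at alpha = %g (%s null)\n",
              nrow(x), sum(x$significant), attr(x, "alpha"), attr(x, "null_type")))
  if (nrow(x))
    print.data.frame(head(as.data.frame(x)[, c("cluster", "size", "max_z",
                                               "mean_z", "sd_z", "p_corr",
                                               "significant")], 10),
                     digits = 4, row.names = FALSE)
  invisible(x)
}

#' Group searchlight RSA with bootstrapped cluster inference
#'
#' The central model fit: computes each subject's searchlight Fisher-z map
#' for the given model RDM, averages them into the group map, builds the
#' permutation/bootstrap null (`K` label permutations per subject, `B`
#' bootstrap group means), forms the per-voxel cluster threshold at
#' `p_voxel`, and reports supra-threshold clusters with cluster-size
#' FWE-corrected p-values.
#'
#' @param betas_list list of per-subject (z-scored) `beta_maps`.
#' @param model an 18-condition model `rdm`.
#' @param radius_mm searchlight radius in mm.
#' @param K permutation maps per subject.
#' @param B bootstrap samples.
#' @param p_voxel voxelwise cluster-forming tail probability.
#' @param alpha cluster-level FWE threshold.
#' @param connectivity cluster connectivity (default 26).
#' @param null_type `"max"` or `"pooled"` cluster-size null.
#' @param min_voxels minimum searchlight sphere size.
#' @param seed RNG seed governing permutations and bootstrap.
#' @param model_name label used in reports.
#' @param center_maps center every subject map (observed and permutation
#'   alike) at its spatial mean before group aggregation.  The GLM noise
#'   covariance between condition betas is identical at every voxel, which
#'   gives each map a model-dependent global offset; centering removes this
#'   shared offset so cluster inference targets spatially specific
#'   representational structure and the permutation null stays exchangeable
#'   with the observed map.
#' @param include_identity include each subject's observed (identity
#'   permutation) map in its bootstrap pool, the standard guarantee for
#'   valid permutation inference; with large `K` the effect is negligible,
#'   at small `K` it corrects the anti-conservative bias of an
#'   atoms-only empirical null.
#' @return Object of class `rsa_group` with the group map, per-subject
#'   maps, threshold, cluster table and configuration.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n_subjects = 3, n_blocks = 1,
#'                           grid = c(10, 10, 10), seed = 2)
#' betas <- lapply(cohort, function(d) {
#'   des <- build_design(d$events, "cue", d$TR, dim(d$data)[4])
#'   zscore_conditions(fit_glm(d, des))
#' })
#' fit <- rsa_group(betas, dimension_weighted_rdm(), radius_mm = 6,
#'                  K = 10, B = 100, seed = 3)
#' print(fit)
#' }
#' @export
rsa_group <- function(betas_list, model, radius_mm = 9, K = 150, B = 10000,
                      p_voxel = 0.01, alpha = 0.01, connectivity = 26,
                      null_type = c("max", "pooled"), min_voxels = 10,
                      seed = 1, model_name = NULL, center_maps = TRUE,
                      include_identity = TRUE) {
  null_type <- match.arg(null_type)
  stopifnot(length(betas_list) >= 2)
  nb <- sphere_neighborhoods(betas_list[[1]]$mask, radius_mm,
                             betas_list[[1]]$voxel_size)
  vectors <- lapply(betas_list, subject_rdm_vectors, nb = nb,
                    min_voxels = min_voxels)
  mv <- std_model_vector(model)
  subject_z <- vapply(vectors, zmap_from_vectors, numeric(length(nb$counts)),
                      model_vec = mv)
  if (center_maps)
    subject_z <- sweep(subject_z, 2, colMeans(subject_z, na.rm = TRUE))
  group_z <- rowMeans(subject_z)
  group_map <- array(NA_real_, nb$dim)
  group_map[nb$vox_lin] <- group_z

  perms <- permutation_maps(betas_list, model, K = K, nb = nb, seed = seed,
                            min_voxels = min_voxels, vectors = vectors)
  if (center_maps)
    perms$maps <- lapply(perms$maps, function(m)
      sweep(m, 2, colMeans(m, na.rm = TRUE)))
  if (include_identity) {
    perms$maps <- lapply(seq_along(perms$maps), function(s)
      cbind(subject_z[, s], perms$maps[[s]]))
    perms$K <- perms$K + 1L
  }
  boot <- bootstrap_group(perms, B = B, seed = seed)
  thr <- voxel_threshold(boot, p_voxel)
  affine <- betas_list[[1]]$affine %||% default_affine(nb$dim)
  clusters <- cluster_fwe(group_map, boot, thr, connectivity = connectivity,
                          alpha = alpha, null_type = null_type,
                          affine = affine)
  thr_map <- array(NA_real_, nb$dim)
  thr_map[nb$vox_lin] <- thr
  structure(list(
    group_map = group_map, group_z = group_z, subject_z = subject_z,
    threshold_map = thr_map, clusters = clusters, nb = nb,
    model_name = model_name %||% attr(model, "type"),
    config = list(radius_mm = radius_mm, K = K, B = B, p_voxel = p_voxel,
                  alpha = alpha, connectivity = connectivity,
                  null_type = null_type, min_voxels = min_voxels,
                  seed = seed, n_subjects = length(betas_list),
                  center_maps = center_maps,
                  include_identity = include_identity,
                  period = betas_list[[1]]$period)),
    class = "rsa_group")
}

#' @export
print.rsa_group <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Group searchlight RSA (%s model, %s period)\n",
              x$model_name, cfg$period %||% "?"))
  cat(sprintf("  %d subjects, radius %g mm, K = %d, B = %d, p_voxel = %g, alpha = %g\n",
              cfg$n_subjects, cfg$radius_mm, cfg$K, cfg$B, cfg$p_voxel,
              cfg$alpha))
  print(x$clusters)
  invisible(x)
}

#' @export
summary.rsa_group <- function(object, ...) {
  object$clusters
}

#' @export
plot.rsa_group <- function(x, slices = NULL, ...) {
  d <- dim(x$group_map)
  if (is.null(slices)) slices <- unique(round(seq(2, d[3] - 1, length.out = 6)))
  op <- par(mfrow = c(2, ceiling(length(slices) / 2)), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  rng <- range(x$group_map, na.rm = TRUE)
  for (k in slices)
    image(x$group_map[, , k], zlim = rng, col = hcl.colors(64, "viridis"),
          axes = FALSE, main = sprintf("z slice %d", k))
  invisible(x)
}

#' Mask of the significant clusters of a fit
#'
#' @param x an `rsa_group` fit.
#' @return Logical 3D array covering all FWE-significant clusters.
#' @export
significant_mask <- function(x) {
  stopifnot(inherits(x, "rsa_group"))
  labs <- attr(x$clusters, "labels")
  sig <- x$clusters$label[x$clusters$significant]
  array(labs %in% sig & labs > 0, dim(labs))
}
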