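test_that("model permutation relabels without changing the entry multiset", {
  m <- dimension_weighted_rdm()
  expect_equal(unclass(permute_model(m, perm = 1:18)), unclass(m))
  p <- permute_model(m, seed = 4)
  expect_equal(sort(as.vector(unclass(p))), sort(as.vector(unclass(m))))
  expect_equal(attr(p, "labels"), attr(m, "labels"))
  ## Monte-Carlo mean of original-vs-permuted correlation matches a
  ## brute-force sample average under exchangeability
  v <- vectorize_upper(m)
  set.seed(6)
  r_matrix <- replicate(500, cor(v, vectorize_upper(permute_model(m))))
  set.seed(106)
  r_entry <- replicate(500, cor(v, v[sample(153)]))
  ## both the label-permutation average and the brute-force entry-shuffle
  ## average sit near zero under exchangeability
  expect_lt(abs(mean(r_entry)), 3 * sqrt(var(r_entry) / 500) + 0.01)
  expect_lt(abs(mean(r_matrix)), 0.1)
})

test_that("permutation maps are reproducible and centered on null data", {
  betas <- make_test_betas(2, grid = c(9, 9, 9), seed = 12)
  m <- dimension_weighted_rdm()
  pm1 <- permutation_maps(betas, m, K = 12, radius_mm = 6, seed = 3)
  pm2 <- permutation_maps(betas, m, K = 12, radius_mm = 6, seed = 3)
  expect_identical(pm1$maps, pm2$maps)
  expect_equal(length(pm1$maps), 2)
  expect_equal(ncol(pm1$maps[[1]]), 12)
  ## per-voxel mean over permutation maps is near zero (CLT bound)
  mn <- rowMeans(pm1$maps[[1]])
  expect_lt(mean(abs(mn)), 3 * sd(pm1$maps[[1]]) / sqrt(12))
  expect_error(permutation_maps(betas, m, K = 5), ">= 10")
})

test_that("bootstrap group maps average one permutation map per subject", {
  betas <- make_test_betas(3, grid = c(8, 8, 8), seed = 5)
  m <- dimension_weighted_rdm()
  pm <- permutation_maps(betas, m, K = 15, radius_mm = 6, seed = 2)
  boot <- bootstrap_group(pm, B = 200, seed = 7)
  expect_equal(dim(boot$null), c(nrow(pm$maps[[1]]), 200))
  ## variance of bootstrap maps ~ mean per-subject map variance / n_subjects
  v_boot <- mean(apply(boot$null, 1, var))
  v_subj <- mean(vapply(pm$maps, function(x) mean(apply(x, 1, var)), numeric(1)))
  expect_equal(v_boot, v_subj / 3, tolerance = 0.2 * v_subj / 3 + 0.005)
  expect_error(bootstrap_group(pm, B = 10), ">= 100")
})

test_that("voxel thresholds are empirical tail quantiles", {
  set.seed(13)
  boot <- structure(list(null = matrix(rnorm(50 * 10000), 50), B = 10000,
                         n_subjects = 4, K = 30), class = "bootstrap_distribution")
  thr <- voxel_threshold(boot, 0.01)
  expect_true(all(abs(thr - qnorm(0.99)) < 0.1))
  med <- voxel_threshold(boot, 0.5)
  expect_equal(as.numeric(med), apply(boot$null, 1, median), tolerance = 1e-10)
  expect_true(all(thr >= voxel_threshold(boot, 0.05)))  # quantile monotonicity
  expect_error(voxel_threshold(boot, 0.6), "p_voxel")
  expect_error(voxel_threshold(structure(list(null = boot$null[, 1:100], B = 100),
                                         class = "bootstrap_distribution"), 0.01),
               ">= 10")
})

test_that("cluster extraction obeys connectivity rules", {
  z <- array(0, c(10, 10, 10))
  z[2:4, 2:4, 2:4] <- 1
  cl <- extract_clusters(z, 0.5, 26)
  expect_equal(cl$n_clusters, 1)
  expect_equal(cl$sizes, 27)
  ## two cubes separated by more than one voxel: two clusters
  z[7:9, 7:9, 7:9] <- 1
  expect_equal(extract_clusters(z, 0.5, 26)$n_clusters, 2)
  expect_equal(extract_clusters(z, 0.5, 6)$n_clusters, 2)
  ## diagonal-touching voxels merge at 26- but not 6-connectivity
  z2 <- array(0, c(5, 5, 5))
  z2[2, 2, 2] <- 1; z2[3, 3, 3] <- 1
  expect_equal(extract_clusters(z2, 0.5, 26)$n_clusters, 1)
  expect_equal(extract_clusters(z2, 0.5, 6)$n_clusters, 2)
})

test_that("cluster labeling matches a breadth-first oracle on random fields", {
  set.seed(17)
  for (i in 1:60) {
    d <- c(sample(4:7, 1), sample(4:7, 1), sample(4:7, 1))
    supra <- array(runif(prod(d)) < 0.35, d)
    conn <- sample(c(6, 18, 26), 1)
    got <- array(templight:::cpp_label_clusters(as.logical(supra),
                                                as.integer(d),
                                                as.integer(conn)), d)
    want <- oracle_label_clusters(supra, conn)
    expect_true(same_partition(got, want))
  }
})

test_that("cluster FWE reporting has the documented schema and conventions", {
  betas <- make_test_betas(3, grid = c(9, 9, 9), seed = 31)
  fit <- rsa_group(betas, dimension_weighted_rdm(), radius_mm = 6, K = 10,
                   B = 120, p_voxel = 0.1, alpha = 0.05, seed = 2)
  tab <- fit$clusters
  expect_true(all(c("size", "max_z", "max_x_mm", "mean_z", "sd_z",
                    "com_x_mm", "p_corr", "significant") %in% names(tab)))
  if (nrow(tab)) {
    expect_true(all(tab$mean_z <= tab$max_z + 1e-12))
    expect_true(all(tab$p_corr > 0 & tab$p_corr <= 1))
    expect_gte(min(tab$p_corr), 1 / (120 + 1))  # plus-one floor
  }
  ## report writes csv and json with provenance
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".json")
  cluster_report(tab, f1, provenance = list(seed = 2))
  cluster_report(tab, f2, provenance = list(seed = 2))
  expect_true(file.exists(f1) && file.exists(f2))
  js <- jsonlite::read_json(f2)
  expect_equal(js$provenance$alpha, 0.05)
  unlink(c(f1, f2))
  ## empty table path
  V <- length(fit$nb$counts)
  empty <- cluster_fwe(array(NA_real_, c(9, 9, 9)),
                       structure(list(null = matrix(rnorm(V * 120), V),
                                      B = 120, K = 10,
                                      nb = fit$nb), class = "bootstrap_distribution"),
                       rep(Inf, V))
  expect_equal(nrow(empty), 0)
  expect_s3_class(cluster_report(empty), "data.frame")
})

test_that("center of mass of a symmetric cluster is its geometric center", {
  z <- array(NA_real_, c(12, 12, 12))
  mask <- array(TRUE, c(12, 12, 12))
  z[] <- 0
  z[4:6, 5:8, 3:4] <- 1  # cuboid
  nb <- sphere_neighborhoods(mask, 3, 3)
  boot <- structure(list(null = matrix(rnorm(prod(dim(z)) * 120, sd = 0.01),
                                       prod(dim(z))),
                         B = 120, K = 10, nb = nb),
                    class = "bootstrap_distribution")
  tab <- cluster_fwe(z, boot, rep(0.5, prod(dim(z))), alpha = 0.05)
  expect_equal(nrow(tab), 1)
  expect_equal(unlist(tab[1, c("com_i", "com_j", "com_k")]),
               c(com_i = 4, com_j = 5.5, com_k = 2.5))  # 0-based centers
})

test_that("group inference is deterministic and exchangeable under relabeling", {
  betas <- make_test_betas(3, grid = c(9, 9, 9), seed = 77)
  m <- dimension_weighted_rdm()
  f1 <- rsa_group(betas, m, radius_mm = 6, K = 10, B = 120, p_voxel = 0.1,
                  seed = 5)
  f2 <- rsa_group(betas, m, radius_mm = 6, K = 10, B = 120, p_voxel = 0.1,
                  seed = 5)
  expect_identical(as.data.frame(f1$clusters), as.data.frame(f2$clusters))
  expect_identical(f1$group_map, f2$group_map)

  ## permuting conditions of all subjects and the model leaves the observed
  ## group map unchanged
  set.seed(3)
  p <- sample(18)
  betas_p <- lapply(betas, function(b) { b$betas <- b$betas[p, ]; b })
  m_p <- rdm(unclass(m)[p, p], labels = attr(m, "labels"))
  f3 <- rsa_group(betas_p, m_p, radius_mm = 6, K = 10, B = 120, p_voxel = 0.1,
                  seed = 5)
  expect_equal(f3$group_map, f1$group_map)
})
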