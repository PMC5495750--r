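test_that("correlation distance spans the 0-2 scale", {
  x <- c(1, 2, 3, 5)
  expect_equal(correlation_distance(x, x), 0)
  expect_equal(correlation_distance(x, -x), 2)
  expect_equal(correlation_distance(c(1, -1, 1, -1), c(1, 1, -1, -1)), 1)
  expect_error(correlation_distance(c(1, 1, 1), x[1:3]), "constant")
  expect_error(correlation_distance(1:2, 1:2), "length")
})

test_that("correlation distance matches the covariance-formula oracle", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(correlation_distance(x, y), oracle_correlation_distance(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Fisher z is the odd atanh transform with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306144334, tolerance = 1e-10)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(fisher_z(r), oracle_fisher_z(r), tolerance = 1e-12)
  expect_warning(z <- fisher_z(1), "clipped")
  expect_equal(z, atanh(1 - 1e-7))
})

test_that("upper-triangle vectorization is row-major and round-trips", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- 0  # fill explicitly below
  vals <- c(12, 13, 14, 23, 24, 34) / 100
  r <- templight:::unvectorize_upper(vals, 4)
  expect_equal(vectorize_upper(r), vals)      # documented row-major order
  expect_equal(unclass(r)[1, 2], 0.12)
  expect_equal(unclass(r)[3, 4], 0.34)
  expect_length(vectorize_upper(dimension_weighted_rdm()), 153)  # 18*17/2
  expect_length(vectorize_upper(rdm(matrix(c(0, 1, 1, 0), 2))), 1)
})

test_that("the dimension-weighted model is a two-block task structure", {
  m <- dimension_weighted_rdm()
  cs <- condition_set()
  expect_equal(dim(unclass(m)), c(18, 18))
  expect_equal(unclass(m)[1, 7], 0)           # same task (SF), different cues
  expect_equal(unclass(m)["SF_cue1", "ORIENTATION_cue1"], 2)  # cross task
  off <- unclass(m)[upper.tri(m)]
  expect_setequal(unique(off), c(0, 2))
  same_task <- outer(cs$task, cs$task, `==`)
  expect_true(all(unclass(m)[upper.tri(m) & same_task] == 0))
  expect_true(all(unclass(m)[upper.tri(m) & !same_task] == 2))
  expect_error(dimension_weighted_rdm(condition_set()[1:10, ]), "18-condition")
})

test_that("stimulus RDM expansion tiles the 9x9 matrix over both tasks", {
  set.seed(1)
  r <- cor(matrix(rnorm(20 * 9), 20))
  r9 <- rdm(1 - r, labels = paste0("cue", 1:9))
  m <- expand_stimulus_rdm(r9)
  expect_equal(unclass(m)[1:9, 1:9], unclass(m)[10:18, 10:18],
               ignore_attr = TRUE)
  expect_equal(unclass(m)[1:9, 1:9], unclass(r9), ignore_attr = TRUE)
  ## same cue under different tasks is distance 0 (sensory-only model)
  expect_equal(unclass(m)["SF_cue3", "ORIENTATION_cue3"], 0)
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(diag(unclass(m)) == 0))
  expect_error(expand_stimulus_rdm(rdm(matrix(0, 3, 3))), "9 x 9")
})

test_that("model-neural RDM correlation is affine-invariant and errors on degenerate models", {
  m <- dimension_weighted_rdm()
  set.seed(3)
  noise <- matrix(rnorm(18 * 18, sd = 0.1), 18)
  nm <- unclass(m) + noise + t(noise)
  diag(nm) <- 0
  nm <- rdm(pmin(pmax(nm, 0), 2), labels = attr(m, "labels"), type = "neural")
  expect_warning(z_self <- rdm_model_correlation(m, m), "clipped")
  expect_equal(z_self, atanh(1 - 1e-7))
  ## positive rescaling of the model leaves the Pearson correlation at 1
  scaled <- rdm(unclass(m) * 0.4, labels = attr(m, "labels"))
  expect_warning(z_scaled <- rdm_model_correlation(scaled, m), "clipped")
  expect_equal(z_scaled, z_self)
  ## noisy neural RDM correlates positively but below the ceiling
  z_noisy <- rdm_model_correlation(nm, m)
  expect_gt(z_noisy, 0.5)
  expect_lt(z_noisy, z_self)
  const <- rdm(matrix(1, 18, 18) - diag(1, 18), labels = attr(m, "labels"))
  expect_error(rdm_model_correlation(nm, const), "constant model")
})

test_that("permuted model entries are uncorrelated with the original on average", {
  m <- dimension_weighted_rdm()
  v <- vectorize_upper(m)
  set.seed(9)
  zs <- replicate(1000, {
    p <- sample(153)
    atanh(cor(v, v[p]))
  })
  expect_lt(abs(mean(zs)), 0.01)
})

test_that("rdm construction enforces the RDM invariants", {
  expect_error(rdm(matrix(1:6, 2, 3)), "square")
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(rdm(bad), "symmetric")
  expect_error(rdm(matrix(c(0, 3, 3, 0), 2)), "\\[0, 2\\]")
  expect_error(rdm(matrix(c(1, 0, 0, 1), 2)), "diagonal")
})

test_that("RDMs serialize to labeled CSV and back", {
  m <- dimension_weighted_rdm()
  f <- tempfile(fileext = ".csv")
  write_rdm_csv(m, f)
  m2 <- read_rdm_csv(f)
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
  expect_equal(attr(m2, "labels"), attr(m, "labels"))
  unlink(f)
})
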