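test_that("Gaussian smoothing is mass-conserving with the stated sigma", {
  v <- array(0, c(15, 15, 15))
  expect_identical(smooth_volume(v + 1, 0), v + 1)  # fwhm 0 is identity
  v[8, 8, 8] <- 1
  s <- smooth_volume(v, fwhm_mm = 4, voxel_size_mm = 3)
  expect_equal(sum(s), 1, tolerance = 1e-6)         # interior mass conserved
  ## profile through the center matches the closed-form Gaussian
  sigma <- 4 / 2.3548 / 3
  prof <- s[, 8, 8] / s[8, 8, 8]
  expected <- exp(-((1:15 - 8)^2) / (2 * sigma^2))
  expect_equal(prof, expected, tolerance = 1e-4)
  expect_error(smooth_volume(v, -1), ">= 0")
})

test_that("design matrices carry 18 condition regressors plus nuisance and drift", {
  sched <- block_schedule(seed = 5)
  ev <- schedule_events(sched)
  n_scans <- ceiling((max(ev$onset + ev$duration) + 16) / 2)
  des <- build_design(ev, "cue", 2, n_scans)
  expect_equal(length(des$condition_idx), 18)
  expect_equal(colnames(des$X)[des$condition_idx], condition_set()$label)
  expect_equal(qr(des$X)$rank, ncol(des$X))
  ## delay-period design has the same shape
  des_d <- build_design(ev, "delay", 2, n_scans)
  expect_equal(length(des_d$condition_idx), 18)
  ## missing phase events rejected
  expect_error(build_design(ev[ev$phase != "cue", ], "cue", 2, n_scans),
               "missing")
  ## doubling an event's duration roughly doubles the regressor integral
  r1 <- templight:::make_regressor(20, 2, 2, 100)
  r2 <- templight:::make_regressor(20, 4, 2, 100)
  expect_equal(sum(r2) / sum(r1), 2, tolerance = 0.05)
})

test_that("OLS betas recover planted amplitudes exactly without noise", {
  sched <- session_schedule(1, seed = 4)
  grid <- c(8, 8, 8)
  roi <- array(FALSE, grid); roi[2:5, 2:5, 2:5] <- TRUE
  target <- dimension_weighted_rdm()
  d <- simulate_subject(sched, list(effect_spec(roi, target, 1, "cue")),
                        noise_sigma = 0, grid = grid, seed = 7)
  des <- build_design(d$events, "cue", d$TR, dim(d$data)[4])
  fit <- fit_glm(d, des)
  patt <- condition_patterns(target, sum(roi),
                             seed = templight:::derive_seed(7, sum(utf8ToInt("effect"))))
  est <- fit$betas[, match(which(roi), which(d$mask))]
  expect_lt(max(abs(est - patt)) / max(abs(patt)), 1e-6)
  ## zero data give zero betas
  d0 <- d; d0$data[] <- 0
  expect_equal(max(abs(fit_glm(d0, des)$betas)), 0)
  ## scan count mismatch rejected
  d_short <- d0
  d_short$data <- d0$data[, , , 1:10, drop = FALSE]
  expect_error(fit_glm(d_short, des), "scan count")
})

test_that("OLS matches the normal-equation oracle on random problems", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(20:40, 1); p <- sample(3:8, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- matrix(rnorm(n * 4), n)
    qb <- qr.coef(qr(X), y)
    expect_equal(qb, oracle_ols(X, y), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("pure-noise betas are unbiased", {
  sched <- session_schedule(1, seed = 9)
  d <- simulate_subject(sched, list(), noise_sigma = 1, grid = c(13, 13, 13),
                        seed = 10)
  fit <- fit_glm(d, build_design(d$events, "cue", d$TR, dim(d$data)[4]))
  m <- mean(fit$betas)
  expect_lt(abs(m) / sd(fit$betas), 0.05)
})

test_that("voxelwise z-scoring normalizes conditions and ignores constant offsets", {
  sched <- block_schedule(seed = 1)
  d <- simulate_subject(sched, list(), noise_sigma = 1, grid = c(6, 6, 6), seed = 2)
  fit <- fit_glm(d, build_design(d$events, "cue", d$TR, dim(d$data)[4]))
  z <- zscore_conditions(fit)
  expect_lt(max(abs(colMeans(z$betas))), 1e-12)
  sds <- sqrt(colSums(sweep(z$betas, 2, colMeans(z$betas))^2) / 17)
  expect_lt(max(abs(sds - 1)), 1e-12)
  ## adding a constant across conditions at a voxel changes nothing
  fit2 <- fit
  fit2$betas[, 5] <- fit2$betas[, 5] + 7
  expect_equal(zscore_conditions(fit2)$betas[, 5], z$betas[, 5])
  ## zero-variance voxels flagged and zeroed
  fit3 <- fit
  fit3$betas[, 2] <- 3
  z3 <- zscore_conditions(fit3)
  expect_equal(unname(z3$betas[, 2]), rep(0, 18))
  expect_equal(attr(z3, "flagged"), 2L)
})

test_that("cue-period betas are immune to delay-only planted signal", {
  for (seed in 1:2) {
    sched <- session_schedule(2, seed = seed)
    grid <- c(8, 8, 8)
    roi <- array(FALSE, grid); roi[2:6, 2:6, 2:6] <- TRUE
    d <- simulate_subject(sched,
                          list(effect_spec(roi, dimension_weighted_rdm(), 1, "delay")),
                          noise_sigma = 0, grid = grid, seed = seed)
    des <- build_design(d$events, "cue", d$TR, dim(d$data)[4])
    fit <- fit_glm(d, des)
    leak <- mean(abs(fit$betas[, match(which(roi), which(d$mask))]))
    expect_lt(leak, 0.2)  # planted delay patterns have unit scale
  }
})
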