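## Shared fixtures and independent oracles used across test files.
## Everything is generated in code; no data files.

## brute-force correlation distance via the explicit covariance formula
oracle_correlation_distance <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sx <- sqrt(sum((x - mean(x))^2) / (n - 1))
  sy <- sqrt(sum((y - mean(y))^2) / (n - 1))
  1 - sxy / (sx * sy)
}

oracle_fisher_z <- function(r) 0.5 * log((1 + r) / (1 - r))

## closed-form normal-equation OLS
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

## breadth-first connected components on a logical 3D array
oracle_label_clusters <- function(supra, connectivity = 26) {
  d <- dim(supra)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(off))
  off <- off[nz > 0 & (connectivity == 26 | (connectivity == 18 & nz <= 2) |
                         (connectivity == 6 & nz <= 1)), , drop = FALSE]
  labels <- array(0L, d)
  nxt <- 0L
  for (start in which(supra)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1) %% d[1] + 1
      j <- ((cur - 1) %/% d[1]) %% d[2] + 1
      k <- (cur - 1) %/% (d[1] * d[2]) + 1
      for (o in seq_len(nrow(off))) {
        ii <- i + off[o, 1]; jj <- j + off[o, 2]; kk <- k + off[o, 3]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
        lin <- ii + (jj - 1) * d[1] + (kk - 1) * d[1] * d[2]
        if (supra[lin] && labels[lin] == 0L) {
          labels[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

## small cohort of GLM-fitted, z-scored beta maps (pure noise by default)
make_test_betas <- function(n_subjects = 3, grid = c(10, 10, 10),
                            n_blocks = 1, seed = 1, effects = list(),
                            noise_sigma = 1) {
  cohort <- simulate_cohort(n_subjects, effects = effects,
                            n_blocks = n_blocks, noise_sigma = noise_sigma,
                            seed = seed, grid = grid)
  lapply(cohort, function(d) {
    des <- build_design(d$events, "cue", d$TR, dim(d$data)[4])
    zscore_conditions(fit_glm(d, des))
  })
}

## identical labels of two cluster labelings up to renumbering
same_partition <- function(a, b) {
  fa <- as.integer(factor(a[a > 0], levels = unique(a[a > 0])))
  fb <- as.integer(factor(b[b > 0], levels = unique(b[b > 0])))
  all((a > 0) == (b > 0)) && all(fa == fb)
}
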