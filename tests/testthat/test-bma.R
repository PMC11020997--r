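test_that("posterior model probabilities match the quadrature oracle", {
  skip_if_not_installed("pracma")
  set.seed(61)
  # K = 2 and K = 3 toy instances on the standardized scale (se_Gamma = 1)
  X2 <- matrix(rnorm(8 * 2), 8, 2)
  y2 <- as.vector(X2 %*% c(0.4, 0)) + rnorm(8)
  fit2 <- bma_fit(X2, y2, rep(1, 8))
  expect_equal(fit2$posteriors, bma_quadrature_oracle(X2, y2),
               tolerance = 1e-6)

  X3 <- matrix(rnorm(10 * 3), 10, 3)
  y3 <- as.vector(X3 %*% c(0.3, 0, 0)) + rnorm(10)
  fit3 <- bma_fit(X3, y3, rep(1, 10))
  expect_equal(fit3$posteriors, bma_quadrature_oracle(X3, y3),
               tolerance = 1e-6)
})

test_that("posteriors normalize and MIP/MACE satisfy their definitions", {
  s <- simulate_multivariable(sim_config(J = 40, K = 4, rho = 0.4,
                                         theta = c(0.3, 0, 0, 0),
                                         seed = 62))
  fit <- bma_fit(s$gamma_matrix, s$Gamma, s$se_Gamma)
  expect_equal(sum(fit$posteriors), 1, tolerance = 1e-12)
  # recompute MIP/MACE from the stored model space
  for (k in seq_along(fit$factors)) {
    inc <- vapply(fit$subsets, function(S) k %in% S, logical(1))
    mip_k <- sum(fit$posteriors[-1][inc])
    expect_equal(unname(fit$mip[k]), mip_k, tolerance = 1e-12)
    mace_k <- sum(vapply(which(inc), function(i)
      fit$posteriors[i + 1] * fit$thetas[[i + 1]][match(k, fit$subsets[[i]])],
      numeric(1)))
    expect_equal(unname(fit$mace[k]), mace_k, tolerance = 1e-12)
  }
})

test_that("exchangeable null factors get symmetric inclusion evidence", {
  # identical columns, zero outcome: MIPs exactly equal
  X <- matrix(rep(c(0.1, 0.2, 0.15, 0.05, 0.12), 2), ncol = 2)
  fit <- bma_fit(X, rep(0, 5), rep(1, 5))
  expect_equal(unname(fit$mip[1]), unname(fit$mip[2]), tolerance = 1e-12)
})

test_that("MIP is invariant to factor relabeling", {
  s <- simulate_multivariable(sim_config(J = 30, K = 3, rho = 0.6,
                                         theta = c(0.25, 0, 0),
                                         seed = 63))
  f1 <- bma_fit(s$gamma_matrix, s$Gamma, s$se_Gamma)
  perm <- c(2, 3, 1)
  gm <- s$gamma_matrix[, perm]
  f2 <- bma_fit(gm, s$Gamma, s$se_Gamma)
  expect_equal(unname(f2$mip), unname(f1$mip[perm]), tolerance = 1e-10)
})

test_that("a vanishing effect prior pushes Bayes factors to 1", {
  s <- simulate_multivariable(sim_config(J = 25, K = 3, rho = 0.3,
                                         theta = c(0.3, 0, 0),
                                         seed = 64))
  fit <- bma_fit(s$gamma_matrix, s$Gamma, s$se_Gamma,
                 bma_config(prior_variance = 1e-12))
  # all models collapse to their priors: MIP_k -> prior inclusion prob
  expect_equal(unname(fit$mip), rep(0.1, 3), tolerance = 1e-4)
})

test_that("K = 1 matches the analytic two-model Bayes factor", {
  set.seed(65)
  x <- rnorm(12); y <- 0.3 * x + rnorm(12)
  fit <- bma_fit(matrix(x, ncol = 1), y, rep(1, 12),
                 bma_config(prior_prob = 0.2, prior_variance = 0.5))
  # independent analytic route: y ~ N(0, I + s2 x x^T) vs y ~ N(0, I)
  s2 <- 0.5
  v <- 1 + s2 * sum(x^2)
  log_bf <- -0.5 * log(v) +
    0.5 * s2 * sum(x * y)^2 / v
  post_odds <- exp(log_bf) * 0.2 / 0.8
  expect_equal(fit$posteriors[2] / fit$posteriors[1], post_odds,
               tolerance = 1e-10)
})

test_that("permutation p-values are extreme, uniform and reproducible", {
  s <- simulate_multivariable(sim_config(J = 40, K = 3, rho = 0.7,
                                         theta = c(0.4, 0, 0),
                                         seed = 66))
  cfg <- bma_config(n_permutations = 100, seed = 5)
  p <- bma_permutation_p(s$gamma_matrix, s$Gamma, s$se_Gamma, cfg)
  # a strong signal beats every permutation
  expect_equal(unname(p[1]), 1 / 101, tolerance = 1e-12)
  p2 <- bma_permutation_p(s$gamma_matrix, s$Gamma, s$se_Gamma, cfg)
  expect_identical(as.vector(p), as.vector(p2))

  # null data: p roughly uniform (mean near 0.5 over factors and seeds)
  means <- sapply(1:6, function(i) {
    sn <- simulate_multivariable(sim_config(J = 30, K = 3, rho = 0,
                                            theta = 0, seed = 950 + i))
    mean(bma_permutation_p(sn$gamma_matrix, sn$Gamma, sn$se_Gamma,
                           bma_config(n_permutations = 100, seed = i)))
  })
  expect_gte(mean(means), 0.4)
  expect_lte(mean(means), 0.6)
})

test_that("BH adjustment reproduces the step-up hand trace", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_fdr(0.7), 0.7)
})

test_that("influence filtering removes a planted outlier exactly once", {
  s <- simulate_multivariable(sim_config(J = 40, K = 3, rho = 0.5,
                                         theta = c(0.3, 0, 0),
                                         seed = 68))
  # clean data: nothing excluded
  f0 <- bma_influence_filter(s$gamma_matrix, s$Gamma, s$se_Gamma)
  expect_equal(nrow(f0$excluded_variants), 0)
  expect_equal(f0$gamma_matrix, s$gamma_matrix)

  # plant one grossly offset outcome effect
  G <- s$Gamma
  G[7] <- G[7] + 10 * s$se_Gamma[7]
  f1 <- bma_influence_filter(s$gamma_matrix, G, s$se_Gamma)
  expect_true(7 %in% f1$excluded_variants$index)
  expect_true("q_outlier" %in%
                f1$excluded_variants$reason[f1$excluded_variants$index == 7])
  # single-pass idempotence: refiltering the filtered output is a no-op
  f2 <- bma_influence_filter(f1$gamma_matrix, f1$Gamma, f1$se_Gamma)
  expect_equal(nrow(f2$excluded_variants), 0)
})

test_that("exhaustive enumeration is guarded for large factor panels", {
  gm <- matrix(rnorm(30 * 26), 30, 26)
  expect_error(bma_fit(gm, rnorm(30), rep(1, 30)), "max_model_size")
})
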