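test_that("Wald ratio and its delta-method errors are exact", {
  e <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.2)
  e2 <- wald_ratio(0.1, 0.01, 0.05, 0.02, second_order = TRUE)
  expect_equal(e2$se, sqrt(0.2^2 + (0.5 * 0.1)^2), tolerance = 1e-12)
  e0 <- wald_ratio(0.1, 0.01, 0, 0.02)
  expect_equal(e0$beta, 0)
  expect_equal(e0$se, 0.2)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "undefined")
})

test_that("IVW matches hand computation and the regression oracle", {
  d <- make_hdata(c(0.1, 0.2), c(0.05, 0.10), seG = 0.02)
  e <- ivw(d, "fixed")
  expect_equal(e$beta, 0.5, tolerance = 1e-12)
  expect_equal(ivw(d, "random")$se, e$se)  # Q = 0, no inflation

  d2 <- make_hdata(c(1, 1), c(0.4, 0.6), seG = 0.1)
  ef <- ivw(d2, "fixed"); er <- ivw(d2, "random")
  expect_equal(ef$beta, 0.5)
  expect_equal(ef$se, 1 / sqrt(200), tolerance = 1e-12)
  expect_equal(er$se, sqrt(2) / sqrt(200), tolerance = 1e-12)

  # closed form equals zero-intercept weighted least squares
  set.seed(11)
  for (i in 1:10) {
    J <- sample(3:30, 1)
    d3 <- make_hdata(rnorm(J, 0.1, 0.05), rnorm(J, 0.02, 0.03),
                     seG = runif(J, 0.01, 0.1))
    w <- 1 / d3$se_outcome^2
    oracle <- wls_oracle(matrix(d3$beta_exposure), d3$beta_outcome, w)
    expect_equal(ivw(d3, "fixed")$beta, oracle, tolerance = 1e-10)
  }
  expect_error(ivw(d[1, ]), "insufficient")
})

test_that("IVW is invariant to jointly flipping instrument signs", {
  set.seed(12)
  d <- make_hdata(rnorm(10, 0.1, 0.03), rnorm(10, 0.05, 0.02),
                  seG = runif(10, 0.01, 0.05))
  flip <- d
  flip$beta_exposure[c(2, 5)] <- -flip$beta_exposure[c(2, 5)]
  flip$beta_outcome[c(2, 5)] <- -flip$beta_outcome[c(2, 5)]
  expect_equal(ivw(flip)$beta, ivw(d)$beta, tolerance = 1e-12)
})

test_that("Egger recovers exact lines and matches the WLS oracle", {
  d <- make_hdata(c(0.1, 0.2, 0.3), c(0.06, 0.10, 0.14), seG = 0.05)
  e <- egger(d)
  expect_equal(e$beta, 0.4, tolerance = 1e-9)
  expect_equal(e$intercept, 0.02, tolerance = 1e-9)

  set.seed(13)
  for (i in 1:5) {
    J <- sample(4:25, 1)
    d2 <- make_hdata(abs(rnorm(J, 0.1, 0.05)), rnorm(J, 0.03, 0.02),
                     seG = runif(J, 0.01, 0.08))
    w <- 1 / d2$se_outcome^2
    oracle <- wls_oracle(cbind(1, d2$beta_exposure), d2$beta_outcome, w)
    e2 <- egger(d2)
    expect_equal(e2$intercept, oracle[1], tolerance = 1e-10)
    expect_equal(e2$beta, oracle[2], tolerance = 1e-10)
  }
  expect_error(egger(d[1:2, ]), "insufficient")
})

test_that("Egger slope equals IVW when the fitted intercept is zero", {
  # constructed so the weighted intercept is exactly 0: symmetric design
  d <- make_hdata(c(1, 2, 3), c(0.5, 1.0, 1.5), seG = 0.1)
  e <- egger(d)
  expect_equal(e$intercept, 0, tolerance = 1e-10)
  expect_equal(e$beta, ivw(d, "fixed")$beta, tolerance = 1e-10)
})

test_that("weighted median interpolates cumulative standardized ranks", {
  # ratios (0.4, 0.5, 0.6), normalized weights (0.25, 0.5, 0.25):
  # ranks (0.125, 0.5, 0.875), estimate exactly 0.5
  d <- make_hdata(c(1, 1, 1), c(0.4, 0.5, 0.6),
                  seG = c(0.02, 0.02 / sqrt(2), 0.02))
  e <- weighted_median(d, n_boot = 0)
  expect_equal(e$beta, 0.5, tolerance = 1e-12)

  # all ratios equal: the common ratio regardless of weights
  d2 <- make_hdata(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20),
                   seG = c(0.01, 0.03, 0.07))
  expect_equal(weighted_median(d2, n_boot = 0)$beta, 0.5,
               tolerance = 1e-12)

  # equal weights reduce to the unweighted median interpolation
  d3 <- make_hdata(rep(1, 4), c(0.2, 0.4, 0.6, 0.8), seG = 0.05)
  expect_equal(weighted_median(d3, n_boot = 0)$beta, 0.5,
               tolerance = 1e-12)

  # same seed, same bootstrap se
  s1 <- weighted_median(d3, n_boot = 200, seed = 4)$se
  s2 <- weighted_median(d3, n_boot = 200, seed = 4)$se
  expect_identical(s1, s2)
  expect_error(weighted_median(d[1:2, ], n_boot = 0), "insufficient")
})

test_that("mode estimators find the ratio cluster, not the outlier", {
  g <- rep(1, 4)
  G <- c(0.50, 0.51, 0.49, 2.0)
  d <- make_hdata(g, G, seG = 0.05)
  e <- mode_estimate(d, "simple", n_boot = 0)
  expect_gte(e$beta, 0.49); expect_lte(e$beta, 0.51)

  # agreement with a dense-grid density argmax oracle
  r <- G / g
  h <- 0.9 * min(sd(r), IQR(r) / 1.349) * length(r)^(-1 / 5)
  expect_equal(e$beta, grid_mode_oracle(r, rep(0.25, 4), h),
               tolerance = 1e-4)

  # weighted variant with the outlier down-weighted 100x
  dw <- make_hdata(g, G, seG = c(0.05, 0.05, 0.05, 0.5))
  ew <- mode_estimate(dw, "weighted", n_boot = 0)
  w <- (1 / dw$se_outcome^2); w <- w / sum(w)
  expect_equal(ew$beta, grid_mode_oracle(r, w, h), tolerance = 1e-4)
  expect_gte(ew$beta, 0.49); expect_lte(ew$beta, 0.51)

  # degenerate: all ratios identical
  d0 <- make_hdata(c(1, 2, 4), c(0.5, 1, 2), seG = 0.05)
  expect_equal(mode_estimate(d0, "simple", n_boot = 0)$beta, 0.5)
})

test_that("odds-ratio view exponentiates the Wald interval", {
  expect_equal(unname(to_odds_ratio(mr_estimate("ivw_random", 0, 0.1, 5))[1]), 1)
  e <- mr_estimate("ivw_random", log(1.159), 0.05, 5)
  expect_equal(unname(to_odds_ratio(e)["or"]), 1.159, tolerance = 1e-12)
  or <- to_odds_ratio(mr_estimate("ivw_random", 0.1, 0.05, 5))
  expect_equal(unname(or), c(exp(0.1), exp(0.1 - 1.96 * 0.05),
                             exp(0.1 + 1.96 * 0.05)), tolerance = 1e-12)
  expect_equal(round(unname(or), 3), c(1.105, 1.002, 1.219))
})

test_that("the estimator suite dispatches on instrument count", {
  d <- make_hdata(c(0.1, 0.2, 0.3, 0.15), c(0.05, 0.1, 0.16, 0.08),
                  seG = 0.03)
  tab <- mr_all_methods(d, n_boot = 50, seed = 1)
  expect_setequal(tab$method, c("ivw_random", "ivw_fixed", "egger",
                                "weighted_median", "simple_mode",
                                "weighted_mode"))
  tab1 <- mr_all_methods(d[1, ], n_boot = 0)
  expect_equal(tab1$method, "wald_ratio")
  # single-instrument IVW degenerates to the Wald ratio via dispatch
  expect_equal(tab1$beta, d$beta_outcome[1] / d$beta_exposure[1])
  tab2 <- mr_all_methods(d[1:2, ], n_boot = 0)
  expect_setequal(tab2$method, c("ivw_random", "ivw_fixed"))
})

test_that("all five estimators converge to the truth with valid instruments", {
  # moderate-n simulation: mean estimate near theta for every method
  theta <- 0.15
  means <- sapply(1:60, function(i) {
    s <- simulate_two_sample(sim_config(J = 30, theta = theta,
                                        n_exp = 2e5, n_out = 4e5,
                                        case_fraction = 0.5,
                                        seed = 500 + i))
    d <- make_hdata(s$exposure$beta, s$outcome$beta,
                    seg = s$exposure$se, seG = s$outcome$se)
    c(ivw(d)$beta, egger(d)$beta, weighted_median(d, n_boot = 0)$beta,
      mode_estimate(d, "simple", n_boot = 0)$beta,
      mode_estimate(d, "weighted", n_boot = 0)$beta)
  })
  for (k in 1:5) expect_equal(mean(means[k, ]), theta, tolerance = 0.05)
})
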