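#' Construct an MR estimate
#'
#' Uniform result record for all causal estimators. Confidence bounds are
#' Wald 95% limits `beta +/- 1.96 se` and p-values are two-sided normal.
#'
#' @param method Estimator name.
#' @param beta,se Causal estimate and standard error.
#' @param n_snps Number of instruments used.
#' @param intercept,intercept_se,intercept_p Egger intercept triple
#'   (Egger only).
#' @return Object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_snps,
                        intercept = NULL, intercept_se = NULL,
                        intercept_p = NULL) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                 pvalue = .norm_p(beta, se), n_snps = n_snps,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_p = intercept_p),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pvalue))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  or <- to_odds_ratio(x)
  data.frame(method = x$method, nsnp = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             or = or[["or"]], or_low = or[["or_low"]],
             or_high = or[["or_high"]], stringsAsFactors = FALSE)
}

#' Wald ratio estimate for a single instrument
#'
#' Per-variant causal estimate `Gamma / gamma` (outcome effect over
#' exposure effect). The default first-order standard error is
#' `se_Gamma / |gamma|`; the second-order delta-method error additionally
#' propagates the exposure uncertainty:
#' `sqrt(se_Gamma^2 / gamma^2 + Gamma^2 se_gamma^2 / gamma^4)`.
#'
#' @param gamma,se_gamma Exposure effect and its standard error.
#' @param Gamma,se_Gamma Outcome effect and its standard error.
#' @param second_order Use the second-order standard error.
#' @return An [mr_estimate()] with method `"wald_ratio"`.
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma,
                       second_order = FALSE) {
  if (gamma == 0) stop("undefined ratio: exposure effect gamma is 0")
  beta <- Gamma / gamma
  se <- if (second_order) {
    sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)
  } else {
    se_Gamma / abs(gamma)
  }
  mr_estimate("wald_ratio", beta, se, 1L)
}

# IVW building block on raw vectors; returns list(beta, se_fixed, Q)
.ivw_core <- function(g, G, seG) {
  w <- 1 / seG^2
  denom <- sum(w * g^2)
  beta <- sum(w * g * G) / denom
  list(beta = beta, se_fixed = 1 / sqrt(denom),
       Q = sum(w * (G - beta * g)^2))
}

#' Inverse-variance-weighted estimate
#'
#' Meta-analysis of per-variant Wald ratios with first-order inverse
#' variance weights `1 / se_Gamma^2`, equivalent to zero-intercept
#' weighted regression of the outcome effects on the exposure effects:
#' `beta = sum(w g Gamma) / sum(w g^2)`. The fixed-effects standard error
#' is `(sum w g^2)^(-1/2)`; the random-effects (multiplicative
#' over-dispersion) error inflates it by `max(1, sqrt(Q / (J - 1)))` with
#' Cochran's Q evaluated at the estimate, so it can never be
#' anti-conservative.
#'
#' @param hset A [harmonized_set()] (or effect-pair `data.frame`) with at
#'   least 2 variants.
#' @param effects `"random"` (default, primary model) or `"fixed"`.
#' @return An [mr_estimate()] with method `"ivw_random"` or `"ivw_fixed"`.
#' @export
ivw <- function(hset, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  d <- .hdata(hset)
  if (nrow(d) < 2)
    stop("insufficient instruments for IVW (need >= 2); use wald_ratio")
  core <- .ivw_core(d$beta_exposure, d$beta_outcome, d$se_outcome)
  se <- core$se_fixed
  if (effects == "random")
    se <- se * max(1, sqrt(core$Q / (nrow(d) - 1)))
  mr_estimate(paste0("ivw_", effects), core$beta, se, nrow(d))
}

# weighted simple linear regression via the normal equations, with
# multiplicative over-dispersion scaling floored at min_scale
.wls_line <- function(x, y, w, min_scale = 1) {
  X <- cbind(1, x)
  A <- crossprod(X, w * X)
  b <- solve(A, crossprod(X, w * y))[, 1]
  resid <- y - X %*% b
  s <- sqrt(sum(w * resid^2) / (length(y) - 2))
  se_unit <- sqrt(diag(solve(A)))
  scale <- max(min_scale, s)
  list(intercept = unname(b[1]), slope = unname(b[2]),
       se_intercept = unname(se_unit[1] * scale),
       se_slope = unname(se_unit[2] * scale), sigma = s)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept, `Gamma = alpha + theta gamma`, weights `1 / se_Gamma^2`.
#' Before fitting, each pair is oriented so that all exposure effects are
#' non-negative (jointly flipping the signs of `(gamma, Gamma)`), the
#' standard Egger orientation. The intercept estimates the average
#' directional pleiotropy; its two-sided normal test is the Egger
#' intercept test. Standard errors use multiplicative over-dispersion with
#' the residual scale floored at 1.
#'
#' @param hset A [harmonized_set()] with at least 3 variants.
#' @return An [mr_estimate()] with method `"egger"` carrying the
#'   intercept triple.
#' @export
egger <- function(hset) {
  d <- .hdata(hset)
  if (nrow(d) < 3)
    stop("insufficient instruments for MR-Egger (need >= 3)")
  flip <- sign(d$beta_exposure)
  flip[flip == 0] <- 1
  g <- d$beta_exposure * flip
  G <- d$beta_outcome * flip
  fit <- .wls_line(g, G, 1 / d$se_outcome^2)
  est <- mr_estimate("egger", fit$slope, fit$se_slope, nrow(d),
                     intercept = fit$intercept,
                     intercept_se = fit$se_intercept,
                     intercept_p = .norm_p(fit$intercept, fit$se_intercept))
  est
}

# per-variant ratio estimates and first-order inverse-variance weights
.ratios <- function(d, second_order = FALSE) {
  b <- d$beta_outcome / d$beta_exposure
  se <- if (second_order) {
    sqrt(d$se_outcome^2 / d$beta_exposure^2 +
           d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4)
  } else {
    d$se_outcome / abs(d$beta_exposure)
  }
  list(beta = b, w = 1 / se^2)
}

# weighted median by cumulative-rank interpolation
.weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  S <- cumsum(w)
  p <- (S - w / 2) / S[length(S)]
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  approx(p, b, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap over the summary statistics; returns matrix of
# resampled (beta_exposure, beta_outcome) estimates via `statistic`
.parametric_boot <- function(d, n_boot, seed, statistic) {
  set.seed(seed)
  J <- nrow(d)
  vapply(seq_len(n_boot), function(i) {
    g <- rnorm(J, d$beta_exposure, d$se_exposure)
    G <- rnorm(J, d$beta_outcome, d$se_outcome)
    statistic(data.frame(beta_exposure = g, se_exposure = d$se_exposure,
                         beta_outcome = G, se_outcome = d$se_outcome))
  }, numeric(1))
}

#' Weighted-median estimate
#'
#' The weighted median of the per-variant Wald ratios: ratios are sorted
#' ascending with inverse-variance weights, cumulative standardized ranks
#' `p_j = (S_j - w_j/2) / S_J` are formed, and the estimate is the linear
#' interpolation of the ratios at `p = 0.5`. Consistent when at least half
#' the weight comes from valid instruments. The standard error is a
#' seeded parametric bootstrap (resampling each `gamma_j`, `Gamma_j` from
#' normal distributions at their observed values and SEs).
#'
#' @param hset A [harmonized_set()] with at least 3 variants.
#' @param n_boot Bootstrap replicates (default 1000); `0` skips the
#'   bootstrap and returns `NA` standard error (point estimate only).
#' @param seed RNG seed for the bootstrap (required when `n_boot > 0`).
#' @param second_order Use second-order ratio weights.
#' @return An [mr_estimate()] with method `"weighted_median"`.
#' @export
weighted_median <- function(hset, n_boot = 1000, seed = NULL,
                            second_order = FALSE) {
  d <- .hdata(hset)
  if (nrow(d) < 3)
    stop("insufficient instruments for weighted median (need >= 3)")
  r <- .ratios(d, second_order)
  beta <- .weighted_median_point(r$beta, r$w)
  se <- NA_real_
  if (n_boot > 0) {
    if (is.null(seed)) stop("seed is required for the bootstrap")
    boots <- .parametric_boot(d, n_boot, seed, function(dd) {
      rr <- .ratios(dd, second_order)
      .weighted_median_point(rr$beta, rr$w)
    })
    se <- sd(boots)
  }
  est <- mr_estimate("weighted_median", beta, se, nrow(d))
  est
}

# mode of a weighted normal-kernel density over ratio estimates:
# evaluate at the ratio values, golden-section refine within the bracket
.kernel_mode <- function(b, w, h) {
  if (h == 0) return(b[1])
  dens <- function(x) {
    vapply(x, function(xx) sum(w * exp(-0.5 * ((xx - b) / h)^2)),
           numeric(1))
  }
  f0 <- dens(b)
  i <- which.max(f0)
  lo <- max(min(b), b[i] - h)
  hi <- min(max(b), b[i] + h)
  if (lo == hi) return(b[i])
  opt <- optimize(dens, c(lo, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  if (opt$objective >= f0[i]) opt$maximum else b[i]
}

.mode_bandwidth <- function(b, phi) {
  spread <- min(sd(b), IQR(b) / 1.349)
  phi * 0.9 * spread * length(b)^(-1 / 5)
}

#' Mode-based estimate (simple or weighted)
#'
#' The mode of the smoothed empirical density of per-variant Wald ratios:
#' a normal kernel with Silverman-type bandwidth
#' `h = phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)` is placed on each ratio
#' (equal weights for the simple mode, inverse-variance weights for the
#' weighted mode) and the density's argmax is located by evaluating it at
#' the ratio values and refining within the best bracket. Consistent when
#' the largest group of instruments with the same ratio is valid (ZEMPA).
#' Standard error by seeded parametric bootstrap, measured as the
#' MAD-scaled spread of the bootstrap modes.
#'
#' @param hset A [harmonized_set()] with at least 3 variants.
#' @param weighting `"simple"` (equal weights) or `"weighted"`
#'   (inverse-variance).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates; `0` skips (NA standard error).
#' @param seed RNG seed for the bootstrap.
#' @param second_order Use second-order ratio weights.
#' @return An [mr_estimate()] with method `"simple_mode"` or
#'   `"weighted_mode"`.
#' @export
mode_estimate <- function(hset, weighting = c("simple", "weighted"),
                          phi = 1, n_boot = 1000, seed = NULL,
                          second_order = FALSE) {
  weighting <- match.arg(weighting)
  d <- .hdata(hset)
  if (nrow(d) < 3)
    stop("insufficient instruments for mode estimator (need >= 3)")
  point <- function(dd) {
    r <- .ratios(dd, second_order)
    w <- if (weighting == "simple") rep(1, length(r$beta)) else r$w
    h <- .mode_bandwidth(r$beta, phi)
    .kernel_mode(r$beta, w / sum(w), h)
  }
  beta <- point(d)
  se <- NA_real_
  if (n_boot > 0) {
    if (is.null(seed)) stop("seed is required for the bootstrap")
    boots <- .parametric_boot(d, n_boot, seed, point)
    se <- mad(boots)
  }
  mr_estimate(paste0(weighting, "_mode"), beta, se, nrow(d))
}

#' Convert a log-odds estimate to an odds ratio with 95% CI
#'
#' @param est An [mr_estimate()] on the log-odds scale (binary outcome).
#' @return Named numeric vector `c(or, or_low, or_high)` where the bounds
#'   are `exp(beta +/- 1.96 se)`.
#' @export
to_odds_ratio <- function(est) {
  c(or = exp(est$beta), or_low = exp(est$beta - Z95 * est$se),
    or_high = exp(est$beta + Z95 * est$se))
}

#' Run the full univariable estimator suite
#'
#' Dispatches on the number of instruments: a single instrument gives the
#' Wald ratio; two give IVW only; three or more give IVW (random and
#' fixed), MR-Egger, weighted median, and the simple and weighted modes.
#'
#' @param hset A [harmonized_set()].
#' @param n_boot,seed Bootstrap settings for the median/mode estimators.
#' @return A `data.frame` with one row per estimator (columns `method`,
#'   `nsnp`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `or`, `or_low`,
#'   `or_high`).
#' @export
mr_all_methods <- function(hset, n_boot = 1000, seed = 1) {
  d <- .hdata(hset)
  J <- nrow(d)
  ests <- list()
  if (J == 0) stop("no instruments")
  if (J == 1) {
    ests <- list(wald_ratio(d$beta_exposure, d$se_exposure,
                            d$beta_outcome, d$se_outcome))
  } else {
    ests <- list(ivw(d, "random"), ivw(d, "fixed"))
    if (J >= 3) {
      ests <- c(ests, list(
        egger(d),
        weighted_median(d, n_boot = n_boot, seed = seed),
        mode_estimate(d, "simple", n_boot = n_boot, seed = seed + 1),
        mode_estimate(d, "weighted", n_boot = n_boot, seed = seed + 2)))
    }
  }
  do.call(rbind, lapply(ests, as.data.frame))
}
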