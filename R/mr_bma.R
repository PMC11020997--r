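#' MR-BMA configuration
#'
#' Priors and settings for Bayesian model averaging over candidate risk
#' factors. The defaults (inclusion probability 0.1, effect prior
#' variance 0.25) follow the original MR-BMA release.
#'
#' @param prior_prob Prior inclusion probability `pi` in (0, 1) for each
#'   factor; default 0.1.
#' @param prior_variance Prior variance `sigma^2` of each causal effect
#'   (on the standardized scale); default 0.25.
#' @param max_model_size Largest model (subset) size enumerated; `NULL`
#'   enumerates all non-empty subsets.
#' @param n_permutations Permutation replicates for empirical p-values;
#'   default 1000.
#' @param seed RNG seed for the permutation procedure.
#' @return List of class `bma_config`.
#' @export
bma_config <- function(prior_prob = 0.1, prior_variance = 0.25,
                       max_model_size = NULL, n_permutations = 1000,
                       seed = NULL) {
  stopifnot(prior_prob > 0, prior_prob < 1, prior_variance > 0)
  structure(list(prior_prob = prior_prob, prior_variance = prior_variance,
                 max_model_size = max_model_size,
                 n_permutations = n_permutations, seed = seed),
            class = "bma_config")
}

# enumerate all non-empty subsets of 1..K up to size mms
.enumerate_subsets <- function(K, mms) {
  out <- list()
  for (m in seq_len(min(K, mms))) {
    cols <- utils::combn(K, m)
    out <- c(out, lapply(seq_len(ncol(cols)), function(i) cols[, i]))
  }
  out
}

# log marginal likelihood (up to a subset-independent constant) and
# posterior-mean effects of the conjugate normal model on standardized data
.bma_model <- function(Xs, y, sigma2) {
  m <- ncol(Xs)
  A <- diag(m) + sigma2 * crossprod(Xs)
  Xty <- crossprod(Xs, y)
  cA <- chol(A)
  logdet <- 2 * sum(log(diag(cA)))
  AinvXty <- backsolve(cA, forwardsolve(t(cA), Xty))
  quad <- sum(y^2) - sigma2 * sum(Xty * AinvXty)
  list(logml = -0.5 * logdet - 0.5 * quad,
       theta = sigma2 * as.vector(AinvXty))
}

#' Bayesian model averaging over risk-factor subsets (MR-BMA)
#'
#' Enumerates every non-empty subset of the K candidate risk factors (up
#' to `max_model_size`), scores each with the closed-form marginal
#' likelihood of the weighted linear model `Gamma = gamma theta + e` under
#' independent normal priors `N(0, sigma^2)` on the causal effects and
#' unit residual variance after inverse-se standardization (both the
#' outcome effects and the exposure-effect columns are divided by
#' `se_Gamma`). Subset priors are `pi^|S| (1-pi)^(K-|S|)`; the empty model
#' is included in the normalization with its prior and null marginal
#' likelihood, so posterior model probabilities sum to one over the
#' enumerated space. Reports, per factor, the marginal inclusion
#' probability (MIP: summed posterior over models containing the factor)
#' and the model-averaged causal effect (MACE: posterior-weighted model
#' estimate, zero when absent).
#'
#' @param gamma_matrix J x K matrix of instrument-exposure effects.
#' @param Gamma,se_Gamma Outcome effects and standard errors (length J).
#' @param config A [bma_config()].
#' @return Object of class `bma_result`: `models` (data.frame of subsets,
#'   posterior probabilities and causal estimates, ordered by posterior),
#'   `mip`, `mace` (named per factor), `posteriors`, `config`.
#' @export
bma_fit <- function(gamma_matrix, Gamma, se_Gamma, config = bma_config()) {
  X0 <- as.matrix(gamma_matrix)
  J <- nrow(X0); K <- ncol(X0)
  factors <- colnames(X0) %||% paste0("factor", seq_len(K))
  colnames(X0) <- factors
  mms <- config$max_model_size %||% K
  if (K > 25 && mms >= K)
    stop("exhaustive enumeration over ", K,
         " factors is intractable; set max_model_size")
  stopifnot(J > min(K, mms))

  # inverse-se standardization: unit residual variance scale
  y <- Gamma / se_Gamma
  X <- X0 / se_Gamma
  sigma2 <- config$prior_variance
  pi_ <- config$prior_prob

  subsets <- .enumerate_subsets(K, mms)
  n_models <- length(subsets) + 1L  # + empty model
  logml <- numeric(n_models)
  logprior <- numeric(n_models)
  thetas <- vector("list", n_models)
  # empty model first
  logml[1] <- -0.5 * sum(y^2)
  logprior[1] <- K * log(1 - pi_)
  thetas[[1]] <- numeric(0)
  for (i in seq_along(subsets)) {
    S <- subsets[[i]]
    fit <- .bma_model(X[, S, drop = FALSE], y, sigma2)
    logml[i + 1] <- fit$logml
    logprior[i + 1] <- length(S) * log(pi_) + (K - length(S)) * log(1 - pi_)
    thetas[[i + 1]] <- fit$theta
  }
  lp <- logml + logprior
  post <- exp(lp - max(lp))
  post <- post / sum(post)

  mip <- setNames(numeric(K), factors)
  mace <- setNames(numeric(K), factors)
  for (i in seq_along(subsets)) {
    S <- subsets[[i]]
    mip[S] <- mip[S] + post[i + 1]
    mace[S] <- mace[S] + post[i + 1] * thetas[[i + 1]]
  }

  members <- c("(none)", vapply(subsets, function(S)
    paste(factors[S], collapse = ","), character(1)))
  est_str <- c("", vapply(seq_along(subsets), function(i)
    paste(signif(thetas[[i + 1]], 3), collapse = ","), character(1)))
  models <- data.frame(model = members,
                       size = c(0L, lengths(subsets)),
                       posterior = post,
                       estimates = est_str, stringsAsFactors = FALSE)
  models <- models[order(-models$posterior), , drop = FALSE]
  rownames(models) <- NULL

  structure(list(models = models, mip = mip, mace = mace,
                 posteriors = post, subsets = subsets, thetas = thetas,
                 factors = factors, config = config),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat("MR-BMA over", length(x$factors), "factors,",
      nrow(x$models), "models\n")
  cat("Top models:\n")
  print(head(x$models, 5), row.names = FALSE, digits = 3)
  cat("Per-factor MIP / MACE:\n")
  print(data.frame(factor = x$factors, MIP = unname(x$mip),
                   MACE = unname(x$mace)), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Permutation p-values for MR-BMA inclusion probabilities
#'
#' Re-runs [bma_fit()] on `B` datasets in which the outcome effect vector
#' (with its standard errors) is permuted across variants, breaking any
#' exposure-outcome relation while preserving the exposure-effect
#' correlation structure. The empirical p-value for factor k is
#' `(1 + #{permuted MIP_k >= observed MIP_k}) / (B + 1)`.
#'
#' @inheritParams bma_fit
#' @return Named numeric vector of per-factor empirical p-values; the
#'   observed [bma_result()] is attached as attribute `observed`.
#' @export
bma_permutation_p <- function(gamma_matrix, Gamma, se_Gamma,
                              config = bma_config()) {
  B <- config$n_permutations
  stopifnot(B >= 100)
  if (is.null(config$seed)) stop("config$seed is required")
  obs <- bma_fit(gamma_matrix, Gamma, se_Gamma, config)
  set.seed(config$seed)
  K <- length(obs$factors)
  exceed <- numeric(K)
  for (b in seq_len(B)) {
    perm <- sample.int(length(Gamma))
    mip_b <- bma_fit(gamma_matrix, Gamma[perm], se_Gamma[perm], config)$mip
    exceed <- exceed + (mip_b >= obs$mip)
  }
  p <- setNames((1 + exceed) / (B + 1), obs$factors)
  attr(p, "observed") <- obs
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_(j >= i) p_(j) m / j` clipped at 1 and mapped back to the
#' input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}

#' Exclude outlying and influential variants before MR-BMA
#'
#' One diagnostic pass in the style of the MR-BMA workflow: fit the
#' best-supported (highest posterior, non-empty) model from a preliminary
#' [bma_fit()], compute each variant's Cook's distance from that weighted
#' fit and its heterogeneity contribution `q_j` (squared standardized
#' residual), and exclude variants beyond either threshold. Defaults:
#' Cook's distance above `4 / J`; `q_j` above the upper `0.05 / J`
#' chi-square(1) quantile (Bonferroni-style).
#'
#' @inheritParams bma_fit
#' @param cooks_threshold Cook's distance cutoff; default the median of
#'   the F(m, J - m) reference distribution for the best model's size m,
#'   the classical calibration for Cook's distance.
#' @param q_threshold Heterogeneity cutoff; default
#'   `qchisq(1 - 0.05 / J, 1)`.
#' @return List with filtered `gamma_matrix`, `Gamma`, `se_Gamma`, the
#'   refit `bma_result` on the filtered data, and `excluded_variants`
#'   (data.frame `index`, `reason`).
#' @export
bma_influence_filter <- function(gamma_matrix, Gamma, se_Gamma,
                                 config = bma_config(),
                                 cooks_threshold = NULL,
                                 q_threshold = NULL) {
  X0 <- as.matrix(gamma_matrix)
  J <- nrow(X0)
  q_threshold <- q_threshold %||% qchisq(1 - 0.05 / J, df = 1)

  pre <- bma_fit(X0, Gamma, se_Gamma, config)
  nonempty <- pre$models[pre$models$size > 0, , drop = FALSE]
  best <- nonempty$model[1]
  S <- match(strsplit(best, ",")[[1]], pre$factors)
  cooks_threshold <- cooks_threshold %||%
    qf(0.5, length(S), J - length(S))
  stopifnot(cooks_threshold > 0, q_threshold > 0)

  y <- Gamma / se_Gamma
  X <- X0 / se_Gamma
  fit <- lm(y ~ 0 + X[, S, drop = FALSE])
  cooks <- cooks.distance(fit)
  qj <- residuals(fit)^2   # squared standardized residual (se units)

  out_cook <- which(cooks > cooks_threshold)
  out_q <- which(qj > q_threshold)
  excl <- sort(union(out_cook, out_q))
  if (length(excl) >= J) stop("influence filter would exclude all variants")
  excluded <- data.frame(
    index = excl,
    reason = ifelse(excl %in% out_q, "q_outlier", "influential"),
    stringsAsFactors = FALSE)

  keep <- setdiff(seq_len(J), excl)
  Xf <- X0[keep, , drop = FALSE]
  Gf <- Gamma[keep]; sf <- se_Gamma[keep]
  list(gamma_matrix = Xf, Gamma = Gf, se_Gamma = sf,
       fit = bma_fit(Xf, Gf, sf, config),
       excluded_variants = excluded)
}
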