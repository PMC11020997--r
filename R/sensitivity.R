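#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (Gamma_j - beta_ref * gamma_j)^2` with inverse-variance
#' weights `w_j = 1 / se_Gamma_j^2`, referred to a chi-square distribution
#' on `J - 1` degrees of freedom. By default `beta_ref` is the
#' fixed-effects IVW estimate, at which Q is minimal. A p-value below 0.05
#' is the conventional heterogeneity signal (and the trigger for using the
#' MR-PRESSO outlier-corrected estimate downstream).
#'
#' @param hset A [harmonized_set()] with at least 2 variants.
#' @param beta_ref Reference causal effect; default the fixed-effects IVW
#'   estimate.
#' @return List of class `heterogeneity_result`: `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(hset, beta_ref = NULL) {
  d <- .hdata(hset)
  if (nrow(d) < 2) stop("Cochran's Q needs >= 2 variants")
  w <- 1 / d$se_outcome^2
  if (is.null(beta_ref))
    beta_ref <- .ivw_core(d$beta_exposure, d$beta_outcome, d$se_outcome)$beta
  Q <- sum(w * (d$beta_outcome - beta_ref * d$beta_exposure)^2)
  df <- nrow(d) - 1L
  structure(list(Q = Q, df = df, pvalue = pchisq(Q, df, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n",
              x$Q, x$df, x$pvalue))
  invisible(x)
}

#' Egger intercept test for directional pleiotropy
#'
#' Reports the intercept of the MR-Egger regression with its standard
#' error and two-sided normal p-value, plus the conventional decision flag
#' `pleiotropy_suspected = (p < 0.05)`: an intercept distinguishable from
#' zero means horizontal pleiotropy cannot be ruled out.
#'
#' @param hset A [harmonized_set()] with at least 3 variants.
#' @return List with `intercept`, `se`, `pvalue`, `pleiotropy_suspected`.
#' @export
egger_intercept_test <- function(hset) {
  e <- egger(hset)
  list(intercept = e$intercept, se = e$intercept_se,
       pvalue = e$intercept_p,
       pleiotropy_suspected = e$intercept_p < 0.05)
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect omitting each instrument in turn; a
#' result driven by one influential variant shows up as a single omission
#' that moves the estimate materially.
#'
#' @param hset A [harmonized_set()] with at least 3 variants.
#' @param method `"ivw_random"` (default) or `"ivw_fixed"`.
#' @return A `data.frame` with one row per omitted variant (`variant_id`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pvalue`); the full-set estimate
#'   is attached as attribute `full_estimate` for plotting.
#' @export
leave_one_out <- function(hset, method = c("ivw_random", "ivw_fixed")) {
  method <- match.arg(method)
  effects <- sub("ivw_", "", method)
  d <- .hdata(hset)
  if (nrow(d) < 3) stop("leave-one-out needs >= 3 variants")
  rows <- lapply(seq_len(nrow(d)), function(j) {
    e <- ivw(d[-j, , drop = FALSE], effects)
    data.frame(variant_id = d$variant_id[j] %||% paste0("v", j),
               beta = e$beta, se = e$se, ci_low = e$ci_low,
               ci_high = e$ci_high, pvalue = e$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_estimate") <- ivw(d, effects)
  out
}
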