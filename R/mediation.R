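#' Two-step MR mediation analysis
#'
#' Product-of-coefficients mediation from three MR legs estimated in
#' non-overlapping samples: `beta1` (exposure -> mediator, trait SD
#' units), `beta2` (mediator -> outcome, log-odds per mediator SD) and
#' `beta3` (total exposure -> outcome, log-odds). The indirect effect is
#' `beta1 * beta2`, with first-order delta (Sobel) variance
#' `beta2^2 se1^2 + beta1^2 se2^2` (the two legs come from independent
#' samples, so no covariance term). The proportion mediated is
#' `beta1 * beta2 / beta3`; its default delta variance also propagates
#' the uncertainty in `beta3`
#' (`Var(prop) = Var(ind)/beta3^2 + ind^2 se3^2 / beta3^4`, zero
#' covariance), while `ci_mode = "fixed_total"` treats `beta3` as fixed
#' and propagates only the indirect effect's variance.
#'
#' @param beta1,se1 Exposure -> mediator effect and SE.
#' @param beta2,se2 Mediator -> outcome effect and SE (log-odds scale for
#'   a binary outcome, never the OR scale).
#' @param beta3,se3 Total exposure -> outcome effect and SE; `beta3` must
#'   be nonzero.
#' @param ci_mode `"full"` (default; `beta3` uncertainty included) or
#'   `"fixed_total"`.
#' @return Object of class `mediation_result` with fields `beta1..se3`,
#'   `indirect`, `se_indirect`, `pvalue` (Sobel test of the indirect
#'   effect), `proportion`, `se_proportion`, `prop_ci_low`,
#'   `prop_ci_high`, and logical `inconsistent` flagging an indirect
#'   effect of opposite sign to the total effect.
#' @export
#' @examples
#' # worked example: microbiome -> triglycerides -> disease
#' two_step_mediation(0.023, 0.009, log(1.159), 0.0486, log(1.110), 0.0497)
two_step_mediation <- function(beta1, se1, beta2, se2, beta3, se3,
                               ci_mode = c("full", "fixed_total")) {
  ci_mode <- match.arg(ci_mode)
  stopifnot(se1 > 0, se2 > 0, se3 > 0)
  if (beta3 == 0) stop("proportion mediated undefined: total effect is 0")

  indirect <- beta1 * beta2
  var_ind <- beta2^2 * se1^2 + beta1^2 * se2^2
  se_ind <- sqrt(var_ind)
  pvalue <- .norm_p(indirect, se_ind)

  proportion <- indirect / beta3
  var_prop <- var_ind / beta3^2
  if (ci_mode == "full")
    var_prop <- var_prop + indirect^2 * se3^2 / beta3^4
  se_prop <- sqrt(var_prop)

  inconsistent <- indirect != 0 && sign(indirect) != sign(beta3)
  if (inconsistent)
    warning("inconsistent mediation: indirect and total effects have ",
            "opposite signs")

  structure(list(beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                 beta3 = beta3, se3 = se3, indirect = indirect,
                 se_indirect = se_ind, pvalue = pvalue,
                 proportion = proportion, se_proportion = se_prop,
                 prop_ci_low = proportion - Z95 * se_prop,
                 prop_ci_high = proportion + Z95 * se_prop,
                 ci_mode = ci_mode, inconsistent = inconsistent),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  beta1 (exposure->mediator) = %.4g (se %.4g)\n",
              x$beta1, x$se1))
  cat(sprintf("  beta2 (mediator->outcome)  = %.4g (se %.4g)\n",
              x$beta2, x$se2))
  cat(sprintf("  beta3 (total effect)       = %.4g (se %.4g)\n",
              x$beta3, x$se3))
  cat(sprintf("  indirect = %.4g (se %.4g), p = %.3g\n",
              x$indirect, x$se_indirect, x$pvalue))
  cat(sprintf("  proportion mediated = %.1f%% (95%% CI %.1f%% to %.1f%%, %s)\n",
              100 * x$proportion, 100 * x$prop_ci_low,
              100 * x$prop_ci_high, x$ci_mode))
  if (x$inconsistent) cat("  WARNING: inconsistent mediation\n")
  invisible(x)
}

#' Choose the MR estimate feeding a mediation leg
#'
#' The decision rule for which estimator supplies each mediation
#' coefficient: when Cochran's Q signals heterogeneity (p < 0.05,
#' strictly) the MR-PRESSO outlier-corrected estimate is used, otherwise
#' the random-effects IVW estimate.
#'
#' @param results_by_method List with elements `ivw` (random-effects IVW
#'   [mr_estimate()]) and `presso` (a [run_presso()] result or its
#'   corrected [mr_estimate()]; may be `NULL` when fewer than 4
#'   instruments were available).
#' @param heterogeneity A [cochran_q()] result.
#' @return The chosen [mr_estimate()], with attribute `selection` naming
#'   the rule outcome (`"ivw"` or `"presso"`).
#' @export
select_step_estimates <- function(results_by_method, heterogeneity) {
  stopifnot(!is.null(results_by_method$ivw))
  if (heterogeneity$pvalue < 0.05) {
    presso <- results_by_method$presso
    if (is.null(presso))
      stop("heterogeneity detected but no MR-PRESSO estimate available ",
           "(needs >= 4 instruments)")
    est <- if (inherits(presso, "presso_result"))
      presso$estimate_corrected else presso
    attr(est, "selection") <- "presso"
  } else {
    est <- results_by_method$ivw
    attr(est, "selection") <- "ivw"
  }
  est
}
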