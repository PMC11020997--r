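#' Multivariable IVW
#'
#' Estimates each exposure's direct effect conditional on the others by
#' weighted least squares of the outcome effects on the J x K matrix of
#' exposure effects, without intercept, weights `1 / se_Gamma^2`.
#' Standard errors use multiplicative over-dispersion with the residual
#' scale floored at 1; per-exposure p-values are two-sided normal Wald
#' tests. With a single exposure this reduces exactly to univariable IVW
#' (random effects).
#'
#' @param gamma_matrix J x K matrix of per-variant exposure effects
#'   (columns named by exposure).
#' @param se_gamma_matrix Optional J x K matrix of their standard errors
#'   (carried through for reporting; not used by the IVW fit).
#' @param Gamma,se_Gamma Outcome effects and standard errors (length J).
#' @param exposure_names Exposure labels; default the column names.
#' @return Object of class `mvmr_result`: `exposure_names`, `betas`,
#'   `ses`, `pvalues`, `n_snps`, and a `table` data.frame with OR columns.
#' @export
mvmr_ivw <- function(gamma_matrix, se_gamma_matrix = NULL, Gamma, se_Gamma,
                     exposure_names = NULL) {
  X <- as.matrix(gamma_matrix)
  J <- nrow(X); K <- ncol(X)
  exposure_names <- exposure_names %||% colnames(X) %||%
    paste0("exposure", seq_len(K))
  stopifnot(length(Gamma) == J, length(se_Gamma) == J)
  if (J <= K)
    stop("under-identified: need more instruments (", J,
         ") than exposures (", K, ")")
  qrX <- qr(X)
  if (qrX$rank < K) {
    dep <- exposure_names[qrX$pivot[(qrX$rank + 1):K]]
    stop("collinear exposure effect columns: ",
         paste(dep, collapse = ", "))
  }
  w <- 1 / se_Gamma^2
  A <- crossprod(X, w * X)
  betas <- solve(A, crossprod(X, w * Gamma))[, 1]
  resid <- Gamma - X %*% betas
  s <- sqrt(sum(w * resid^2) / (J - K))
  ses <- unname(sqrt(diag(solve(A))) * max(1, s))
  betas <- unname(betas)
  pvals <- .norm_p(betas, ses)
  tab <- data.frame(exposure = exposure_names, beta = betas, se = ses,
                    p = pvals, or = exp(betas),
                    or_low = exp(betas - Z95 * ses),
                    or_high = exp(betas + Z95 * ses),
                    stringsAsFactors = FALSE)
  structure(list(exposure_names = exposure_names, betas = betas,
                 ses = ses, pvalues = pvals, n_snps = J, table = tab),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("Multivariable IVW on", x$n_snps, "instruments\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Build a joint instrument matrix for multivariable MR
#'
#' Forms the union of each exposure's instrument variants, looks up every
#' exposure's effect (and the outcome's, after harmonization to each
#' exposure's effect allele) at the union variants, and returns the
#' matrices [mvmr_ivw()] consumes. In strict mode (default) variants
#' missing an effect for any exposure are excluded; with
#' `impute_missing = TRUE` missing exposure effects are set to 0 and the
#' affected variants flagged.
#'
#' @param exposures Named list of summary-statistics `data.frame`s, one
#'   per exposure (already significance-filtered/clumped as desired).
#' @param exposure_full Optional named list of the exposures' full
#'   (unfiltered) summary statistics used to look up effects at union
#'   variants; defaults to `exposures`.
#' @param outcome Outcome summary-statistics `data.frame`.
#' @param impute_missing Impute missing exposure effects as 0 instead of
#'   excluding the variant.
#' @return List with `gamma_matrix`, `se_gamma_matrix`, `Gamma`,
#'   `se_Gamma`, `variant_ids`, `imputed` (logical matrix of imputations).
#' @export
mvmr_union <- function(exposures, outcome, exposure_full = NULL,
                       impute_missing = FALSE) {
  stopifnot(length(exposures) >= 2, !is.null(names(exposures)))
  exposure_full <- exposure_full %||% exposures
  union_ids <- unique(unlist(lapply(exposures, `[[`, "variant_id")))
  K <- length(exposures)
  # all effects are re-expressed on the OUTCOME's reported effect allele so
  # that the K exposure columns share one orientation per variant
  G <- se_G <- setNames(rep(NA_real_, length(union_ids)), union_ids)
  gm <- sem <- matrix(NA_real_, length(union_ids), K,
                      dimnames = list(union_ids, names(exposures)))
  for (k in seq_len(K)) {
    full_k <- exposure_full[[k]]
    sub <- full_k[full_k$variant_id %in% union_ids, , drop = FALSE]
    h <- harmonize(sub, outcome)
    if (nrow(h$data) == 0) next
    idx <- match(h$data$variant_id, union_ids)
    orig <- outcome$beta[match(h$data$variant_id, outcome$variant_id)]
    # harmonize() aligned the outcome to the exposure's allele; flip the
    # exposure effect back wherever the outcome effect was negated
    s <- ifelse(h$data$beta_outcome == orig, 1, -1)
    gm[idx, k] <- s * h$data$beta_exposure
    sem[idx, k] <- h$data$se_exposure
    G[idx] <- orig
    se_G[idx] <- outcome$se[match(h$data$variant_id, outcome$variant_id)]
  }
  imputed <- is.na(gm) & !is.na(G)
  if (impute_missing) {
    gm[imputed] <- 0
    sem[imputed] <- Inf
  }
  keep <- !is.na(G) & rowSums(is.na(gm)) == 0
  list(gamma_matrix = gm[keep, , drop = FALSE],
       se_gamma_matrix = sem[keep, , drop = FALSE],
       Gamma = unname(G[keep]), se_Gamma = unname(se_G[keep]),
       variant_ids = union_ids[keep],
       imputed = imputed[keep, , drop = FALSE])
}
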