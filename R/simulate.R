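#' Simulation configuration
#'
#' Study conditions for the synthetic GWAS summary-statistics generator.
#' The defaults emulate the motivating setting: a microbiome-scale
#' exposure GWAS (n = 18,473), a case-control outcome GWAS (8,288 cases,
#' 68,969 controls) and a large lipid-scale mediator GWAS (n = 441,016),
#' with instruments drawn to pass the exposure significance threshold
#' (p < 1e-5) and three mutually non-overlapping samples.
#'
#' @param J Number of instruments (at least 4).
#' @param n_exp,n_med,n_out Sample sizes of the exposure, mediator and
#'   outcome GWAS.
#' @param case_fraction Outcome case fraction for the log-odds variance
#'   approximation; `NULL` for a continuous outcome.
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param theta True causal effect(s); a vector of length K for the
#'   multivariable generator.
#' @param gamma_sd Spread of true instrument-exposure effects (drawn as
#'   `|N(0, gamma_sd^2)|`, effect-allele oriented).
#' @param p_threshold Exposure significance threshold instruments must
#'   pass (default 1e-5).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-variant direct
#'   (pleiotropic) outcome effects; mean 0 is balanced, nonzero is
#'   directional.
#' @param outlier_count,outlier_offset Number of variants whose observed
#'   outcome effect is shifted, and the shift in `se_Gamma` units.
#' @param mediation List `beta1` (exposure -> mediator), `beta2`
#'   (mediator -> outcome), `direct` (direct exposure -> outcome),
#'   `J_med` (mediator's own instrument count) and `p_threshold_med`
#'   (mediator instrument threshold, default 5e-8).
#' @param K,rho Number of correlated risk factors and their effect
#'   correlation (multivariable generator).
#' @param seed RNG seed; all randomness in a simulation flows from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(J = 20, n_exp = 18473, n_med = 441016,
                       n_out = 77257, case_fraction = 8288 / 77257,
                       maf_range = c(0.05, 0.5), theta = 0.1,
                       gamma_sd = 0.05, p_threshold = 1e-5,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       outlier_count = 0, outlier_offset = 0,
                       mediation = list(beta1 = 0.2, beta2 = 0.3,
                                        direct = 0.1, J_med = 50,
                                        p_threshold_med = 5e-8),
                       K = 3, rho = 0.7, seed = 1) {
  stopifnot(J >= 4, n_exp > 0, n_med > 0, n_out > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(J = J, n_exp = n_exp, n_med = n_med, n_out = n_out,
                 case_fraction = case_fraction, maf_range = maf_range,
                 theta = theta, gamma_sd = gamma_sd,
                 p_threshold = p_threshold,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 outlier_count = outlier_count,
                 outlier_offset = outlier_offset, mediation = mediation,
                 K = K, rho = rho, seed = seed),
            class = "sim_config")
}

# per-variant SE of a GWAS effect under the standard approximations:
# 1 / sqrt(2 maf (1 - maf) n) for a standardized continuous trait,
# additionally scaled by the case-control variance factor phi (1 - phi)
# for a binary (log-odds) trait
.gwas_se <- function(maf, n, case_fraction = NULL) {
  v <- if (is.null(case_fraction)) 1 else case_fraction * (1 - case_fraction)
  1 / sqrt(2 * maf * (1 - maf) * n * v)
}

# draw true effects |N(0, sd^2)| and observed effects N(true, se) such
# that BOTH the implied true and the observed p-values pass `p_thr`
.draw_instrument_effects <- function(J, se, sd, p_thr) {
  z_min <- qnorm(p_thr / 2, lower.tail = FALSE)
  true <- abs(rnorm(J, 0, sd))
  redo <- true / se < z_min
  while (any(redo)) {
    true[redo] <- abs(rnorm(sum(redo), 0, sd))
    redo <- true / se < z_min
  }
  obs <- rnorm(J, true, se)
  redo <- abs(obs) / se < z_min
  while (any(redo)) {
    obs[redo] <- rnorm(sum(redo), true[redo], se[redo])
    redo <- abs(obs) / se < z_min
  }
  list(true = true, obs = obs)
}

# assemble a summary-record data.frame in the dialect read_gwas_table emits
.sum_records <- function(ids, maf, beta, se, n, pos_offset = 0) {
  data.frame(variant_id = ids, chrom = "1",
             pos = pos_offset + seq_along(ids) * 1e6,
             effect_allele = "A", other_allele = "G", eaf = maf,
             beta = beta, se = se, pvalue = .norm_p(beta, se),
             n = n, stringsAsFactors = FALSE)
}

#' Simulate a two-sample exposure-outcome GWAS pair
#'
#' Generates summary statistics directly on the summary-statistic scale
#' (no individual-level genotypes): minor-allele frequencies uniform in
#' `maf_range`; true instrument effects `|N(0, gamma_sd^2)|` redrawn
#' until both the implied and the observed exposure p-values pass the
#' instrument threshold (so generated sets always survive significance
#' filtering); per-variant pleiotropic effects `N(mu_alpha, tau_alpha^2)`;
#' outcome effects `theta gamma_j + alpha_j` observed with independent
#' noise (two-sample design, no overlap). Optionally the observed outcome
#' effects of `outlier_count` randomly chosen variants are shifted by
#' `outlier_offset` outcome-SE units.
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` summary-record data.frames
#'   and a `truth` list (`theta`, true `gamma`, `alpha`, `outlier_idx`,
#'   seed).
#' @export
simulate_two_sample <- function(config = sim_config()) {
  set.seed(config$seed)
  J <- config$J
  maf <- runif(J, config$maf_range[1], config$maf_range[2])
  se_g <- .gwas_se(maf, config$n_exp)
  eff <- .draw_instrument_effects(J, se_g, config$gamma_sd,
                                  config$p_threshold)
  alpha <- rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd)
  se_G <- .gwas_se(maf, config$n_out, config$case_fraction)
  Gamma_true <- config$theta[1] * eff$true + alpha
  Gamma_obs <- rnorm(J, Gamma_true, se_G)
  outlier_idx <- integer(0)
  if (config$outlier_count > 0) {
    outlier_idx <- sort(sample.int(J, config$outlier_count))
    Gamma_obs[outlier_idx] <- Gamma_obs[outlier_idx] +
      config$outlier_offset * se_G[outlier_idx]
  }
  ids <- paste0("rs", seq_len(J))
  list(exposure = .sum_records(ids, maf, eff$obs, se_g, config$n_exp),
       outcome = .sum_records(ids, maf, Gamma_obs, se_G, config$n_out),
       truth = list(theta = config$theta[1], gamma = eff$true,
                    alpha = alpha, outlier_idx = outlier_idx,
                    seed = config$seed))
}

#' Simulate an exposure-mediator-outcome summary-statistics triplet
#'
#' Path model for two-step mediation: over the exposure's instruments,
#' mediator effects are `beta1 gamma_j` plus mediator-sample noise and
#' outcome effects are `(direct + beta1 beta2) gamma_j` plus pleiotropy
#' and outcome-sample noise (three non-overlapping samples). A separate
#' set of `J_med` instruments for the mediator itself (significant at the
#' genome-wide threshold in the larger mediator GWAS) carries outcome
#' effects `beta2 delta_j` plus noise, for estimating the
#' mediator -> outcome leg.
#'
#' @param config A [sim_config()] with its `mediation` block set.
#' @return List with `exposure`, `mediator`, `outcome` (the exposure's
#'   instruments seen in each GWAS), `mediator_instruments` (list
#'   `mediator`, `outcome`) and `truth` (`beta1`, `beta2`, `direct`,
#'   `total`, `proportion`).
#' @export
simulate_mediation_triplet <- function(config = sim_config()) {
  set.seed(config$seed)
  med <- config$mediation
  J <- config$J
  total <- med$direct + med$beta1 * med$beta2

  maf <- runif(J, config$maf_range[1], config$maf_range[2])
  se_g <- .gwas_se(maf, config$n_exp)
  eff <- .draw_instrument_effects(J, se_g, config$gamma_sd,
                                  config$p_threshold)
  alpha <- rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd)
  se_m <- .gwas_se(maf, config$n_med)
  m_obs <- rnorm(J, med$beta1 * eff$true, se_m)
  se_y <- .gwas_se(maf, config$n_out, config$case_fraction)
  y_obs <- rnorm(J, total * eff$true + alpha, se_y)
  ids <- paste0("rsE", seq_len(J))

  J2 <- med$J_med %||% 50
  p2 <- med$p_threshold_med %||% 5e-8
  maf2 <- runif(J2, config$maf_range[1], config$maf_range[2])
  se_d <- .gwas_se(maf2, config$n_med)
  delta <- .draw_instrument_effects(J2, se_d, config$gamma_sd, p2)
  se_y2 <- .gwas_se(maf2, config$n_out, config$case_fraction)
  y2_obs <- rnorm(J2, med$beta2 * delta$true, se_y2)
  ids2 <- paste0("rsM", seq_len(J2))

  list(exposure = .sum_records(ids, maf, eff$obs, se_g, config$n_exp),
       mediator = .sum_records(ids, maf, m_obs, se_m, config$n_med),
       outcome = .sum_records(ids, maf, y_obs, se_y, config$n_out),
       mediator_instruments = list(
         mediator = .sum_records(ids2, maf2, delta$obs, se_d,
                                 config$n_med, pos_offset = 1e8),
         outcome = .sum_records(ids2, maf2, y2_obs, se_y2,
                                config$n_out, pos_offset = 1e8)),
       truth = list(beta1 = med$beta1, beta2 = med$beta2,
                    direct = med$direct, total = total,
                    proportion = med$beta1 * med$beta2 / total,
                    gamma = eff$true, delta = delta$true,
                    seed = config$seed))
}

#' Simulate correlated multi-factor exposure effects for MR-BMA / MVMR
#'
#' Per-variant effects on K candidate risk factors are drawn from a
#' K-variate normal with common correlation `rho` (emulating a panel of
#' strongly correlated lipid traits); each variant is redrawn until it is
#' a genome-scale instrument for at least one factor. The outcome is
#' built from the designated true causal factors:
#' `Gamma_j = sum_k theta_k gamma_jk` plus case-control noise.
#'
#' @param config A [sim_config()]; `theta` is recycled to length `K`.
#' @return List with `gamma_matrix`, `se_gamma_matrix` (J x K), `Gamma`,
#'   `se_Gamma`, `outcome` records and `truth` (`theta`, true effects).
#' @export
simulate_multivariable <- function(config = sim_config()) {
  set.seed(config$seed)
  J <- config$J; K <- config$K; rho <- config$rho
  stopifnot(K >= 2, abs(rho) < 1)
  theta <- rep_len(config$theta, K)
  R <- matrix(rho, K, K); diag(R) <- 1
  L <- chol(config$gamma_sd^2 * R)

  maf <- runif(J, config$maf_range[1], config$maf_range[2])
  se_g <- .gwas_se(maf, config$n_exp)
  z_min <- qnorm(config$p_threshold / 2, lower.tail = FALSE)
  draw_rows <- function(n) matrix(rnorm(n * K), n, K) %*% L
  gm_true <- draw_rows(J)
  redo <- apply(abs(gm_true) / se_g, 1, max) < z_min
  while (any(redo)) {
    gm_true[redo, ] <- draw_rows(sum(redo))
    redo <- apply(abs(gm_true) / se_g, 1, max) < z_min
  }
  se_gm <- matrix(se_g, J, K)
  gm_obs <- gm_true + matrix(rnorm(J * K), J, K) * se_gm

  se_G <- .gwas_se(maf, config$n_out, config$case_fraction)
  Gamma_true <- as.vector(gm_true %*% theta)
  Gamma_obs <- rnorm(J, Gamma_true, se_G)

  ids <- paste0("rs", seq_len(J))
  factors <- paste0("factor", seq_len(K))
  dimnames(gm_obs) <- dimnames(se_gm) <- list(ids, factors)
  list(gamma_matrix = gm_obs, se_gamma_matrix = se_gm,
       Gamma = Gamma_obs, se_Gamma = se_G,
       outcome = .sum_records(ids, maf, Gamma_obs, se_G, config$n_out),
       truth = list(theta = setNames(theta, factors),
                    gamma_true = gm_true, seed = config$seed))
}

#' Write simulated summary statistics to disk
#'
#' Writes each summary-record table as TSV (the dialect
#' [read_gwas_table()] reads) and the truth record as a YAML sidecar.
#'
#' @param sim Output of one of the `simulate_*` generators.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flatten <- function(x, prefix = "") {
    for (nm in names(x)) {
      el <- x[[nm]]
      path_nm <- if (nzchar(prefix)) paste0(prefix, "_", nm) else nm
      if (is.data.frame(el)) {
        write.table(el, file.path(dir, paste0(path_nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      } else if (is.list(el) && nm != "truth") {
        flatten(el, path_nm)
      }
    }
  }
  flatten(sim[setdiff(names(sim), "truth")])
  truth <- lapply(sim$truth, function(v)
    if (is.matrix(v)) as.vector(v) else unname(v))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
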