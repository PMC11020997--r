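#' Pipeline run configuration
#'
#' Collects inputs and thresholds for the two-stage analysis. Exposure,
#' outcome and mediator inputs may be summary-record `data.frame`s (as
#' returned by [read_gwas_table()] or the simulators) or file paths,
#' which are read with `column_map`. File inputs are checked up front so
#' a missing file is a configuration error raised before any computation.
#'
#' @param exposures Named list of exposure summary statistics.
#' @param outcome Outcome summary statistics.
#' @param mediators Named list of mediator summary statistics (Stage II).
#' @param column_map Column mapping for file inputs
#'   (see [read_gwas_table()]).
#' @param ld Optional [ld_info()] for clumping.
#' @param exposure_p,reverse_p,mediator_p Instrument thresholds: 1e-5 for
#'   exposures, genome-wide 5e-8 for the reverse direction and for
#'   mediators.
#' @param r2_threshold,window_kb Clumping parameters.
#' @param palindrome_maf Palindrome MAF cutoff for harmonization.
#' @param f_min Weak-instrument F cutoff.
#' @param binary_outcome Declare the outcome binary (odds-ratio
#'   reporting); never inferred from the data.
#' @param detect_p Detection threshold on the primary (random-effects
#'   IVW) p-value; default 0.05, uncorrected.
#' @param fdr_across_exposures Additionally report BH-FDR-adjusted
#'   detection across exposures.
#' @param n_boot Bootstrap replicates for median/mode estimators (0
#'   skips their standard errors).
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param bma MR-BMA settings, a [bma_config()].
#' @param seed Seed driving every stochastic component.
#' @return List of class `run_config`.
#' @export
run_config <- function(exposures, outcome, mediators = list(),
                       column_map = NULL, ld = NULL,
                       exposure_p = 1e-5, reverse_p = 5e-8,
                       mediator_p = 5e-8, r2_threshold = 0.001,
                       window_kb = 10000, palindrome_maf = 0.42,
                       f_min = 10, binary_outcome = TRUE,
                       detect_p = 0.05, fdr_across_exposures = FALSE,
                       n_boot = 1000, presso_n_sim = 1000,
                       bma = bma_config(), seed = 1) {
  stopifnot(exposure_p > 0, exposure_p < 1, reverse_p > 0, reverse_p < 1,
            mediator_p > 0, mediator_p < 1, r2_threshold > 0,
            palindrome_maf >= 0, palindrome_maf <= 0.5)
  load_one <- function(x, what) {
    if (is.character(x)) {
      if (!file.exists(x))
        stop("configuration error: ", what, " file not found: ", x)
      if (is.null(column_map))
        stop("configuration error: column_map required for file inputs")
      read_gwas_table(x, column_map)
    } else {
      stopifnot(is.data.frame(x))
      x
    }
  }
  if (is.data.frame(exposures)) exposures <- list(exposure = exposures)
  exp_names <- names(exposures) %||%
    sprintf("exposure%d", seq_along(exposures))
  exposures <- lapply(seq_along(exposures), function(i)
    load_one(exposures[[i]], paste0("exposure '", exp_names[i], "'")))
  names(exposures) <- exp_names
  outcome <- load_one(outcome, "outcome")
  med_names <- names(mediators) %||%
    sprintf("mediator%d", seq_along(mediators))
  mediators <- lapply(seq_along(mediators), function(i)
    load_one(mediators[[i]], paste0("mediator '", med_names[i], "'")))
  names(mediators) <- med_names
  structure(list(exposures = exposures, outcome = outcome,
                 mediators = mediators, ld = ld, exposure_p = exposure_p,
                 reverse_p = reverse_p, mediator_p = mediator_p,
                 r2_threshold = r2_threshold, window_kb = window_kb,
                 palindrome_maf = palindrome_maf, f_min = f_min,
                 binary_outcome = binary_outcome, detect_p = detect_p,
                 fdr_across_exposures = fdr_across_exposures,
                 n_boot = n_boot, presso_n_sim = presso_n_sim,
                 bma = bma, seed = seed),
            class = "run_config")
}

#' Univariable MR of one exposure on one outcome
#'
#' The full per-pair workflow: instrument selection (strict p-value
#' filter, greedy clumping, F screen), harmonization, the estimator
#' suite, and sensitivity diagnostics (Cochran's Q; Egger intercept and
#' leave-one-out with at least 3 instruments; MR-PRESSO when Q signals
#' heterogeneity at p < 0.05 and at least 4 instruments remain). With a
#' single surviving instrument the causal estimate degenerates to the
#' Wald ratio; with none, or when harmonization leaves fewer than the
#' estimators need, the pair is reported as having insufficient
#' instruments rather than failing.
#'
#' @param exposure,outcome Summary-statistics `data.frame`s.
#' @param config A [run_config()] supplying thresholds (its exposure
#'   lists are ignored here).
#' @param p_threshold Instrument threshold for this pair; defaults to
#'   `config$exposure_p`.
#' @param exposure_name,outcome_name Labels.
#' @return List of class `mr_result`: `instruments`, `hset`, `estimates`
#'   (data.frame), `heterogeneity`, `egger_intercept`, `loo`, `presso`,
#'   `detected`, `status`.
#' @export
mr_univariable <- function(exposure, outcome, config,
                           p_threshold = NULL,
                           exposure_name = "exposure",
                           outcome_name = "outcome") {
  p_threshold <- p_threshold %||% config$exposure_p
  iv <- select_instruments(exposure, p_threshold = p_threshold,
                           ld = config$ld,
                           r2_threshold = config$r2_threshold,
                           window_kb = config$window_kb,
                           f_min = config$f_min,
                           trait_name = exposure_name)
  res <- list(exposure_name = exposure_name, outcome_name = outcome_name,
              instruments = iv, hset = NULL, estimates = NULL,
              heterogeneity = NULL, egger_intercept = NULL, loo = NULL,
              presso = NULL, detected = FALSE, status = "ok")
  hset <- harmonize(iv$records, outcome,
                    palindrome_maf_cutoff = config$palindrome_maf,
                    exposure_name = exposure_name,
                    outcome_name = outcome_name)
  res$hset <- hset
  J <- nrow(hset$data)
  if (J < 2) {
    res$status <- "insufficient_instruments"
    if (J == 1) {
      d <- hset$data
      est <- wald_ratio(d$beta_exposure, d$se_exposure,
                        d$beta_outcome, d$se_outcome)
      res$estimates <- as.data.frame(est)
    }
    return(structure(res, class = "mr_result"))
  }
  res$estimates <- mr_all_methods(hset, n_boot = config$n_boot,
                                  seed = config$seed)
  res$heterogeneity <- cochran_q(hset)
  if (J >= 3) {
    res$egger_intercept <- egger_intercept_test(hset)
    res$loo <- leave_one_out(hset)
  }
  if (res$heterogeneity$pvalue < 0.05 && J >= 4) {
    res$presso <- run_presso(hset, n_sim = config$presso_n_sim,
                             seed = config$seed)
  }
  ivw_p <- res$estimates$pvalue[res$estimates$method == "ivw_random"]
  res$detected <- length(ivw_p) == 1 && ivw_p < config$detect_p
  structure(res, class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR: %s -> %s [%s]%s\n", x$exposure_name, x$outcome_name,
              x$status, if (isTRUE(x$detected)) " DETECTED" else ""))
  if (!is.null(x$estimates))
    print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Stage I: bidirectional univariable MR and multivariable follow-up
#'
#' For every exposure: instrument selection at the exposure threshold,
#' harmonization, the five-estimator suite and sensitivity diagnostics.
#' Exposures whose random-effects IVW p-value falls below the detection
#' threshold are flagged; for each, a reverse-direction MR
#' (outcome -> exposure, instruments at the genome-wide threshold) probes
#' reverse causation, and all detected exposures enter a joint
#' multivariable IVW for their direct effects.
#'
#' @param config A [run_config()].
#' @return List of class `mr_stage1`: `results` (per exposure),
#'   `detected` (names), `reverse` (per detected exposure), `mvmr`,
#'   `fdr` (optional BH-adjusted detection table).
#' @export
run_stage1 <- function(config) {
  results <- lapply(names(config$exposures), function(nm) {
    mr_univariable(config$exposures[[nm]], config$outcome, config,
                   p_threshold = config$exposure_p, exposure_name = nm,
                   outcome_name = "outcome")
  })
  names(results) <- names(config$exposures)
  detected <- names(results)[vapply(results, function(r)
    isTRUE(r$detected), logical(1))]

  fdr_tab <- NULL
  if (config$fdr_across_exposures) {
    ps <- vapply(results, function(r) {
      p <- r$estimates$pvalue[r$estimates$method == "ivw_random"]
      if (length(p) == 1) p else NA_real_
    }, numeric(1))
    ok <- !is.na(ps)
    fdr_tab <- data.frame(exposure = names(results)[ok], pvalue = ps[ok],
                          fdr = bh_fdr(ps[ok]), stringsAsFactors = FALSE)
  }

  reverse <- lapply(detected, function(nm) {
    mr_univariable(config$outcome, config$exposures[[nm]], config,
                   p_threshold = config$reverse_p,
                   exposure_name = "outcome", outcome_name = nm)
  })
  names(reverse) <- detected

  mvmr <- NULL
  if (length(detected) >= 2) {
    insets <- lapply(detected, function(nm)
      results[[nm]]$instruments$records)
    names(insets) <- detected
    un <- mvmr_union(insets, config$outcome,
                     exposure_full = config$exposures[detected])
    if (nrow(un$gamma_matrix) > length(detected)) {
      mvmr <- mvmr_ivw(un$gamma_matrix, un$se_gamma_matrix,
                       un$Gamma, un$se_Gamma, exposure_names = detected)
    }
  }
  structure(list(results = results, detected = detected,
                 reverse = reverse, mvmr = mvmr, fdr = fdr_tab,
                 config = config),
            class = "mr_stage1")
}

#' Stage II: mediator prioritization and two-step mediation
#'
#' Step 1: univariable MR of every mediator on the outcome (instruments
#' at the genome-wide threshold); mediators detected at the nominal
#' threshold are prioritized with MR-BMA (after a single
#' outlier/influence filtering pass), with permutation p-values and
#' BH-FDR adjustment. Step 2: univariable MR of each detected exposure
#' on each prioritized mediator. For every exposure-mediator pair with
#' both legs detected, the mediation coefficients are chosen by the
#' heterogeneity rule (MR-PRESSO-corrected when Cochran's Q p < 0.05,
#' otherwise random-effects IVW) and combined with
#' [two_step_mediation()].
#'
#' @param config A [run_config()] with `mediators` set.
#' @param stage1 The [run_stage1()] bundle; must contain at least one
#'   detected exposure.
#' @return List of class `mr_stage2`: `mediator_mr` (step 1 results),
#'   `bma` (list `fit`, `permutation_p`, `fdr_p`, `excluded`),
#'   `prioritized` (mediator names), `step2` (exposure-on-mediator
#'   results), `mediation` (data.frame of mediation results per pair, or
#'   a `"no mediation pathway"` message).
#' @export
run_stage2 <- function(config, stage1) {
  stopifnot(inherits(stage1, "mr_stage1"))
  if (length(stage1$detected) == 0)
    stop("stage 1 detected no exposures; nothing to mediate")
  if (length(config$mediators) == 0)
    stop("configuration error: no mediators supplied")

  # step 1: mediator -> outcome
  mediator_mr <- lapply(names(config$mediators), function(nm) {
    mr_univariable(config$mediators[[nm]], config$outcome, config,
                   p_threshold = config$mediator_p, exposure_name = nm,
                   outcome_name = "outcome")
  })
  names(mediator_mr) <- names(config$mediators)
  det_med <- names(mediator_mr)[vapply(mediator_mr, function(r)
    isTRUE(r$detected), logical(1))]

  bma_out <- NULL
  prioritized <- det_med
  if (length(det_med) >= 2) {
    insets <- lapply(det_med, function(nm)
      mediator_mr[[nm]]$instruments$records)
    names(insets) <- det_med
    un <- mvmr_union(insets, config$outcome,
                     exposure_full = config$mediators[det_med])
    cfg <- config$bma
    cfg$seed <- cfg$seed %||% config$seed
    filt <- bma_influence_filter(un$gamma_matrix, un$Gamma, un$se_Gamma,
                                 config = cfg)
    perm_p <- bma_permutation_p(filt$gamma_matrix, filt$Gamma,
                                filt$se_Gamma, config = cfg)
    fdr_p <- setNames(bh_fdr(as.vector(perm_p)), names(perm_p))
    bma_out <- list(fit = filt$fit, permutation_p = perm_p,
                    fdr_p = fdr_p, excluded = filt$excluded_variants)
    prioritized <- names(fdr_p)[fdr_p < 0.05]
  }

  # step 2: detected exposure -> prioritized mediator
  step2 <- list()
  mediation_rows <- list()
  for (ex in stage1$detected) {
    for (md in prioritized) {
      leg1 <- mr_univariable(config$exposures[[ex]],
                             config$mediators[[md]], config,
                             p_threshold = config$exposure_p,
                             exposure_name = ex, outcome_name = md)
      step2[[paste(ex, md, sep = "->")]] <- leg1
      if (!isTRUE(leg1$detected)) next

      pick <- function(res) {
        ivw_row <- res$estimates[res$estimates$method == "ivw_random", ]
        est <- mr_estimate("ivw_random", ivw_row$beta, ivw_row$se,
                           ivw_row$nsnp)
        select_step_estimates(list(ivw = est, presso = res$presso),
                              res$heterogeneity)
      }
      e1 <- pick(leg1)
      e2 <- pick(mediator_mr[[md]])
      e3 <- pick(stage1$results[[ex]])
      m <- two_step_mediation(e1$beta, e1$se, e2$beta, e2$se,
                              e3$beta, e3$se)
      mediation_rows[[paste(ex, md, sep = "->")]] <- data.frame(
        exposure = ex, mediator = md,
        beta1 = m$beta1, se1 = m$se1, source1 = attr(e1, "selection"),
        beta2 = m$beta2, se2 = m$se2, source2 = attr(e2, "selection"),
        beta3 = m$beta3, se3 = m$se3, source3 = attr(e3, "selection"),
        indirect = m$indirect, se_indirect = m$se_indirect,
        pvalue = m$pvalue, proportion = m$proportion,
        prop_ci_low = m$prop_ci_low, prop_ci_high = m$prop_ci_high,
        stringsAsFactors = FALSE)
    }
  }
  mediation <- if (length(mediation_rows) > 0) {
    do.call(rbind, mediation_rows)
  } else {
    "no mediation pathway"
  }
  structure(list(mediator_mr = mediator_mr, bma = bma_out,
                 prioritized = prioritized, step2 = step2,
                 mediation = mediation),
            class = "mr_stage2")
}

#' Write report tables for a pipeline run
#'
#' Emits the plot-ready data tables: a forest table (odds ratio and CI
#' per exposure and method), per-exposure scatter data (instrument
#' exposure/outcome effects with each method's fitted line),
#' leave-one-out tables, and, when Stage II ran, the mediation report.
#' Tables are plain TSV so a re-render from the same bundle is
#' byte-identical.
#'
#' @param stage1 A [run_stage1()] bundle.
#' @param dir Output directory.
#' @param stage2 Optional [run_stage2()] bundle.
#' @return Character vector of written file paths, invisibly.
#' @export
render_reports <- function(stage1, dir, stage2 = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }

  forest <- do.call(rbind, lapply(names(stage1$results), function(nm) {
    est <- stage1$results[[nm]]$estimates
    if (is.null(est)) return(NULL)
    cbind(exposure = nm, est)
  }))
  if (!is.null(forest)) wt(forest, "forest.tsv")

  scatter <- do.call(rbind, lapply(names(stage1$results), function(nm) {
    h <- stage1$results[[nm]]$hset
    if (is.null(h) || nrow(h$data) == 0) return(NULL)
    cbind(exposure = nm, h$data[, c("variant_id", "beta_exposure",
                                    "se_exposure", "beta_outcome",
                                    "se_outcome")])
  }))
  if (!is.null(scatter)) wt(scatter, "scatter.tsv")

  fits <- do.call(rbind, lapply(names(stage1$results), function(nm) {
    est <- stage1$results[[nm]]$estimates
    if (is.null(est)) return(NULL)
    icpt <- stage1$results[[nm]]$egger_intercept
    data.frame(exposure = nm, method = est$method, slope = est$beta,
               intercept = ifelse(est$method == "egger",
                                  icpt$intercept %||% 0, 0))
  }))
  if (!is.null(fits)) wt(fits, "scatter_fits.tsv")

  loo <- do.call(rbind, lapply(names(stage1$results), function(nm) {
    l <- stage1$results[[nm]]$loo
    if (is.null(l)) return(NULL)
    cbind(exposure = nm, l)
  }))
  if (!is.null(loo)) wt(loo, "leave_one_out.tsv")

  diag <- do.call(rbind, lapply(names(stage1$results), function(nm) {
    r <- stage1$results[[nm]]
    data.frame(
      exposure = nm, status = r$status,
      Q = r$heterogeneity$Q %||% NA_real_,
      Q_df = r$heterogeneity$df %||% NA_integer_,
      Q_p = r$heterogeneity$pvalue %||% NA_real_,
      egger_intercept = r$egger_intercept$intercept %||% NA_real_,
      intercept_p = r$egger_intercept$pvalue %||% NA_real_,
      presso_global_p = r$presso$global_p %||% NA_real_,
      n_outliers = length(r$presso$outlier_indices %||% integer(0)),
      stringsAsFactors = FALSE)
  }))
  wt(diag, "diagnostics.tsv")

  if (!is.null(stage1$mvmr)) wt(stage1$mvmr$table, "mvmr.tsv")

  if (!is.null(stage2)) {
    if (is.data.frame(stage2$mediation)) {
      wt(stage2$mediation, "mediation.tsv")
    } else {
      writeLines(stage2$mediation, file.path(dir, "mediation.tsv"))
      written <- c(written, file.path(dir, "mediation.tsv"))
    }
    if (!is.null(stage2$bma)) {
      wt(stage2$bma$fit$models, "bma_models.tsv")
      wt(data.frame(factor = names(stage2$bma$fit$mip),
                    MIP = as.vector(stage2$bma$fit$mip),
                    MACE = as.vector(stage2$bma$fit$mace),
                    empirical_p = as.vector(stage2$bma$permutation_p),
                    fdr_p = as.vector(stage2$bma$fdr_p)),
         "bma_factors.tsv")
    }
  }
  invisible(written)
}
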