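.COMP <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) .COMP[[ea]] == oa

#' Construct a harmonized exposure-outcome set
#'
#' Container for variant-aligned effect pairs used by every estimator.
#' Usually produced by [harmonize()]; building one directly is useful for
#' simulations and tests.
#'
#' @param data `data.frame` with at least `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`; optionally `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `eaf_outcome`.
#' @param dropped `data.frame` (`variant_id`, `reason`) of excluded
#'   variants.
#' @param exposure_name,outcome_name Trait labels.
#' @return Object of class `harmonized_set`.
#' @export
harmonized_set <- function(data, dropped = NULL, exposure_name = "exposure",
                           outcome_name = "outcome") {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  stopifnot(all(need %in% names(data)))
  if (!"variant_id" %in% names(data))
    data$variant_id <- paste0("v", seq_len(nrow(data)))
  stopifnot(all(data$se_exposure > 0), all(data$se_outcome > 0))
  dropped <- dropped %||% data.frame(variant_id = character(),
                                     reason = character(),
                                     stringsAsFactors = FALSE)
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 data = data, dropped = dropped),
            class = "harmonized_set")
}

# coerce a harmonized_set or bare data.frame to the effect-pair data.frame
.hdata <- function(x) {
  d <- if (inherits(x, "harmonized_set")) x$data else x
  stopifnot(is.data.frame(d),
            all(c("beta_exposure", "se_exposure",
                  "beta_outcome", "se_outcome") %in% names(d)))
  d
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set:", x$exposure_name, "->", x$outcome_name, "\n")
  cat("  retained:", nrow(x$data), " dropped:", nrow(x$dropped), "\n")
  if (nrow(x$dropped) > 0)
    print(table(x$dropped$reason))
  invisible(x)
}

# resolve duplicate variant ids within one trait: keep lowest p
.dedupe <- function(records) {
  dup_log <- data.frame(variant_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(records$variant_id)) {
    ord <- order(records$pvalue)
    rec <- records[ord, , drop = FALSE]
    dups <- duplicated(rec$variant_id)
    dup_log <- data.frame(variant_id = rec$variant_id[dups],
                          reason = "duplicate", stringsAsFactors = FALSE)
    records <- rec[!dups, , drop = FALSE]
  }
  list(records = records, log = dup_log)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele for every shared
#' variant, handling the eight allele-orientation cases: identical alleles
#' (kept as-is), swapped alleles (outcome beta negated, outcome frequency
#' flipped to 1 - eaf), strand complements (mapped to complements first),
#' and complement-swaps. Palindromic variants (A/T or C/G), whose strand
#' cannot be resolved from alleles alone, are aligned by allele-frequency
#' concordance: when exposure and outcome effect-allele frequencies lie on
#' the same side of 0.5 the orientation is taken as concordant, otherwise
#' the outcome effect is flipped. Palindromic variants with intermediate
#' minor-allele frequency — `min(eaf, 1 - eaf) > palindrome_maf_cutoff` on
#' either side — or with a missing frequency are dropped, because the
#' frequency rule cannot resolve them. Every exclusion is logged with a
#' reason (`not_in_outcome`, `palindromic_high_maf`, `allele_mismatch`,
#' `duplicate`); nothing is dropped silently.
#'
#' @param exposure,outcome Summary-statistics `data.frame`s as returned by
#'   [read_gwas_table()].
#' @param palindrome_maf_cutoff MAF above which palindromic variants are
#'   considered unresolvable; default 0.42.
#' @param exposure_name,outcome_name Trait labels.
#' @return A [harmonized_set()] whose `data` holds columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`,
#'   `pvalue_exposure`, `pvalue_outcome`.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_cutoff = 0.42,
                      exposure_name = "exposure", outcome_name = "outcome") {
  de <- .dedupe(exposure); do_ <- .dedupe(outcome)
  exposure <- de$records; outcome <- do_$records
  dropped <- rbind(de$log, do_$log)

  out_idx <- match(exposure$variant_id, outcome$variant_id)
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    vid <- exposure$variant_id[i]
    j <- out_idx[i]
    if (is.na(j)) {
      dropped <- rbind(dropped, data.frame(variant_id = vid,
                                           reason = "not_in_outcome"))
      next
    }
    ea <- exposure$effect_allele[i]; oa <- exposure$other_allele[i]
    ea_o <- outcome$effect_allele[j]; oa_o <- outcome$other_allele[j]
    beta_o <- outcome$beta[j]; eaf_o <- outcome$eaf[j]
    eaf_e <- exposure$eaf[i]

    if (.is_palindromic(ea, oa)) {
      # A/T or C/G: strand is ambiguous; resolve by frequency concordance
      if (!setequal(c(ea_o, oa_o), c(ea, oa))) {
        dropped <- rbind(dropped, data.frame(variant_id = vid,
                                             reason = "allele_mismatch"))
        next
      }
      maf_e <- if (is.na(eaf_e)) NA_real_ else min(eaf_e, 1 - eaf_e)
      maf_o <- if (is.na(eaf_o)) NA_real_ else min(eaf_o, 1 - eaf_o)
      if (is.na(maf_e) || is.na(maf_o) ||
          maf_e > palindrome_maf_cutoff || maf_o > palindrome_maf_cutoff) {
        dropped <- rbind(dropped, data.frame(variant_id = vid,
                                             reason = "palindromic_high_maf"))
        next
      }
      same_side <- (eaf_e < 0.5) == (eaf_o < 0.5)
      if (!same_side) {
        beta_o <- -beta_o
        eaf_o <- 1 - eaf_o
      }
    } else {
      # map the outcome's alleles to this strand if they are complements
      if (ea_o %in% c(.COMP[[ea]], .COMP[[oa]]) &&
          !(ea_o %in% c(ea, oa))) {
        ea_o <- .COMP[[ea_o]]; oa_o <- .COMP[[oa_o]]
      }
      if (ea_o == ea && oa_o == oa) {
        # aligned
      } else if (ea_o == oa && oa_o == ea) {
        beta_o <- -beta_o
        if (!is.na(eaf_o)) eaf_o <- 1 - eaf_o
      } else {
        dropped <- rbind(dropped, data.frame(variant_id = vid,
                                             reason = "allele_mismatch"))
        next
      }
    }
    rows[[i]] <- data.frame(
      variant_id = vid, effect_allele = ea, other_allele = oa,
      eaf = eaf_e, beta_exposure = exposure$beta[i],
      se_exposure = exposure$se[i], beta_outcome = beta_o,
      se_outcome = outcome$se[j], eaf_outcome = eaf_o,
      pvalue_exposure = exposure$pvalue[i],
      pvalue_outcome = outcome$pvalue[j], stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(data)) {
    data <- data.frame(variant_id = character(), effect_allele = character(),
                       other_allele = character(), eaf = numeric(),
                       beta_exposure = numeric(), se_exposure = numeric(),
                       beta_outcome = numeric(), se_outcome = numeric(),
                       eaf_outcome = numeric(), pvalue_exposure = numeric(),
                       pvalue_outcome = numeric(), stringsAsFactors = FALSE)
  }
  rownames(data) <- NULL
  rownames(dropped) <- NULL
  harmonized_set(data, dropped, exposure_name, outcome_name)
}

#' Write a harmonized set and its exclusion log to TSV
#'
#' @param hset A [harmonized_set()].
#' @param path Output path for the harmonized table; the exclusion log is
#'   written next to it with suffix `.dropped.tsv`.
#' @return `path`, invisibly.
#' @export
write_harmonized_tsv <- function(hset, path) {
  d <- hset$data
  out <- data.frame(variant_id = d$variant_id, ea = d$effect_allele,
                    oa = d$other_allele, eaf = d$eaf,
                    beta_exp = d$beta_exposure, se_exp = d$se_exposure,
                    beta_out = d$beta_outcome, se_out = d$se_outcome)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(hset$dropped, sub("\\.tsv$", "", path) |>
                paste0(".dropped.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
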