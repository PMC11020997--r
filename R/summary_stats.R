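#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (optionally gzip-compressed, detected by a
#' `.gz` extension) of per-variant association statistics and maps its
#' columns onto the standard fields used throughout the package:
#' `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`
#' (required) and `chrom`, `pos`, `eaf`, `n` (optional).
#'
#' Rows whose `beta`, `se` or `pvalue` is missing or unparseable, whose
#' `se` is not strictly positive, whose p-value falls outside (0, 1], or
#' whose alleles are not single bases in A/C/G/T are skipped, never silently
#' dropped: every skipped row is recorded in the `skip_log` attribute with a
#' reason. Alleles are upper-cased on read.
#'
#' @param path Path to a delimited text file (TSV, CSV or whitespace),
#'   optionally gzipped.
#' @param column_map Named character vector or list mapping logical field
#'   names (`variant_id`, `effect_allele`, ... ) to column names in the
#'   file header.
#' @param delimiter Field separator; `NULL` (default) auto-detects.
#'
#' @return A `data.frame` with one row per retained variant and columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`; the attribute `skip_log` is a
#'   `data.frame` (`variant_id`, `reason`) of skipped rows.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP",
#'              "rs1\tA\tG\t0.1\t0.01\t1e-9"), f)
#' read_gwas_table(f, c(variant_id = "SNP", effect_allele = "EA",
#'                      other_allele = "OA", beta = "BETA", se = "SE",
#'                      pvalue = "P"))
read_gwas_table <- function(path, column_map, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  column_map <- unlist(column_map)
  required <- c("variant_id", "effect_allele", "other_allele",
                "beta", "se", "pvalue")
  missing_req <- setdiff(required, names(column_map))
  if (length(missing_req) > 0)
    stop("column_map must map fields: ", paste(missing_req, collapse = ", "))

  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    txt <- paste(readLines(con), collapse = "\n")
    close(con)
    if (!nzchar(txt)) txt <- "\n"
    dt <- data.table::fread(text = txt, sep = delimiter %||% "auto",
                            header = TRUE, data.table = FALSE,
                            colClasses = "character", showProgress = FALSE)
  } else {
    dt <- data.table::fread(path, sep = delimiter %||% "auto",
                            header = TRUE, data.table = FALSE,
                            colClasses = "character", showProgress = FALSE)
  }
  absent <- setdiff(unname(column_map), names(dt))
  if (length(absent) > 0)
    stop("mapped column(s) not found in header: ",
         paste(absent, collapse = ", "))

  empty <- data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), effect_allele = character(),
                      other_allele = character(), eaf = numeric(),
                      beta = numeric(), se = numeric(), pvalue = numeric(),
                      n = numeric(), stringsAsFactors = FALSE)
  skip0 <- data.frame(variant_id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  if (nrow(dt) == 0) {
    attr(empty, "skip_log") <- skip0
    return(empty)
  }

  get_col <- function(field, as = "numeric") {
    if (!field %in% names(column_map)) {
      return(rep(if (as == "numeric") NA_real_ else NA_character_, nrow(dt)))
    }
    x <- dt[[column_map[[field]]]]
    if (as == "numeric") suppressWarnings(as.numeric(x)) else as.character(x)
  }

  out <- data.frame(
    variant_id    = get_col("variant_id", "character"),
    chrom         = get_col("chrom", "character"),
    pos           = suppressWarnings(as.integer(get_col("pos"))),
    effect_allele = toupper(get_col("effect_allele", "character")),
    other_allele  = toupper(get_col("other_allele", "character")),
    eaf           = get_col("eaf"),
    beta          = get_col("beta"),
    se            = get_col("se"),
    pvalue        = get_col("pvalue"),
    n             = get_col("n"),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, nrow(out))
  bad_stat <- is.na(out$beta) | is.na(out$se) | is.na(out$pvalue)
  reason[bad_stat] <- "unparseable_statistic"
  bad_se <- !bad_stat & out$se <= 0
  reason[bad_se] <- "nonpositive_se"
  bad_p <- is.na(reason) & (out$pvalue <= 0 | out$pvalue > 1)
  reason[bad_p] <- "invalid_pvalue"
  ok_allele <- out$effect_allele %in% c("A", "C", "G", "T") &
    out$other_allele %in% c("A", "C", "G", "T") &
    out$effect_allele != out$other_allele
  reason[is.na(reason) & !ok_allele] <- "invalid_alleles"

  keep <- is.na(reason)
  skip_log <- data.frame(variant_id = out$variant_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skip_log") <- skip_log
  out
}

#' Filter variants by association p-value
#'
#' Retains exactly the records whose p-value is strictly below the
#' threshold (genome-wide instrument selection uses a strict "P <" rule,
#' so boundary values are excluded).
#'
#' @param records A summary-statistics `data.frame` with a `pvalue` column.
#' @param p_threshold Significance threshold in (0, 1); e.g. `1e-5` for
#'   microbiome exposures, `5e-8` for genome-wide significance.
#' @return The subset of `records` with `pvalue < p_threshold`.
#' @export
filter_by_pvalue <- function(records, p_threshold) {
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1,
            p_threshold > 0, p_threshold < 1 || p_threshold == 1)
  out <- records[!is.na(records$pvalue) & records$pvalue < p_threshold, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise linkage-disequilibrium table
#'
#' Wraps a table of pairwise r-squared values into the symmetric lookup
#' structure used by [clump()]. Pairs absent from the table are treated as
#' r-squared = 0 (independent); the diagonal is implicitly 1.
#'
#' @param pairs `data.frame` with columns `variant_a`, `variant_b`, `r2`.
#' @param window_kb Window size (kb) over which the r-squared values were
#'   computed / should be applied.
#' @return An object of class `ld_info`.
#' @export
ld_info <- function(pairs = NULL, window_kb = 10000) {
  if (is.null(pairs)) {
    pairs <- data.frame(variant_a = character(), variant_b = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("variant_a", "variant_b", "r2") %in% names(pairs)),
            all(pairs$r2 >= 0 & pairs$r2 <= 1))
  lookup <- new.env(parent = emptyenv())
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$variant_a[i]; b <- pairs$variant_b[i]
      assign(paste(a, b, sep = "\r"), pairs$r2[i], envir = lookup)
      assign(paste(b, a, sep = "\r"), pairs$r2[i], envir = lookup)
    }
  }
  structure(list(pairs = pairs, window_kb = window_kb, lookup = lookup),
            class = "ld_info")
}

.ld_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  if (is.null(ld)) return(0)
  get0(paste(a, b, sep = "\r"), envir = ld$lookup, ifnotfound = 0)
}

#' Greedy LD clumping
#'
#' Selects an approximately independent instrument set by the standard
#' greedy rule: sort variants by ascending p-value (ties broken by
#' `variant_id` lexicographic order), repeatedly keep the best remaining
#' variant and discard every other variant within the window having
#' r-squared at or above the threshold with it. The boundary is excluded:
#' a pair at exactly the threshold is discarded (the rule is
#' "r2 >= threshold"). Missing LD pairs count as r-squared 0. When
#' positions are unknown the window constraint is dropped and pruning is
#' genome-wide.
#'
#' @param records Summary-statistics `data.frame`.
#' @param ld An [ld_info()] object, or `NULL` for no LD (all independent).
#' @param r2_threshold Exclusion threshold in (0, 1]; default 0.001.
#' @param window_kb Clumping window in kb (inclusive at both endpoints,
#'   positions 1-based); default 10000.
#' @return The retained subset, sorted by ascending p-value.
#' @export
clump <- function(records, ld = NULL, r2_threshold = 0.001,
                  window_kb = 10000) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  if (nrow(records) == 0) return(records)
  ord <- order(records$pvalue, records$variant_id)
  rec <- records[ord, , drop = FALSE]
  have_pos <- !is.na(rec$pos) & !is.na(rec$chrom)
  active <- rep(TRUE, nrow(rec))
  keep <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!active[i]) next
    keep[i] <- TRUE
    active[i] <- FALSE
    for (j in which(active)) {
      in_window <- if (have_pos[i] && have_pos[j]) {
        rec$chrom[j] == rec$chrom[i] &&
          abs(rec$pos[j] - rec$pos[i]) <= window_kb * 1000
      } else TRUE
      if (in_window &&
          .ld_r2(ld, rec$variant_id[i], rec$variant_id[j]) >= r2_threshold) {
        active[j] <- FALSE
      }
    }
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exposure variance explained by an instrument set
#'
#' Two standard approximations for the variance in a (standardized) trait
#' explained by a set of independent variants:
#' `frequency` mode sums `2 * maf * (1 - maf) * beta^2` over variants;
#' `tstat` mode sums `t^2 / (t^2 + n - 2)` with `t = beta / se`, which
#' needs no allele frequencies. The result is clipped to `[0, 1)`.
#'
#' @param records Summary-statistics `data.frame`.
#' @param n Sample size (required for `tstat` mode; must exceed 2).
#' @param mode `"frequency"` or `"tstat"`.
#' @return Total R-squared, a single number in `[0, 1)`.
#' @export
variance_explained <- function(records, n = NULL,
                               mode = c("frequency", "tstat")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0) return(0)
  if (mode == "frequency") {
    if (anyNA(records$eaf)) {
      stop("eaf missing for variant(s): ",
           paste(records$variant_id[is.na(records$eaf)], collapse = ", "),
           " (needed for frequency mode)")
    }
    maf <- pmin(records$eaf, 1 - records$eaf)
    r2 <- sum(2 * maf * (1 - maf) * records$beta^2)
  } else {
    stopifnot(!is.null(n), n > 2)
    t2 <- (records$beta / records$se)^2
    r2 <- sum(t2 / (t2 + n - 2))
  }
  min(max(r2, 0), 1 - .Machine$double.eps)
}

#' Instrument-strength F-statistic
#'
#' Set-level F-statistic `F = R2 * (n - k - 1) / (k * (1 - R2))` where `n`
#' is the exposure GWAS sample size and `k` the number of instruments.
#' The conventional weak-instrument screen excludes sets with F < 10
#' (F = 10 exactly is retained).
#'
#' @param r2 Exposure variance explained, in `[0, 1)`.
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of instruments, at least 1.
#' @return The F-statistic.
#' @export
f_statistic <- function(r2, n, k) {
  stopifnot(r2 >= 0, r2 < 1, k >= 1)
  if (n <= k + 1) stop("n must exceed k + 1 (got n = ", n, ", k = ", k, ")")
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Per-variant F-statistics
#'
#' Diagnostic per-SNP instrument strength `(beta / se)^2`.
#'
#' @param records Summary-statistics `data.frame`.
#' @return Numeric vector named by `variant_id`.
#' @export
per_snp_f <- function(records) {
  setNames((records$beta / records$se)^2, records$variant_id)
}

#' Select instruments for one exposure
#'
#' Applies the full instrument-selection sequence: strict p-value
#' filtering, greedy LD clumping, variance-explained and F-statistic
#' computation, and the F >= 10 weak-instrument screen (applied at the
#' set level; sets below the cutoff are flagged, with `per_snp_f` kept for
#' diagnostics).
#'
#' @param records Summary-statistics `data.frame` for the exposure.
#' @param n Exposure GWAS sample size; taken from the records' `n` column
#'   when `NULL`.
#' @param p_threshold Instrument significance threshold (default `1e-5`).
#' @param ld,r2_threshold,window_kb Passed to [clump()].
#' @param f_min Minimum acceptable set-level F (default 10; `F >= f_min`
#'   retained).
#' @param r2_mode R-squared mode for [variance_explained()]; default
#'   `"auto"` uses `frequency` when all variants have `eaf`, else `tstat`.
#' @param trait_name Label carried through to results.
#' @return An object of class `instrument_set`: list with `records`,
#'   `trait_name`, `r2_explained`, `f_statistic`, `per_snp_f`, `weak`
#'   (logical) and the thresholds used.
#' @export
select_instruments <- function(records, n = NULL, p_threshold = 1e-5,
                               ld = NULL, r2_threshold = 0.001,
                               window_kb = 10000, f_min = 10,
                               r2_mode = c("auto", "frequency", "tstat"),
                               trait_name = "exposure") {
  r2_mode <- match.arg(r2_mode)
  n <- n %||% suppressWarnings(max(records$n, na.rm = TRUE))
  sel <- filter_by_pvalue(records, p_threshold)
  sel <- clump(sel, ld = ld, r2_threshold = r2_threshold,
               window_kb = window_kb)
  k <- nrow(sel)
  if (r2_mode == "auto")
    r2_mode <- if (k > 0 && !anyNA(sel$eaf)) "frequency" else "tstat"
  r2 <- if (k == 0) 0 else variance_explained(sel, n = n, mode = r2_mode)
  f <- if (k == 0 || !is.finite(n) || n <= k + 1) NA_real_
       else f_statistic(r2, n, k)
  structure(list(trait_name = trait_name, records = sel,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb, r2_explained = r2,
                 f_statistic = f, per_snp_f = per_snp_f(sel),
                 weak = is.finite(f) && f < f_min, f_min = f_min),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for", x$trait_name, "\n")
  cat("  variants:", nrow(x$records),
      " (p <", format(x$p_threshold), ", clump r2 >=",
      format(x$r2_threshold), "excluded)\n")
  cat("  R2 =", signif(x$r2_explained, 4),
      " F =", signif(x$f_statistic, 4),
      if (isTRUE(x$weak)) " [WEAK: F < 10]" else "", "\n")
  invisible(x)
}
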