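test_that("swapped outcome alleles are negated and frequency-flipped", {
  expo <- make_records("rs1", "A", "G", 0.1, 0.01, 1e-9, eaf = 0.3)
  outc <- make_records("rs1", "G", "A", -0.05, 0.02, 0.01, eaf = 0.7)
  h <- harmonize(expo, outc)
  expect_equal(nrow(h$data), 1)
  expect_equal(h$data$beta_outcome, 0.05)
  expect_equal(h$data$eaf, 0.3)
  expect_equal(h$data$eaf_outcome, 0.3)
})

test_that("all eight allele orientations resolve to the same signs", {
  # truth: exposure A/G beta +0.1 (eaf 0.2), outcome effect +0.05 for A
  cases <- list(
    list(ea = "A", oa = "G", b = 0.05, eaf = 0.2),   # same
    list(ea = "G", oa = "A", b = -0.05, eaf = 0.8),  # swap
    list(ea = "T", oa = "C", b = 0.05, eaf = 0.2),   # complement
    list(ea = "C", oa = "T", b = -0.05, eaf = 0.8))  # complement-swap
  for (cs in cases) {
    expo <- make_records("rs1", "A", "G", 0.1, 0.01, 1e-9, eaf = 0.2)
    outc <- make_records("rs1", cs$ea, cs$oa, cs$b, 0.02, 0.01,
                         eaf = cs$eaf)
    h <- harmonize(expo, outc)
    expect_equal(h$data$beta_outcome, 0.05,
                 label = paste("outcome beta for", cs$ea, cs$oa))
    expect_equal(h$data$beta_exposure, 0.1)
  }
  # the same four cases with the exposure pair flipped to G/A, beta -0.1
  for (cs in cases) {
    expo <- make_records("rs1", "G", "A", -0.1, 0.01, 1e-9, eaf = 0.8)
    outc <- make_records("rs1", cs$ea, cs$oa, cs$b, 0.02, 0.01,
                         eaf = cs$eaf)
    h <- harmonize(expo, outc)
    # aligned to the exposure's effect allele G: both betas negative
    expect_equal(h$data$beta_outcome, -0.05)
    expect_equal(h$data$beta_exposure, -0.1)
  }
})

test_that("palindromic variants follow the intermediate-MAF rule", {
  # eaf 0.50 > 0.42 cutoff: dropped
  expo <- make_records("rs1", "A", "T", 0.1, 0.01, 1e-9, eaf = 0.50)
  outc <- make_records("rs1", "A", "T", 0.05, 0.02, 0.01, eaf = 0.50)
  h <- harmonize(expo, outc)
  expect_equal(nrow(h$data), 0)
  expect_equal(h$dropped$reason, "palindromic_high_maf")

  # low MAF, concordant frequencies: retained in the same orientation
  expo <- make_records("rs1", "A", "T", 0.1, 0.01, 1e-9, eaf = 0.10)
  outc <- make_records("rs1", "A", "T", 0.05, 0.02, 0.01, eaf = 0.12)
  h <- harmonize(expo, outc)
  expect_equal(h$data$beta_outcome, 0.05)

  # discordant frequencies: flipped
  outc2 <- make_records("rs1", "A", "T", 0.05, 0.02, 0.01, eaf = 0.88)
  h2 <- harmonize(expo, outc2)
  expect_equal(h2$data$beta_outcome, -0.05)

  # missing frequency: cannot apply the rule, dropped
  outc3 <- make_records("rs1", "A", "T", 0.05, 0.02, 0.01)
  h3 <- harmonize(expo, outc3)
  expect_equal(h3$dropped$reason, "palindromic_high_maf")

  # MAF rule applies to either side: outcome intermediate drops the row
  outc4 <- make_records("rs1", "A", "T", 0.05, 0.02, 0.01, eaf = 0.45)
  expect_equal(harmonize(expo, outc4)$dropped$reason,
               "palindromic_high_maf")
})

test_that("irreconcilable alleles, absent variants and duplicates are logged", {
  expo <- make_records(c("rs1", "rs2", "rs2", "rs3"), "A", "G",
                       0.1, 0.01, c(1e-9, 1e-8, 1e-6, 1e-7), eaf = 0.3)
  outc <- make_records(c("rs1", "rs2"), c("A", "G"), c("C", "A"),
                       0.05, 0.02, 0.01, eaf = 0.3)
  h <- harmonize(expo, outc)
  reasons <- sort(h$dropped$reason)
  expect_equal(reasons, c("allele_mismatch", "duplicate",
                          "not_in_outcome"))
  expect_equal(h$data$variant_id, "rs2")  # lowest-p duplicate kept
  expect_equal(h$data$pvalue_exposure, 1e-8)
})

test_that("harmonizing an already-aligned set is the identity", {
  set.seed(3)
  s <- simulate_two_sample(sim_config(J = 10, seed = 3))
  h1 <- harmonize(s$exposure, s$outcome)
  # feed the retained rows back through as summary records
  expo2 <- make_records(h1$data$variant_id, h1$data$effect_allele,
                        h1$data$other_allele, h1$data$beta_exposure,
                        h1$data$se_exposure, h1$data$pvalue_exposure,
                        eaf = h1$data$eaf)
  outc2 <- make_records(h1$data$variant_id, h1$data$effect_allele,
                        h1$data$other_allele, h1$data$beta_outcome,
                        h1$data$se_outcome, h1$data$pvalue_outcome,
                        eaf = h1$data$eaf_outcome)
  h2 <- harmonize(expo2, outc2)
  expect_equal(h2$data$beta_exposure, h1$data$beta_exposure)
  expect_equal(h2$data$beta_outcome, h1$data$beta_outcome)
  expect_equal(nrow(h2$dropped), 0)
})

test_that("harmonized sets serialize to TSV with the exclusion log", {
  expo <- make_records(c("rs1", "rs2"), "A", "G", 0.1, 0.01, 1e-9,
                       eaf = 0.3)
  outc <- make_records("rs1", "A", "G", 0.05, 0.02, 0.01, eaf = 0.3)
  h <- harmonize(expo, outc)
  f <- tempfile(fileext = ".tsv")
  write_harmonized_tsv(h, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("variant_id", "ea", "oa", "eaf", "beta_exp",
                             "se_exp", "beta_out", "se_out"))
  drop_tab <- read.delim(sub("\\.tsv$", ".dropped.tsv", f))
  expect_equal(drop_tab$reason, "not_in_outcome")
})
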