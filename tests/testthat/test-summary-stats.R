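test_that("read_gwas_table round-trips records and logs skipped rows", {
  f <- write_gwas_fixture(c(
    "SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\ta\tg\t0.30\t0.1\t0.01\t1e-9\t1000",
    "rs2\tC\tT\t0.50\t-0.2\t0.05\t0.03\t1000"))
  rec <- read_gwas_table(f, std_map)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$beta, c(0.1, -0.2))
  expect_equal(rec$se, c(0.01, 0.05))
  expect_equal(rec$pvalue, c(1e-9, 0.03))
  expect_equal(rec$effect_allele, c("A", "C"))  # upper-cased
  expect_equal(nrow(attr(rec, "skip_log")), 0)

  # header-only file
  f2 <- write_gwas_fixture("SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN")
  rec2 <- read_gwas_table(f2, std_map)
  expect_equal(nrow(rec2), 0)
  expect_equal(nrow(attr(rec2, "skip_log")), 0)

  # nonpositive se skipped with reason
  f3 <- write_gwas_fixture(c(
    "SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\tA\tG\t0.3\t0.1\t0.01\t1e-9\t1000",
    "rs2\tA\tG\t0.3\t0.1\t0\t1e-9\t1000"))
  rec3 <- read_gwas_table(f3, std_map)
  expect_equal(nrow(rec3), 1)
  log3 <- attr(rec3, "skip_log")
  expect_equal(log3$variant_id, "rs2")
  expect_equal(log3$reason, "nonpositive_se")

  # gzip by extension
  fz <- write_gwas_fixture(c(
    "SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\tA\tG\t0.3\t0.1\t0.01\t1e-9\t1000"), gz = TRUE)
  expect_equal(read_gwas_table(fz, std_map)$beta, 0.1)

  # missing mapped column is a configuration error naming the column
  expect_error(read_gwas_table(f, c(std_map[-7], pvalue = "PVAL")), "PVAL")
})

test_that("p-value filtering is strictly below the threshold", {
  rec <- make_records(paste0("rs", 1:3), "A", "G", 0.1, 0.01,
                      c(1e-6, 1e-5, 1e-4))
  expect_equal(filter_by_pvalue(rec, 1e-5)$variant_id, "rs1")
  expect_equal(nrow(filter_by_pvalue(rec, 1)), 3)
  expect_equal(nrow(filter_by_pvalue(rec[0, ], 1e-5)), 0)
  # idempotence
  once <- filter_by_pvalue(rec, 1e-5)
  expect_identical(filter_by_pvalue(once, 1e-5), once)
})

test_that("greedy clumping discards linked variants, boundary inclusive", {
  rec <- make_records(paste0("rs", 1:3), "A", "G", 0.1, 0.01,
                      c(1e-8, 1e-7, 1e-6))
  ld <- ld_info(data.frame(variant_a = "rs1", variant_b = "rs2", r2 = 0.5))
  expect_equal(clump(rec, ld)$variant_id, c("rs1", "rs3"))

  # a pair at exactly the threshold is excluded (rule is r2 >= threshold)
  ld2 <- ld_info(data.frame(variant_a = "rs1", variant_b = "rs2",
                            r2 = 0.001))
  expect_equal(clump(rec, ld2, r2_threshold = 0.001)$variant_id,
               c("rs1", "rs3"))

  # independent variants pass through, sorted by p
  shuffled <- rec[c(3, 1, 2), ]
  expect_equal(clump(shuffled, NULL)$variant_id, paste0("rs", 1:3))
})

test_that("clumping respects the window and is idempotent", {
  rec <- make_records(paste0("rs", 1:2), "A", "G", 0.1, 0.01,
                      c(1e-8, 1e-7))
  rec$chrom <- "1"
  rec$pos <- c(1L, 20000001L)  # 20 Mb apart, outside a 10 Mb window
  ld <- ld_info(data.frame(variant_a = "rs1", variant_b = "rs2", r2 = 0.9))
  expect_equal(clump(rec, ld, window_kb = 10000)$variant_id,
               c("rs1", "rs2"))
  expect_equal(clump(rec, ld, window_kb = 30000)$variant_id, "rs1")

  # idempotence over random instances
  set.seed(42)
  for (i in 1:5) {
    n <- 8
    r <- make_records(paste0("rs", 1:n), "A", "G", 0.1, 0.01,
                      runif(n, 1e-9, 1e-5))
    pr <- t(utils::combn(n, 2))
    ld_r <- ld_info(data.frame(variant_a = paste0("rs", pr[, 1]),
                               variant_b = paste0("rs", pr[, 2]),
                               r2 = rbinom(nrow(pr), 1, 0.3) *
                                 runif(nrow(pr))))
    once <- clump(r, ld_r)
    expect_identical(clump(once, ld_r), once)
  }
})

test_that("variance explained matches the closed forms", {
  one <- make_records("rs1", "A", "G", 0.1, 0.02, 1e-9, eaf = 0.5)
  expect_equal(variance_explained(one, mode = "frequency"), 0.005)
  expect_equal(variance_explained(one, n = 1000, mode = "tstat"),
               25 / (25 + 998), tolerance = 1e-12)
  null_b <- make_records("rs1", "A", "G", 0, 0.02, 0.9, eaf = 0.3)
  expect_equal(variance_explained(null_b, mode = "frequency"), 0)
  expect_equal(variance_explained(null_b, n = 1000, mode = "tstat"), 0)
  # missing eaf in frequency mode names the variant
  miss <- make_records("rs9", "A", "G", 0.1, 0.02, 1e-9)
  expect_error(variance_explained(miss, mode = "frequency"), "rs9")
})

test_that("F-statistic follows the printed formula and screening rule", {
  expect_equal(f_statistic(0.5, 3, 1), 1.0)
  expect_equal(f_statistic(0.02, 1000, 5), 0.02 * 994 / (5 * 0.98),
               tolerance = 1e-12)
  expect_lt(f_statistic(0.02, 1000, 5), 10)  # flagged weak
  expect_error(f_statistic(0.5, 2, 1), "exceed")

  # F exactly 10 is retained by the set-level screen
  # pick r2 so that F = 10 at n = 1001, k = 10: r2 = 100/(990 + 100)
  r2 <- 100 / 1090
  expect_equal(f_statistic(r2, 1001, 10), 10, tolerance = 1e-12)
  rec <- make_records(paste0("rs", 1:10), "A", "G", 0.1, 0.01, 1e-9,
                      eaf = 0.25)
  iv <- select_instruments(rec, n = 1001, f_min = 10)
  expect_false(iv$weak && iv$f_statistic == 10)
})

test_that("select_instruments assembles the screening pipeline", {
  set.seed(7)
  s <- simulate_two_sample(sim_config(J = 12, theta = 0, seed = 7))
  iv <- select_instruments(s$exposure, p_threshold = 1e-5,
                           trait_name = "bug")
  expect_s3_class(iv, "instrument_set")
  expect_equal(nrow(iv$records), 12)  # generator guarantees significance
  expect_true(all(iv$records$pvalue < 1e-5))
  expect_false(iv$weak)
  expect_gte(iv$f_statistic, 10)
  expect_length(iv$per_snp_f, 12)
})
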