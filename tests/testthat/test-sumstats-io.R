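test_that("well-formed files pass through and violating rows are rejected with reasons", {
  f <- make_sumstats_file(withr::local_tempfile(), .rows = 3)
  tab <- read_sumstats(f)
  expect_s3_class(tab, "cohort_table")
  expect_equal(nrow(tab), 3)
  expect_equal(nrow(attr(tab, "rejections")), 0)

  # se = 0 drops exactly that record and logs it
  f2 <- make_sumstats_file(withr::local_tempfile(), .rows = 3, se = c(0.05, 0, 0.05))
  log <- withr::local_tempfile()
  tab2 <- read_sumstats(f2, log_path = log)
  expect_equal(nrow(tab2), 2)
  rej <- attr(tab2, "rejections")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$reason, "nonpositive_se")
  logged <- jsonlite::stream_in(file(log), verbose = FALSE)
  expect_equal(logged$reason, "nonpositive_se")

  # lowercase alleles are normalized, not rejected
  f3 <- make_sumstats_file(withr::local_tempfile(), .rows = 2,
                           effect_allele = c("a", "t"),
                           other_allele = c("g", "c"))
  tab3 <- read_sumstats(f3)
  expect_equal(nrow(tab3), 2)
  expect_setequal(tab3$effect_allele, c("A", "T"))

  # indel-style multi-character alleles are rejected (SNPs only)
  f4 <- make_sumstats_file(withr::local_tempfile(), .rows = 2,
                           effect_allele = c("A", "AT"))
  expect_equal(attr(read_sumstats(f4), "rejections")$reason, "non_snp_allele")

  # p inconsistent with beta/se beyond the Wald tolerance is rejected
  df5 <- make_sumstats_df(2)
  df5$p[1] <- 2 * pnorm(-abs(df5$beta[1] / df5$se[1]))  # consistent
  df5$p[2] <- 0.9                                        # z = 1 -> p 0.317
  f5 <- write_tsv_fixture(df5, withr::local_tempfile(),
                          header = c("SNP", "CHR", "POS", "EA", "OA", "EAF",
                                     "BETA", "SE", "P", "N"))
  expect_equal(attr(read_sumstats(f5), "rejections")$reason, "p_z_inconsistent")
})

test_that("missing columns and empty files are hard errors; column_map handles dialects", {
  df <- make_sumstats_df(2)
  names(df) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  f <- write_tsv_fixture(df[, -8], withr::local_tempfile())
  expect_error(read_sumstats(f), "SE")

  fe <- write_tsv_fixture(df[0, ], withr::local_tempfile())
  expect_error(read_sumstats(fe), "empty")

  # GWAMA-ish header mapped onto canonical names
  names(df) <- c("rs_number", "chromosome", "position", "reference_allele",
                 "other_allele", "eaf", "beta", "se", "p-value", "n_samples")
  fg <- write_tsv_fixture(df, withr::local_tempfile())
  tab <- read_sumstats(fg, column_map = c(
    SNP = "rs_number", CHR = "chromosome", POS = "position",
    EA = "reference_allele", OA = "other_allele", EAF = "eaf", BETA = "beta",
    SE = "se", P = "p-value", N = "n_samples"))
  expect_equal(nrow(tab), 2)
  expect_error(read_sumstats(fg, column_map = c(FOO = "bar")), "unknown")
})

test_that("write/read round-trips a table exactly", {
  sim <- simulate_cohort_sumstats(sim_config(seed = 11, n_loci = 2))
  tab <- sim$cohorts[[1]]
  f <- withr::local_tempfile()
  write_sumstats(tab, f)
  back <- read_sumstats(f, cohort_name = attr(tab, "cohort_name"),
                        trait = attr(tab, "trait"))
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("MAF filter is strict at the boundary, symmetric, idempotent and order-preserving", {
  tab <- make_sumstats_df(4, eaf = c(0.5, 0.06, 0.05, 0.01))
  kept <- filter_maf(tab, 0.05)
  expect_equal(kept$eaf, c(0.5, 0.06))

  expect_equal(nrow(filter_maf(tab[0, ], 0.05)), 0)
  expect_equal(nrow(filter_maf(make_sumstats_df(1, eaf = 0.97), 0.05)), 0)

  # idempotent, order preserved
  tab2 <- make_sumstats_df(6, eaf = c(0.3, 0.02, 0.4, 0.99, 0.2, 0.1))
  once <- filter_maf(tab2, 0.05)
  expect_equal(filter_maf(once, 0.05), once)
  expect_equal(once$snp_id, tab2$snp_id[c(1, 3, 5, 6)])

  expect_error(filter_maf(tab, 0.6))
})

test_that("allele harmonization flips swapped records, drops ambiguous and irreconcilable ones, and is idempotent", {
  ref <- make_sumstats_df(4,
    effect_allele = c("G", "A", "A", "A"),
    other_allele = c("A", "T", "C", "G"))
  tab <- make_sumstats_df(4,
    effect_allele = c("A", "A", "A", "A"),
    other_allele = c("G", "T", "G", "C"),
    eaf = c(0.3, 0.5, 0.3, 0.3),
    beta = c(0.1, 0.1, 0.1, 0.1),
    p = 2 * pnorm(-abs(0.1 / 0.05)))
  out <- harmonize_alleles(tab, reference = ref)
  log <- attr(out, "harmonization")

  # rs1: swapped vs reference -> beta sign flips, eaf complemented
  expect_equal(log$action[log$snp_id == "rs1"], "flip")
  expect_equal(out$beta[out$snp_id == "rs1"], -0.1)
  expect_equal(out$eaf[out$snp_id == "rs1"], 0.7)
  expect_equal(out$effect_allele[out$snp_id == "rs1"], "G")

  # rs2: palindromic A/T at eaf 0.5 -> strand-ambiguous, dropped
  expect_equal(log$action[log$snp_id == "rs2"], "drop_palindromic")
  expect_false("rs2" %in% out$snp_id)

  # rs3: A/G vs reference A/C -> irreconcilable
  expect_equal(log$action[log$snp_id == "rs3"], "drop_mismatch")

  # rs4: A/C vs reference A/G? (row 4 is A/C vs ref A/G) irreconcilable too
  expect_equal(log$action[log$snp_id == "rs4"], "drop_mismatch")

  # applying again changes nothing (the action log then reads all-keep)
  twice <- harmonize_alleles(out, reference = ref)
  attr(twice, "harmonization") <- attr(out, "harmonization") <- NULL
  expect_equal(twice, out)
})

test_that("strand-complement records are relabelled to the reference strand", {
  ref <- make_sumstats_df(2, effect_allele = c("A", "A"),
                          other_allele = c("G", "G"))
  tab <- make_sumstats_df(2, effect_allele = c("T", "C"),
                          other_allele = c("C", "T"), beta = 0.1,
                          p = 2 * pnorm(-2))
  out <- harmonize_alleles(tab, reference = ref)
  # T/C complements to A/G: same orientation -> keep; C/T complements to G/A:
  # swapped -> flip
  log <- attr(out, "harmonization")
  expect_equal(log$action, c("keep", "flip"))
  expect_equal(out$beta, c(0.1, -0.1))
  expect_equal(out$effect_allele, c("A", "A"))
})

test_that("sample-size report sums cohort maxima per trait", {
  t1 <- cohort_table(make_sumstats_df(3, n = c(2741, 2700, 2741)),
                     cohort_name = "APCDR", trait = "WBCc")
  t2 <- cohort_table(make_sumstats_df(3, n = 15061), cohort_name = "BCX2",
                     trait = "WBCc")
  t3 <- cohort_table(make_sumstats_df(2, n = 2681), cohort_name = "APCDR",
                     trait = "Lym")
  t4 <- cohort_table(make_sumstats_df(2, n = 13477), cohort_name = "BCX2",
                     trait = "Lym")
  rep <- sample_size_report(list(t1, t2, t3, t4))
  expect_equal(rep$total[rep$trait == "WBCc"], 17802)
  expect_equal(rep$total[rep$trait == "Lym"], 16158)

  solo <- sample_size_report(list(t1))
  expect_equal(solo$total, 2741)
})
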