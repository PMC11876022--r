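test_that("TSV round-trip parses typed records and honours dialect remapping", {
  tsv <- file.path(tempdir(), "canon.tsv")
  d <- data.frame(snp = c("rs1", "rs2"), chr = c("1", "2"),
                  pos = c(100L, 200L),
                  effect_allele = c("A", "C"), other_allele = c("G", "T"),
                  eaf = c(0.2, 0.4), beta = c(0.05, -0.02),
                  se = c(0.01, 0.02), pval = c(1e-8, 0.03),
                  n = c(1000L, 1000L))
  write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- read_summary_stats(tsv, trait_id = "t")
  expect_s3_class(ss, "mr_sumstats")
  expect_equal(nrow(ss), 2L)
  expect_identical(ss$snp, c("rs1", "rs2"))
  expect_type(ss$beta, "double")
  expect_type(ss$pos, "integer")

  # same content under renamed headers, mapped back through a dialect
  d2 <- d
  names(d2) <- c("SNP_ID", "CHR", "BP", "A1", "A2", "FRQ", "BETA", "SE",
                 "P", "N")
  tsv2 <- file.path(tempdir(), "renamed.tsv")
  write.table(d2, tsv2, sep = "\t", quote = FALSE, row.names = FALSE)
  ss2 <- read_summary_stats(tsv2, trait_id = "t", dialect = c(
    SNP_ID = "snp", CHR = "chr", BP = "pos", A1 = "effect_allele",
    A2 = "other_allele", FRQ = "eaf", BETA = "beta", SE = "se",
    P = "pval", N = "n"))
  expect_identical(as.data.frame(ss), as.data.frame(ss2))

  # round-trip through the writer
  tsv3 <- file.path(tempdir(), "rt.tsv")
  write_summary_stats(ss, tsv3)
  expect_identical(as.data.frame(read_summary_stats(tsv3, "t")),
                   as.data.frame(ss))
})

test_that("invalid rows are rejected with reasons; structural errors abort", {
  base <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"), chr = "1",
                     pos = 1:4, effect_allele = c("A", "A", "N", "A"),
                     other_allele = c("G", "G", "G", "A"),
                     eaf = c(0.3, 0.3, 0.3, 0.3),
                     beta = 0.1, se = c(0.01, 0, 0.01, 0.01),
                     pval = 0.5, n = 100)
  ss <- summary_stats(base, "t")
  expect_equal(nrow(ss), 1L)
  rej <- attr(ss, "rejections")
  expect_equal(nrow(rej), 3L)
  expect_setequal(rej$reason, c("se not positive", "non-ACGT allele",
                                "effect allele equals other allele"))

  expect_error(summary_stats(base[, -7], "t"), "missing required column")
  expect_error(summary_stats(base[0, ], "t"), "empty")

  dup <- base[c(1, 1), ]
  dup$se <- 0.01
  expect_equal(attr(summary_stats(dup, "t"), "rejections")$reason,
               "duplicate snp_id")

  tsv <- file.path(tempdir(), "dialect_err.tsv")
  write.table(base, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(tsv, dialect = c(NOPE = "beta")),
               "absent column")
})

test_that("harmonize keeps, flips, strand-resolves and drops as required", {
  exp <- make_sumstats(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                       beta = c(0.1, 0.2, 0.3, 0.4, 0.5), se = 0.01,
                       eaf = c(0.3, 0.3, 0.3, 0.5, 0.3),
                       effect_allele = c("A", "A", "A", "A", "A"),
                       other_allele = c("G", "G", "G", "T", "G"),
                       trait = "exp")
  # rs1 identical coding; rs2 swapped; rs3 opposite strand (T/C);
  # rs4 palindromic at eaf 0.50; rs5 irreconcilable alleles
  out <- make_sumstats(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                       beta = c(0.01, 0.02, 0.03, 0.04, 0.05), se = 0.02,
                       eaf = c(0.3, 0.7, 0.3, 0.5, 0.3),
                       effect_allele = c("A", "G", "T", "A", "A"),
                       other_allele = c("G", "A", "C", "T", "C"),
                       trait = "out")
  h <- harmonize(exp, out, palindrome_policy = "drop-ambiguous",
                 eaf_window = c(0.42, 0.58))
  expect_equal(h$action,
               c("kept", "flipped", "kept", "dropped-palindromic",
                 "dropped-mismatch"))
  expect_equal(h$beta_out[1], 0.01)
  # swap rule: beta negated, frequency complemented
  expect_equal(h$beta_out[2], -0.02)
  expect_equal(h$eaf_out[2], 0.3)
  expect_equal(h$beta_out[3], 0.03)

  # SNP absent from the outcome
  h2 <- harmonize(exp, make_sumstats("rs1", 0.01, 0.02, trait = "out"))
  expect_equal(h2$action[h2$snp == "rs2"], "dropped-missing")

  # drop-all removes palindromic SNPs regardless of frequency
  h3 <- harmonize(exp, out, palindrome_policy = "drop-all")
  expect_equal(h3$action[4], "dropped-palindromic")
  # keep trusts the literal codes
  h4 <- harmonize(exp, out, palindrome_policy = "keep")
  expect_equal(h4$action[4], "kept")
})

test_that("harmonization is idempotent, involutive under double swap, and bounded", {
  exp <- make_sumstats(paste0("rs", 1:4), beta = c(0.1, -0.2, 0.3, 0.15),
                       se = 0.01, eaf = c(0.2, 0.3, 0.4, 0.25),
                       trait = "exp")
  out_swapped <- make_sumstats(paste0("rs", 1:4),
                               beta = c(0.01, 0.02, -0.03, 0.005), se = 0.02,
                               eaf = 0.65, effect_allele = "G",
                               other_allele = "A", trait = "out")
  h1 <- harmonize(exp, out_swapped)
  expect_true(all(h1$action == "flipped"))

  # re-expressing the harmonized outcome as a table and harmonizing again
  # changes nothing
  realigned <- make_sumstats(h1$snp, h1$beta_out, h1$se_out, eaf = h1$eaf_out,
                             trait = "out")
  h2 <- harmonize(exp, realigned)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_out, h1$beta_out)

  # double swap restores the original sign (involution)
  reswapped <- as.data.frame(out_swapped)
  reswapped$effect_allele <- "A"; reswapped$other_allele <- "G"
  reswapped$beta <- -reswapped$beta
  reswapped$eaf <- 1 - reswapped$eaf
  h3 <- harmonize(exp, summary_stats(reswapped, "out"))
  expect_equal(h3$beta_out, h1$beta_out)

  # row-count bound: |harmonized| <= min(|exposure|, |outcome|)
  sub <- as.data.frame(out_swapped)[1:2, ]
  h4 <- harmonize(exp, summary_stats(sub, "out"))
  kept <- sum(h4$action %in% c("kept", "flipped"))
  expect_lte(kept, min(nrow(exp), 2))
})
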