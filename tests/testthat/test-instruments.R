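test_that("variance explained follows 2 beta^2 maf (1-maf) with MAF symmetry", {
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(0.1, 0.5), 2 * 0.01 * 0.25)
  expect_equal(variance_explained(0.1, 0.8), variance_explained(0.1, 0.2))
  expect_error(variance_explained(0.1, 0), "eaf")
  expect_error(variance_explained(0.1, 1.2), "eaf")
  # audit mode reproduces the published linear-beta rendering verbatim
  expect_equal(variance_explained(0.1, 0.8, formula = "as-printed"),
               2 * 0.8 * 0.2 * 2 * 0.1)
})

test_that("F statistic matches the (N-k-1)/k * R2/(1-R2) form", {
  expect_equal(f_statistic(100, 3, 0), 0)
  expect_equal(f_statistic(100000, 50, 0.01), (100000 - 51) / 50 * 0.01 / 0.99)
  expect_lt(f_statistic(1000, 5, 0.001), 10)  # weak-instrument example
  # strictly monotone in r2, approximately linear for small r2
  f1 <- f_statistic(1e5, 10, 0.001)
  f2 <- f_statistic(1e5, 10, 0.002)
  expect_gt(f2, f1)
  expect_equal(f2 / f1, 2, tolerance = 0.01)
  expect_error(f_statistic(10, 10, 0.1), "n > k")
  expect_error(f_statistic(100, 2, 1), "r2")
})

test_that("greedy clumping applies p, r2 and window rules deterministically", {
  ss <- make_sumstats(c("rsA", "rsB", "rsC"), beta = c(0.1, 0.1, 0.1),
                      se = 0.01, pval = c(1e-10, 1e-9, 1e-8 * 0.99),
                      chr = "1", pos = c(1e6, 2e6, 3e6))
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.5
  r2[1, 3] <- r2[3, 1] <- 0.0005
  dimnames(r2) <- list(ss$snp, ss$snp)
  ld <- ld_matrix(r2, as.data.frame(ss)[, c("snp", "chr", "pos")])
  expect_equal(clump(ss, ld), c("rsA", "rsC"))

  # single significant SNP
  one <- make_sumstats("rsA", 0.1, 0.01, pval = 1e-9)
  expect_equal(clump(one, make_identity_ld(one)), "rsA")

  # no SNP below threshold: empty, not an error
  none <- make_sumstats("rsA", 0.01, 0.01, pval = 0.5)
  expect_identical(clump(none, make_identity_ld(none)), character(0))

  # high r2 but beyond the physical window: both kept
  far <- make_sumstats(c("rs1", "rs2"), c(0.1, 0.1), 0.01,
                       pval = c(1e-10, 1e-9), chr = "1", pos = c(1e6, 2.1e7))
  r2f <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(far$snp, far$snp))
  ldf <- ld_matrix(r2f, as.data.frame(far)[, c("snp", "chr", "pos")])
  expect_equal(sort(clump(far, ldf, window_kb = 10000)), c("rs1", "rs2"))
  # same pair inside the window collapses to the lower-p SNP
  near <- as.data.frame(far); near$pos <- c(1e6, 2e6)
  ldn <- ld_matrix(r2f, near[, c("snp", "chr", "pos")])
  expect_equal(clump(summary_stats(near, "t"), ldn), "rs1")

  # missing SNP in the LD matrix is a configuration error
  expect_error(clump(ss, ldf), "absent from LD matrix")
})

test_that("clumping is invariant to row permutation with snp_id tie-break", {
  set.seed(42)
  k <- 12
  ss <- make_sumstats(sprintf("rs%02d", 1:k), beta = rnorm(k, 0, 0.1),
                      se = 0.01, pval = rep(c(1e-9, 1e-10, 1e-11), 4),
                      chr = "1", pos = seq_len(k) * 1e6)
  r2 <- diag(k)
  r2[2, 5] <- r2[5, 2] <- 0.8
  r2[3, 7] <- r2[7, 3] <- 0.6
  dimnames(r2) <- list(ss$snp, ss$snp)
  ld <- ld_matrix(r2, as.data.frame(ss)[, c("snp", "chr", "pos")])
  ref <- clump(ss, ld)
  for (i in 1:5) {
    perm <- as.data.frame(ss)[sample(k), ]
    expect_equal(clump(summary_stats(perm, "t"), ld), ref)
  }
})

test_that("select_instruments composes the filters and accounts for each stage", {
  ss <- make_sumstats(sprintf("rs%d", 1:4),
                      beta = c(0.1, 0.12, 0.002, 0.08),
                      se = c(0.01, 0.01, 0.0003, 0.01),
                      eaf = 0.3,
                      pval = c(1e-20, 1e-25, 1e-11, 0.2),
                      n = 1e5, chr = "1", pos = (1:4) * 2e7)
  ld <- make_identity_ld(ss)
  ins <- select_instruments(ss, ld)
  # rs4 fails the p filter; rs3 is significant but explains ~1.7e-6 of the
  # variance (single-SNP F ~ 0.17 < 10) and is removed by the F filter
  expect_setequal(ins$snps$snp, c("rs1", "rs2"))
  expect_equal(ins$k, 2L)
  expect_true(all(ins$snps$f_stat >= 10))
  rep <- ins$report
  expect_equal(rep$n[rep$stage == "input"], 4)
  expect_equal(rep$n[rep$stage == "p_filter"], 3)
  expect_equal(rep$n[rep$stage == "clump"], 3)
  expect_equal(rep$n[rep$stage == "f_filter"], 2)

  # per-SNP r2 and F recorded and consistent with the formulas
  expect_equal(ins$snps$r2, variance_explained(ins$snps$beta, ins$snps$eaf))
  expect_equal(ins$snps$f_stat,
               f_statistic(ins$snps$n, 1, ins$snps$r2))

  # set-k audit mode: F uses k = clumped-set size, single pass
  ins_set <- select_instruments(ss, ld, f_k_mode = "set")
  expect_equal(ins_set$snps$f_stat,
               f_statistic(ins_set$snps$n, 3, ins_set$snps$r2))
  # constructed weak set: n = 1000, k = 5, per-SNP r2 = 0.001 -> F ~ 0.199,
  # everything removed under the set reading
  weak <- make_sumstats(sprintf("w%d", 1:5),
                        beta = rep(sqrt(0.001 / (2 * 0.25)), 5),
                        se = 0.001, eaf = 0.5, pval = rep(1e-9, 5),
                        n = 1000, chr = "1", pos = (1:5) * 2e7)
  ins_weak <- select_instruments(weak, make_identity_ld(weak),
                                 f_k_mode = "set")
  expect_equal(ins_weak$k, 0L)
})

test_that("LD matrix round-trips through TSV and validates its invariants", {
  ss <- make_sumstats(c("rs1", "rs2"), c(0.1, 0.2), 0.01,
                      chr = c("1", "2"), pos = c(100, 200))
  r2 <- matrix(c(1, 0.25, 0.25, 1), 2, dimnames = list(ss$snp, ss$snp))
  ld <- ld_matrix(r2, as.data.frame(ss)[, c("snp", "chr", "pos")])
  path <- file.path(tempdir(), "ld_test.tsv")
  write_ld_matrix(ld, path)
  ld2 <- read_ld_matrix(path)
  expect_equal(ld2$r2, ld$r2)
  expect_equal(ld2$positions, ld$positions)

  expect_error(ld_matrix(matrix(c(1, 0.5, 0.2, 1), 2,
                                dimnames = list(c("a", "b"), c("a", "b"))),
                         data.frame(snp = c("a", "b"), chr = "1",
                                    pos = 1:2)),
               "symmetric")
  expect_error(ld_matrix(matrix(c(1, 2, 2, 1), 2,
                                dimnames = list(c("a", "b"), c("a", "b"))),
                         data.frame(snp = c("a", "b"), chr = "1",
                                    pos = 1:2)),
               "\\[0,1\\]")
})
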