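test_that("odds-scale conversion matches hand values and the null", {
  conv <- to_odds_scale(0.068207, 0.021287)
  expect_equal(conv$or, exp(0.068207))
  expect_equal(conv$ci_high, exp(0.068207 + 1.96 * 0.021287))
  expect_equal(conv$pval, 2 * pnorm(-0.068207 / 0.021287))

  null <- to_odds_scale(0, 0.1)
  expect_equal(null$or, 1)
  expect_equal(null$ci_low * null$ci_high, 1)  # symmetric about 1 on log scale
  expect_equal(null$pval, 1)
})

test_that("Wald ratio: value, delta-method se, and sign symmetry", {
  h <- make_hset(0.1, 0.005, 0.02, 0.01)
  est <- wald_ratio(h)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)

  expect_equal(wald_ratio(make_hset(0.1, 0.005, 0, 0.01))$beta, 0)

  neg <- wald_ratio(make_hset(-0.1, 0.005, 0.02, 0.01))
  expect_equal(neg$beta, -0.2)
  expect_equal(neg$se, 0.1)

  expect_error(wald_ratio(make_hset(0, 0.005, 0.02, 0.01)), "undefined")
})

test_that("IVW matches the closed-form weighted regression through the origin", {
  h <- make_hset(c(0.1, 0.2), 0.005, c(0.02, 0.05), c(0.01, 0.02))
  est <- mr_ivw(h, "fixed")
  w <- 1 / h$se_out^2
  expect_equal(est$beta, sum(w * h$beta_exp * h$beta_out) /
                 sum(w * h$beta_exp^2))
  orc <- oracle_wls(matrix(h$beta_exp), h$beta_out, w)
  expect_equal(est$beta, orc$coef, tolerance = 1e-12)
  expect_equal(est$se, orc$se_fixed, tolerance = 1e-12)

  # single row delegates to the Wald ratio
  one <- make_hset(0.1, 0.005, 0.02, 0.01)
  expect_equal(mr_ivw(one)$beta, wald_ratio(one)$beta)

  # identical ratios: beta is that ratio for both effects models, Q = 0,
  # and the standard errors coincide
  hom <- make_hset(c(0.1, 0.2, 0.4), 0.005, c(0.03, 0.06, 0.12), 0.01)
  fx <- mr_ivw(hom, "fixed"); rd <- mr_ivw(hom, "random")
  expect_equal(fx$beta, 0.3)
  expect_equal(rd$beta, 0.3)
  expect_equal(fx$q, 0)
  expect_equal(fx$se, rd$se)

  # algebraic identity: IVW slope is the mean of Wald ratios weighted by
  # beta_exp^2 / se_out^2
  set.seed(11)
  hr <- make_hset(runif(8, 0.05, 0.2), 0.005, rnorm(8, 0.02, 0.01),
                  runif(8, 0.005, 0.02))
  wr <- hr$beta_out / hr$beta_exp
  ww <- hr$beta_exp^2 / hr$se_out^2
  expect_equal(mr_ivw(hr, "fixed")$beta, sum(ww * wr) / sum(ww))
})

test_that("MR-Egger matches an independent WLS oracle and its limits", {
  # rows exactly on a line through the origin: intercept 0, slope the ratio
  hom <- make_hset(c(0.1, 0.2, 0.4), 0.005, c(0.03, 0.06, 0.12), 0.01)
  eg <- mr_egger(hom)
  expect_equal(eg$intercept, 0, tolerance = 1e-12)
  expect_equal(eg$beta, 0.3, tolerance = 1e-12)

  # three constructed rows against the lm-based WLS oracle (after the
  # non-negative exposure orientation)
  h <- make_hset(c(0.1, -0.2, 0.35), 0.005, c(0.025, -0.055, 0.09),
                 c(0.01, 0.02, 0.015))
  flip <- sign(h$beta_exp)
  orc <- oracle_wls(matrix(h$beta_exp * flip), h$beta_out * flip,
                    1 / h$se_out^2, intercept = TRUE)
  eg2 <- mr_egger(h)
  expect_equal(eg2$intercept, orc$coef[1], tolerance = 1e-10)
  expect_equal(eg2$beta, orc$coef[2], tolerance = 1e-10)
  q <- sum((orc$resid)^2 / h$se_out^2)
  mult <- max(1, sqrt(q / (3 - 2)))
  expect_equal(eg2$se, orc$se_fixed[2] * mult, tolerance = 1e-10)
  expect_equal(eg2$intercept_se, orc$se_fixed[1] * mult, tolerance = 1e-10)

  # affine equivariance: shifting all outcome betas of equal-weight rows by
  # c moves the intercept by c, slope unchanged
  hw <- make_hset(c(0.1, 0.2, 0.3, 0.4), 0.005,
                  c(0.02, 0.05, 0.055, 0.09), 0.01)
  base <- mr_egger(hw)
  shifted <- hw; shifted$beta_out <- shifted$beta_out + 0.01
  sh <- mr_egger(shifted)
  expect_equal(sh$intercept, base$intercept + 0.01, tolerance = 1e-10)
  expect_equal(sh$beta, base$beta, tolerance = 1e-10)

  expect_error(mr_egger(hom[1:2, ]), ">= 3")

  # constraining the intercept to zero reproduces IVW
  orc0 <- oracle_wls(matrix(h$beta_exp * flip), h$beta_out * flip,
                     1 / h$se_out^2, intercept = FALSE)
  expect_equal(mr_ivw(h, "fixed")$beta, orc0$coef, tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative weight and is stable", {
  # equal weights, odd count: the middle order statistic
  h <- make_hset(c(0.1, 0.1, 0.1), 0.005, c(0.01, 0.02, 0.09), 0.01)
  wm <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 0.2)  # ratios 0.1, 0.2, 0.9

  # unequal weights against the brute-force cumulative-weight oracle;
  # ratios {0.1, 0.2, 0.9} with normalized weights {0.5, 0.3, 0.2}
  # interpolate to 0.1625 at the 0.5 boundary
  w_target <- c(0.5, 0.3, 0.2)
  se_out <- 0.01 / sqrt(w_target)   # ratio weights 1/se(ratio)^2
  h2 <- make_hset(c(0.1, 0.1, 0.1), 0.005,
                  c(0.01, 0.02, 0.09), se_out / 0.1 * 0.01)
  wt_se <- h2$se_out / abs(h2$beta_exp)
  expect_equal((1 / wt_se^2) / sum(1 / wt_se^2), w_target)
  wm2 <- mr_weighted_median(h2, n_boot = 200, seed = 1)
  expect_equal(wm2$beta,
               oracle_weighted_median(h2$beta_out / h2$beta_exp,
                                      1 / wt_se^2),
               tolerance = 1e-12)
  expect_equal(wm2$beta, 0.1625)

  # bootstrap se reproducible for a fixed seed and stable across seeds
  set.seed(99)
  hb <- make_hset(runif(20, 0.05, 0.2), 0.005, rnorm(20, 0.02, 0.02),
                  runif(20, 0.005, 0.02))
  a <- mr_weighted_median(hb, n_boot = 5000, seed = 7)
  b <- mr_weighted_median(hb, n_boot = 5000, seed = 7)
  c <- mr_weighted_median(hb, n_boot = 5000, seed = 8)
  expect_identical(a$se, b$se)
  expect_equal(a$se, c$se, tolerance = 0.05)
  expect_error(mr_weighted_median(h[1:2, ]), ">= 3")
})

test_that("mode estimators maximize the kernel density of the ratios", {
  # tight cluster at 0.1 plus an outlier: argmax near the cluster,
  # matching a brute-force grid search
  h <- make_hset(rep(0.1, 4), 0.005,
                 c(0.01, 0.011, 0.012, 0.05), 0.01)
  sm <- mr_mode(h, "simple", n_boot = 100, seed = 1)
  r <- h$beta_out / h$beta_exp
  bw <- 0.9 * min(sd(r), mad(r)) * length(r)^(-1 / 5)
  expect_equal(sm$beta, oracle_mode_grid(r, rep(0.25, 4), bw),
               tolerance = 1e-6)
  expect_lt(abs(sm$beta - 0.11), 0.05)

  # weighted variant with nearly all weight on one SNP returns its ratio
  hw <- make_hset(rep(0.1, 3), 0.005, c(0.01, 0.03, 0.05),
                  c(1e-5, 10, 10))
  wm <- mr_mode(hw, "weighted", n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.1, tolerance = 1e-3)

  # all ratios equal: point mass, se 0
  hz <- make_hset(c(0.1, 0.2, 0.4), 0.005, c(0.03, 0.06, 0.12), 0.01)
  mz <- mr_mode(hz, "simple", n_boot = 50, seed = 1)
  expect_equal(mz$beta, 0.3)
  expect_equal(mz$se, 0)

  expect_error(mr_mode(h[1:2, ], "simple"), ">= 3")
})

test_that("estimators agree on clean simulated data and ignore row order", {
  sim <- simulate_triple(sim_config(n_snps_instrument = 120,
                                    n_snps_instrument_med = 1,
                                    n_snps_null = 10,
                                    a = 0, b = 0, c_direct = 0.1,
                                    palindromic_fraction = 0,
                                    allele_flip_fraction = 0,
                                    seed = 21))
  h <- harmonize(sim$exposure, sim$outcome)
  d <- harmonized_rows(h)
  d <- d[order(-abs(d$beta_exp)), ][1:80, ]  # strong instruments
  ests <- mr_all(d, n_boot = 300, seed = 5)
  pts <- ests$beta[ests$method %in%
                     c("ivw", "mr_egger", "weighted_median",
                       "simple_mode", "weighted_mode")]
  expect_true(all(abs(pts - 0.1) < 0.05))

  # equivariance to row reordering
  perm <- d[sample(nrow(d)), ]
  expect_equal(mr_ivw(perm, "fixed")$beta, mr_ivw(d, "fixed")$beta)
  expect_equal(mr_egger(perm)$beta, mr_egger(d)$beta)
  expect_equal(mr_weighted_median(perm, n_boot = 2, seed = 1)$beta,
               mr_weighted_median(d, n_boot = 2, seed = 1)$beta)
})
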