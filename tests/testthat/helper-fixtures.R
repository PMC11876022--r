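# Fixture builders and independent oracles used across the test files.

# Quick summary-statistics builder with sensible defaults.
make_sumstats <- function(snp, beta, se, eaf = 0.3, pval = NULL, n = 1e5,
                          chr = "1", pos = NULL, effect_allele = "A",
                          other_allele = "G", trait = "trait") {
  k <- length(snp)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  if (is.null(pos)) pos <- seq_len(k) * 2e7
  summary_stats(data.frame(
    snp = snp, chr = rep_len(chr, k), pos = rep_len(pos, k),
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k), beta = beta, se = se,
    pval = pmax(pval, 1e-300), n = rep_len(n, k),
    stringsAsFactors = FALSE), trait_id = trait)
}

# Plain harmonized-style data.frame for the estimators (bypasses allele
# bookkeeping when only the regression is under test).
make_hset <- function(bx, sx, by, sy, eaf_exp = 0.3, eaf_out = 0.3,
                      n_exp = 1e5, n_out = 1e5) {
  k <- length(bx)
  data.frame(snp = sprintf("rs%03d", seq_len(k)),
             beta_exp = bx, se_exp = rep_len(sx, k),
             beta_out = by, se_out = rep_len(sy, k),
             eaf_exp = rep_len(eaf_exp, k), eaf_out = rep_len(eaf_out, k),
             n_exp = rep_len(n_exp, k), n_out = rep_len(n_out, k),
             stringsAsFactors = FALSE)
}

# Identity LD matrix over a SNP table.
make_identity_ld <- function(stats) {
  d <- as.data.frame(stats)
  ld_matrix(diag(nrow(d)), d[, c("snp", "chr", "pos")], snp_ids = d$snp)
}

# Independent weighted-least-squares oracle via stats::lm. Returns the
# coefficients and the fixed-effects standard errors (residual variance
# divided out), the closed form the estimators must reproduce.
oracle_wls <- function(X, y, w, intercept = FALSE) {
  d <- data.frame(y = y, X)
  f <- if (intercept) y ~ . else y ~ . + 0
  fit <- stats::lm(f, data = d, weights = w)
  sigma <- summary(fit)$sigma
  list(coef = unname(stats::coef(fit)),
       se_fixed = unname(sqrt(diag(stats::vcov(fit))) / sigma),
       resid = unname(stats::residuals(fit)))
}

# Brute-force cumulative-weight scan for the weighted median.
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  n <- length(r)
  if (p[n] <= 0.5) return(r[n])
  m <- max(which(p < 0.5))
  r[m] + (r[m + 1] - r[m]) * (0.5 - p[m]) / (p[m + 1] - p[m])
}

# Brute-force density maximization by successive grid refinement.
oracle_mode_grid <- function(r, w, h) {
  dens <- function(x) vapply(x, function(xi) sum(w * dnorm(xi, r, h)), 0)
  lo <- min(r) - 3 * h
  hi <- max(r) + 3 * h
  for (round in 1:6) {
    grid <- seq(lo, hi, length.out = 4001)
    i <- which.max(dens(grid))
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
  }
  (lo + hi) / 2
}

# Combine independently simulated triples into one world sharing a single
# outcome table and a block-diagonal LD matrix, so a panel of exposures
# with known architectures can be screened against one outcome. SNP ids
# are prefixed per sim to stay unique.
merge_sims <- function(sims) {
  stopifnot(length(sims) >= 1)
  exposures <- list()
  out_rows <- list()
  lds <- list()
  for (i in seq_along(sims)) {
    s <- sims[[i]]
    pre <- sprintf("s%d_", i)
    rename <- function(tab, trait) {
      d <- as.data.frame(tab)
      d$snp <- paste0(pre, d$snp)
      summary_stats(d, trait_id = trait)
    }
    exposures[[i]] <- rename(s$exposure, paste0("exp_", i))
    out_rows[[i]] <- as.data.frame(rename(s$outcome, "outcome"))
    ld <- s$ld
    ld$snp_ids <- paste0(pre, ld$snp_ids)
    dimnames(ld$r2) <- list(ld$snp_ids, ld$snp_ids)
    ld$positions$snp <- paste0(pre, ld$positions$snp)
    # keep loci physically apart across sims
    ld$positions$pos <- ld$positions$pos + (i - 1) * 7e8
    lds[[i]] <- ld
  }
  k <- sum(vapply(lds, function(l) length(l$snp_ids), 0L))
  r2 <- diag(k)
  ids <- unlist(lapply(lds, `[[`, "snp_ids"))
  at <- 0
  for (l in lds) {
    idx <- at + seq_along(l$snp_ids)
    r2[idx, idx] <- l$r2
    at <- at + length(l$snp_ids)
  }
  dimnames(r2) <- list(ids, ids)
  pos <- do.call(rbind, lapply(lds, `[[`, "positions"))
  outcome <- do.call(rbind, out_rows)
  list(exposures = exposures,
       outcome = summary_stats(outcome, trait_id = "outcome"),
       ld = ld_matrix(r2, pos, snp_ids = ids))
}
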