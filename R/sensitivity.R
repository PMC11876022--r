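#' Cochran Q heterogeneity test and I-squared
#'
#' `Q = sum w_i (beta_out_i - slope * beta_exp_i)^2` with `w_i = 1/se_out_i^2`
#' on `nsnp - 1` degrees of freedom (the IVW slope is the one fitted
#' parameter). `I2 = max(0, (Q - df)/Q)` is the fraction of the variation
#' across instruments attributable to heterogeneity rather than sampling
#' error, labelled none (0), mild (0-25\%], moderate (25-50\%], high
#' (>50\%).
#'
#' @param h Harmonized set with at least two estimable rows.
#' @param slope Causal slope about which residuals are taken; defaults to
#'   the fixed-effects IVW estimate.
#' @return List `q`, `q_df`, `q_pval` (chi-squared upper tail), `i2`,
#'   `severity`.
#' @export
cochran_q <- function(h, slope = NULL) {
  d <- harmonized_rows(h)
  if (nrow(d) < 2) stop("Cochran Q needs >= 2 SNPs", call. = FALSE)
  if (is.null(slope)) slope <- mr_ivw(d, "fixed")$beta
  w <- 1 / d$se_out^2
  q <- sum(w * (d$beta_out - slope * d$beta_exp)^2)
  q_df <- nrow(d) - 1
  i2 <- if (q > 0) max(0, (q - q_df) / q) else 0
  severity <- if (i2 == 0) "none" else if (i2 <= 0.25) "mild"
              else if (i2 <= 0.5) "moderate" else "high"
  list(q = q, q_df = q_df,
       q_pval = stats::pchisq(q, q_df, lower.tail = FALSE),
       i2 = i2, severity = severity)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' @param h Harmonized set with at least three estimable rows (fewer is an
#'   error: the intercept test is not computable, matching the convention of
#'   excluding sub-3-SNP instruments from pleiotropy testing).
#' @param alpha Significance level for the `pleiotropic` flag, default 0.05.
#' @return List `intercept`, `se`, `pval`, `pleiotropic`.
#' @export
egger_intercept_test <- function(h, alpha = 0.05) {
  fit <- mr_egger(h)
  list(intercept = fit$intercept, se = fit$intercept_se,
       pval = fit$intercept_pval,
       pleiotropic = fit$intercept_pval < alpha)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimate with each SNP excluded in turn, under the same
#' fixed/random effects-model switch as the full fit.
#'
#' @param h Harmonized set with at least three estimable rows.
#' @param het_p_switch Heterogeneity p-value below which a refit uses
#'   multiplicative random effects, default 0.05.
#' @param flag_se_mult Flag a SNP when removing it moves the estimate by
#'   more than this multiple of the full-fit standard error; default 2.
#' @return data.frame `snp`, `beta_without`, `se_without`, `pval_without`,
#'   `flagged`, with attribute `beta_all` (the all-SNP estimate).
#' @export
leave_one_out <- function(h, het_p_switch = 0.05, flag_se_mult = 2) {
  d <- harmonized_rows(h)
  if (nrow(d) < 3) stop("leave-one-out needs >= 3 SNPs", call. = FALSE)
  ivw_switched <- function(dd) {
    fixed <- mr_ivw(dd, "fixed")
    if (fixed$q_pval < het_p_switch) mr_ivw(dd, "random") else fixed
  }
  full <- ivw_switched(d)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    fit <- ivw_switched(d[-i, , drop = FALSE])
    data.frame(snp = d$snp[i], beta_without = fit$beta,
               se_without = fit$se, pval_without = fit$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- abs(out$beta_without - full$beta) > flag_se_mult * full$se
  attr(out, "beta_all") <- full$beta
  out
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against
#' the variance they explain in the outcome. Instruments acting through the
#' exposure should explain more of it than of the downstream outcome;
#' `direction_correct` is `r2_exposure > r2_outcome`. The p-value compares
#' the implied correlations (`sqrt(r2)`) via Fisher's z transform with the
#' two sample sizes.
#'
#' @param h Harmonized set; rows need `eaf_exp`, `eaf_out`, `n_exp`,
#'   `n_out` (as produced by [harmonize()]).
#' @return List `r2_exposure`, `r2_outcome`, `direction_correct`,
#'   `steiger_pval`.
#' @export
steiger_test <- function(h) {
  d <- harmonized_rows(h)
  needed <- c("eaf_exp", "eaf_out", "n_exp", "n_out")
  if (!all(needed %in% names(d)) || anyNA(d[needed])) {
    stop("Steiger test needs allele frequencies and sample sizes on both sides",
         call. = FALSE)
  }
  r2_exp <- min(sum(variance_explained(d$beta_exp, d$eaf_exp)), 1)
  r2_out <- min(sum(variance_explained(d$beta_out, d$eaf_out)), 1)
  n_exp <- stats::median(d$n_exp)
  n_out <- stats::median(d$n_out)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(r2_exposure = r2_exp, r2_outcome = r2_out,
       direction_correct = r2_exp > r2_out,
       steiger_pval = 2 * stats::pnorm(-abs(z)))
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratios against their precision (1/se of the ratio).
#' Asymmetry of the funnel suggests directional pleiotropy; the table is
#' exported for plotting, not formally tested.
#'
#' @param h Harmonized set.
#' @return data.frame `snp`, `ratio`, `precision`.
#' @export
funnel_data <- function(h) {
  d <- harmonized_rows(h)
  wt <- wald_terms(d)
  data.frame(snp = d$snp, ratio = wt$ratio, precision = 1 / wt$se,
             stringsAsFactors = FALSE)
}

#' Full sensitivity battery for one harmonized pair
#'
#' Bundles [cochran_q()], [egger_intercept_test()], [leave_one_out()],
#' [steiger_test()] and [funnel_data()]. Components that need more SNPs
#' than are available (pleiotropy and leave-one-out below three) are
#' returned as `NULL` with a note in `skipped`.
#'
#' @param h Harmonized set.
#' @param alpha Significance level for flags.
#' @return List of class `mr_sensitivity`.
#' @export
sensitivity_report <- function(h, alpha = 0.05) {
  d <- harmonized_rows(h)
  rep <- list(nsnp = nrow(d), skipped = character(0))
  rep$heterogeneity <- if (nrow(d) >= 2) cochran_q(d) else NULL
  if (nrow(d) >= 3) {
    rep$pleiotropy <- egger_intercept_test(d, alpha = alpha)
    rep$loo <- leave_one_out(d)
  } else {
    rep$pleiotropy <- NULL
    rep$loo <- NULL
    rep$skipped <- c(rep$skipped, "pleiotropy and leave-one-out need >= 3 SNPs")
  }
  rep$steiger <- tryCatch(steiger_test(d), error = function(e) {
    rep$skipped <<- c(rep$skipped, conditionMessage(e))
    NULL
  })
  rep$funnel <- funnel_data(d)
  class(rep) <- "mr_sensitivity"
  rep
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity report (%d SNPs)\n", x$nsnp))
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("  Cochran Q = %.4g (df %d, p = %.4g), I2 = %.1f%% (%s)\n",
                x$heterogeneity$q, x$heterogeneity$q_df, x$heterogeneity$q_pval,
                100 * x$heterogeneity$i2, x$heterogeneity$severity))
  }
  if (!is.null(x$pleiotropy)) {
    cat(sprintf("  Egger intercept = %.4g (p = %.4g)%s\n",
                x$pleiotropy$intercept, x$pleiotropy$pval,
                if (x$pleiotropy$pleiotropic) " [pleiotropic]" else ""))
  }
  if (!is.null(x$steiger)) {
    cat(sprintf("  Steiger: r2_exp = %.3g, r2_out = %.3g, direction %s (p = %.4g)\n",
                x$steiger$r2_exposure, x$steiger$r2_outcome,
                x$steiger$direction_correct, x$steiger$steiger_pval))
  }
  for (s in x$skipped) cat("  skipped:", s, "\n")
  invisible(x)
}

#' Serialize a sensitivity report to JSON (plus TSV side tables)
#'
#' Writes the scalar report as JSON; the leave-one-out and funnel tables go
#' to `<path>.loo.tsv` and `<path>.funnel.tsv`.
#' @param x An `mr_sensitivity` report.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(x, path) {
  scalars <- x[c("nsnp", "heterogeneity", "pleiotropy", "steiger", "skipped")]
  jsonlite::write_json(scalars, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(x$loo)) write_tsv(x$loo, paste0(path, ".loo.tsv"))
  write_tsv(x$funnel, paste0(path, ".funnel.tsv"))
  invisible(path)
}
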