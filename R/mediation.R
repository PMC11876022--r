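#' Product-of-coefficients mediation effect
#'
#' The indirect (mediated) effect of an exposure on an outcome through a
#' mediator is the product of the exposure-to-mediator effect `beta_a` and
#' the mediator-to-outcome direct effect `beta_b`, with the delta-method
#' standard error `sqrt((beta_a*se_b)^2 + (beta_b*se_a)^2)`.
#'
#' @param beta_a,se_a Exposure-to-mediator effect (univariate MR) and its
#'   standard error.
#' @param beta_b,se_b Mediator-to-outcome direct effect (from multivariable
#'   MR) and its standard error.
#' @return List `beta_m`, `se_m`.
#' @export
mediation_effect <- function(beta_a, se_a, beta_b, se_b) {
  stopifnot(se_a > 0, se_b > 0)
  list(beta_m = beta_a * beta_b,
       se_m = sqrt((beta_a * se_b)^2 + (beta_b * se_a)^2))
}

#' Sobel test of an indirect effect
#'
#' @param beta_m Indirect effect.
#' @param se_m Its standard error ([mediation_effect()]).
#' @return List `z = beta_m/se_m`, two-sided normal `pval`, and `degenerate`
#'   (TRUE when `se_m = 0` with a non-zero effect, reported with `pval = 0`).
#' @export
sobel_test <- function(beta_m, se_m) {
  if (se_m == 0) {
    if (beta_m == 0) return(list(z = 0, pval = 1, degenerate = FALSE))
    return(list(z = sign(beta_m) * Inf, pval = 0, degenerate = TRUE))
  }
  z <- beta_m / se_m
  list(z = z, pval = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Stepwise significance classification of a mediation model
#'
#' Implements the causal stepwise decision tree on the components of a
#' product-of-coefficients mediation model:
#' \enumerate{
#'   \item The indirect effect is significant if both `beta_a` and `beta_b`
#'     are significant at `alpha`; when either is not, the Sobel test
#'     decides.
#'   \item Given a significant indirect effect: a non-significant direct
#'     effect (`beta_c_direct`, the exposure's multivariable-MR effect on
#'     the outcome) means complete mediation; a significant direct effect
#'     of opposite sign to the indirect effect is a covering (suppression)
#'     effect with ratio `|beta_m / beta_c_direct| * 100`; matching signs
#'     give partial mediation with proportion
#'     `beta_m / beta_c_total * 100` (denominator: the univariate total
#'     effect).
#'   \item A non-significant indirect effect is no mediation.
#' }
#'
#' @param p_a,p_b Component p-values (exposure-to-mediator, mediator-to-
#'   outcome direct).
#' @param beta_m Indirect effect; `sobel_pval` its Sobel p-value.
#' @param beta_c_direct,p_c_direct Exposure-to-outcome direct effect
#'   (multivariable MR) and p-value.
#' @param beta_c_total Exposure-to-outcome total effect (univariate MR).
#' @param alpha Significance level, default 0.05.
#' @return List `classification` (one of `"complete-mediation"`,
#'   `"partial-mediation"`, `"covering-effect"`, `"no-mediation"`) and
#'   `proportion` (percent; `NA` unless partial mediation or covering
#'   effect).
#' @export
classify_mediation <- function(p_a, p_b, beta_m, sobel_pval,
                               beta_c_direct, p_c_direct, beta_c_total,
                               alpha = 0.05) {
  vals <- c(p_a, p_b, beta_m, sobel_pval, beta_c_direct, p_c_direct,
            beta_c_total)
  if (anyNA(vals)) stop("missing component estimate: not classifiable", call. = FALSE)
  indirect_sig <- (p_a < alpha && p_b < alpha) || sobel_pval < alpha
  if (!indirect_sig) {
    return(list(classification = "no-mediation", proportion = NA_real_))
  }
  if (p_c_direct >= alpha) {
    return(list(classification = "complete-mediation", proportion = NA_real_))
  }
  if (sign(beta_m) != sign(beta_c_direct)) {
    list(classification = "covering-effect",
         proportion = abs(beta_m / beta_c_direct) * 100)
  } else {
    list(classification = "partial-mediation",
         proportion = beta_m / beta_c_total * 100)
  }
}

#' Estimate one exposure-mediator-outcome mediation model
#'
#' Runs the full component chain for a single triple: univariate IVW for the
#' exposure-to-mediator path (`beta_a`) and the exposure-to-outcome total
#' effect (`beta_c_total`); a two-exposure multivariable MR of the outcome
#' on exposure and mediator for the direct effects (`beta_c_direct` for the
#' exposure, `beta_b` for the mediator); then the product-of-coefficients
#' indirect effect, Sobel test and stepwise classification.
#'
#' Univariate fits use the fixed-effects IVW unless heterogeneity
#' (Cochran Q p < `het_p_switch`) switches them to multiplicative random
#' effects.
#'
#' @param exposure,mediator,outcome [summary_stats()] objects.
#' @param ld An [ld_matrix()] covering the candidate instruments.
#' @param config Pipeline configuration, see [mr_config()].
#' @param model_id Label for the model.
#' @return List of class `mr_mediation` with the component estimates
#'   (`beta_a`, `se_a`, `p_a`, `beta_b`, `se_b`, `p_b`, `beta_m`, `se_m`,
#'   `sobel_z`, `sobel_pval`, `beta_c_total`, `se_c_total`, `p_c_total`,
#'   `beta_c_direct`, `se_c_direct`, `p_c_direct`), the trait ids, `nsnp`
#'   counts, `classification` and `proportion`.
#' @export
estimate_mediation <- function(exposure, mediator, outcome, ld,
                               config = mr_config(), model_id = "model") {
  ivw_switched <- function(h) {
    d <- harmonized_rows(h)
    if (nrow(d) == 1) return(wald_ratio(d))
    fixed <- mr_ivw(d, "fixed")
    if (fixed$q_pval < config$het_p_switch) mr_ivw(d, "random") else fixed
  }
  uni <- function(exp_stats, out_stats) {
    ins <- select_instruments(exp_stats, ld,
                              p_thresh = config$p_thresh,
                              r2_thresh = config$r2_thresh,
                              window_kb = config$window_kb,
                              f_min = config$f_min,
                              f_k_mode = config$f_k_mode,
                              r2_formula = config$r2_formula)
    if (ins$k < 1) stop("no instrument for ", trait_id(exp_stats), call. = FALSE)
    keep <- as.data.frame(exp_stats)
    keep <- keep[keep$snp %in% ins$snps$snp, , drop = FALSE]
    h <- harmonize(summary_stats(keep, trait_id = trait_id(exp_stats)),
                   out_stats,
                   palindrome_policy = config$palindrome_policy,
                   eaf_window = config$eaf_window)
    ivw_switched(h)
  }

  fit_a <- uni(exposure, mediator)       # exposure -> mediator
  fit_c <- uni(exposure, outcome)        # exposure -> outcome (total)

  snps <- select_mvmr_instruments(list(exposure, mediator), ld,
                                  p_thresh = config$p_thresh,
                                  r2_thresh = config$r2_thresh,
                                  window_kb = config$window_kb)
  mv_in <- harmonize_mvmr(list(exposure, mediator), outcome, snps,
                          palindrome_policy = config$palindrome_policy,
                          eaf_window = config$eaf_window)
  mv <- mvmr_ivw(mv_in, model_id = model_id)
  est <- mv$estimates

  med <- mediation_effect(fit_a$beta, fit_a$se, est$beta[2], est$se[2])
  sob <- sobel_test(med$beta_m, med$se_m)
  cls <- classify_mediation(
    p_a = fit_a$pval, p_b = est$pval[2],
    beta_m = med$beta_m, sobel_pval = sob$pval,
    beta_c_direct = est$beta[1], p_c_direct = est$pval[1],
    beta_c_total = fit_c$beta, alpha = config$alpha)

  res <- list(
    model_id = model_id,
    exposure_id = trait_id(exposure),
    mediator_id = trait_id(mediator),
    outcome_id = trait_id(outcome),
    beta_a = fit_a$beta, se_a = fit_a$se, p_a = fit_a$pval,
    nsnp_a = fit_a$nsnp,
    beta_b = est$beta[2], se_b = est$se[2], p_b = est$pval[2],
    beta_m = med$beta_m, se_m = med$se_m,
    sobel_z = sob$z, sobel_pval = sob$pval,
    beta_c_total = fit_c$beta, se_c_total = fit_c$se, p_c_total = fit_c$pval,
    beta_c_direct = est$beta[1], se_c_direct = est$se[1],
    p_c_direct = est$pval[1],
    nsnp_mvmr = mv$nsnp,
    classification = cls$classification,
    proportion = cls$proportion)
  class(res) <- "mr_mediation"
  res
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf("Mediation model %s: %s -> %s -> %s\n", x$model_id,
              x$exposure_id, x$mediator_id, x$outcome_id))
  cat(sprintf("  beta_a = %.6g (p = %.4g), beta_b = %.6g (p = %.4g)\n",
              x$beta_a, x$p_a, x$beta_b, x$p_b))
  cat(sprintf("  indirect beta_m = %.6g (se %.6g), Sobel p = %.4g\n",
              x$beta_m, x$se_m, x$sobel_pval))
  cat(sprintf("  total = %.6g (p = %.4g), direct = %.6g (p = %.4g)\n",
              x$beta_c_total, x$p_c_total, x$beta_c_direct, x$p_c_direct))
  cat(sprintf("  classification: %s%s\n", x$classification,
              if (!is.na(x$proportion)) sprintf(" (%.1f%%)", x$proportion) else ""))
  invisible(x)
}

#' Flatten mediation results to a table
#'
#' One row per model with the component effects, 95\% confidence bounds
#' (`beta +/- 1.96 se`), Sobel test, classification and proportion.
#'
#' @param results List of `mr_mediation` objects (or a single one).
#' @return data.frame.
#' @export
mediation_table <- function(results) {
  if (inherits(results, "mr_mediation")) results <- list(results)
  ci <- function(b, s) sprintf("(%.6f, %.6f)", b - 1.96 * s, b + 1.96 * s)
  rows <- lapply(results, function(x) {
    data.frame(
      model = x$model_id, exposure = x$exposure_id, mediator = x$mediator_id,
      outcome = x$outcome_id,
      beta_a = x$beta_a, ci_a = ci(x$beta_a, x$se_a),
      beta_b = x$beta_b, ci_b = ci(x$beta_b, x$se_b),
      beta_m = x$beta_m, ci_m = ci(x$beta_m, x$se_m),
      beta_c_direct = x$beta_c_direct,
      ci_c_direct = ci(x$beta_c_direct, x$se_c_direct),
      beta_c_total = x$beta_c_total,
      ci_c_total = ci(x$beta_c_total, x$se_c_total),
      sobel_z = x$sobel_z, sobel_pval = x$sobel_pval,
      classification = x$classification, proportion = x$proportion,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
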