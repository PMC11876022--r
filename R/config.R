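#' Pipeline configuration
#'
#' Collects the tunable parameters shared by the screening and mediation
#' workflows. Defaults follow the conventional two-sample MR workflow:
#' genome-wide significance at `5e-8`, LD independence at r-squared 0.001
#' within a 10,000 kb window, F >= 10 instrument strength, palindromic SNPs
#' dropped when the exposure allele frequency is in \[0.42, 0.58\], raw
#' p < 0.05 at every screening gate with no multiple-testing correction,
#' and the headline IVW switching to multiplicative random effects when
#' Cochran Q has p < 0.05.
#'
#' @param p_thresh Instrument significance threshold.
#' @param r2_thresh,window_kb Clumping parameters.
#' @param f_min Minimum instrument F.
#' @param f_k_mode See [select_instruments()].
#' @param r2_formula See [variance_explained()].
#' @param palindrome_policy,eaf_window See [harmonize()].
#' @param alpha Screening / classification significance level.
#' @param het_p_switch Cochran Q p-value below which IVW uses random
#'   effects.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param bandwidth_factor Mode-estimator bandwidth multiplier.
#' @param seed Seed for the bootstrap estimators.
#' @param p_adjust Multiple-testing adjustment applied to screening
#'   p-values; `"none"` (default, matching the raw-p workflow) or any
#'   method of [stats::p.adjust()].
#' @return List of class `mr_config`.
#' @export
mr_config <- function(p_thresh = 5e-8, r2_thresh = 0.001, window_kb = 10000,
                      f_min = 10, f_k_mode = "single",
                      r2_formula = "standard",
                      palindrome_policy = "drop-ambiguous",
                      eaf_window = c(0.42, 0.58),
                      alpha = 0.05, het_p_switch = 0.05,
                      n_boot = 5000, bandwidth_factor = 1, seed = NULL,
                      p_adjust = "none") {
  cfg <- list(p_thresh = p_thresh, r2_thresh = r2_thresh,
              window_kb = window_kb, f_min = f_min, f_k_mode = f_k_mode,
              r2_formula = r2_formula,
              palindrome_policy = palindrome_policy, eaf_window = eaf_window,
              alpha = alpha, het_p_switch = het_p_switch, n_boot = n_boot,
              bandwidth_factor = bandwidth_factor, seed = seed,
              p_adjust = p_adjust)
  class(cfg) <- "mr_config"
  cfg
}
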