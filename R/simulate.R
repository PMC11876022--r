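#' Configuration for the synthetic GWAS generator
#'
#' Describes a known exposure -> mediator -> outcome causal structure from
#' which per-trait GWAS summary statistics are generated. Effects are on a
#' standardized (log-odds for binary traits) scale so the analytic standard
#' error `1/sqrt(2 n maf (1-maf))` applies.
#'
#' Exposure instruments have true exposure effects drawn from
#' `normal(0, beta_gx_scale)` truncated to reach genome-wide significance
#' (`p < 5e-8`) at `n_exp`; their mediator effects are `a` times the
#' exposure effect and their outcome effects `(c_direct + a*b)` times it,
#' plus `pleiotropy_intercept` and heterogeneity noise. Mediator-specific
#' instruments (truncated the same way against `n_med`) have zero exposure
#' effect and outcome effect `b` times their mediator effect; they are what
#' makes the mediator's direct effect identifiable in multivariable MR.
#' Null SNPs have zero true effect everywhere.
#'
#' @param n_snps_instrument Exposure instrument count.
#' @param n_snps_instrument_med Mediator-specific instrument count
#'   (defaults to `n_snps_instrument`).
#' @param n_snps_null Null SNP count.
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param maf_range Interval for the uniform minor-allele-frequency draw.
#' @param beta_gx_scale SD of the (untruncated) instrument effect on its
#'   own trait. The default 0.05 puts observed per-allele effects in the
#'   1e-3 to 1e-1 range typical of large anthropometric and molecular
#'   GWAS, with instrument z-scores spread well above the significance
#'   threshold rather than piled up against it.
#' @param a Exposure-to-mediator causal effect.
#' @param b Mediator-to-outcome causal effect.
#' @param c_direct Exposure-to-outcome direct effect.
#' @param pleiotropy_intercept Constant added to every instrument's true
#'   outcome effect (directional pleiotropy; what the MR-Egger intercept
#'   estimates).
#' @param heterogeneity_sd SD of per-SNP noise added to the true mediator
#'   and outcome effects (balanced effect heterogeneity).
#' @param palindromic_fraction Fraction of SNPs given A/T or C/G allele
#'   pairs.
#' @param allele_flip_fraction Fraction of rows in the mediator and outcome
#'   tables coded on the opposite allele (beta negated, frequency
#'   complemented) to exercise harmonization.
#' @param ld_block_size,ld_block_r2 Size of correlated LD blocks and their
#'   within-block r-squared; block size 1 gives an identity LD matrix.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `mr_sim_config`.
#' @export
sim_config <- function(n_snps_instrument = 50,
                       n_snps_instrument_med = n_snps_instrument,
                       n_snps_null = 50,
                       n_exp = 300000, n_med = 300000, n_out = 300000,
                       maf_range = c(0.05, 0.5),
                       beta_gx_scale = 0.05,
                       a = 0.1, b = 0.07, c_direct = 0,
                       pleiotropy_intercept = 0,
                       heterogeneity_sd = 0,
                       palindromic_fraction = 0.1,
                       allele_flip_fraction = 0.1,
                       ld_block_size = 1, ld_block_r2 = 0.3,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_snps_instrument >= 1, cfg$n_snps_null >= 0,
            cfg$n_exp > 0, cfg$n_med > 0, cfg$n_out > 0,
            length(cfg$maf_range) == 2,
            cfg$maf_range[1] > 0, cfg$maf_range[2] < 1,
            cfg$beta_gx_scale > 0, cfg$heterogeneity_sd >= 0,
            cfg$palindromic_fraction >= 0, cfg$palindromic_fraction <= 1,
            cfg$allele_flip_fraction >= 0, cfg$allele_flip_fraction <= 1,
            cfg$ld_block_size >= 1,
            cfg$ld_block_r2 >= 0, cfg$ld_block_r2 < 1)
  class(cfg) <- "mr_sim_config"
  cfg
}

# Draw from normal(0, scale) conditioned on |x| >= thresh (vectorized,
# exact inverse-CDF on the tail; random sign).
rtrunc_instrument <- function(scale, thresh) {
  p_tail <- stats::pnorm(thresh / scale, lower.tail = FALSE)
  if (any(p_tail < 1e-6)) {
    stop("beta_gx_scale too small: genome-wide significance unreachable ",
         "at this sample size / MAF (tail mass < 1e-6). Increase ",
         "beta_gx_scale or the sample size.", call. = FALSE)
  }
  n <- length(thresh)
  mag <- stats::qnorm(p_tail * stats::runif(n), lower.tail = FALSE) * scale
  mag * sample(c(-1, 1), n, replace = TRUE)
}

# Sample allele pairs; palindromic = A/T or C/G.
sample_alleles <- function(pal) {
  n <- length(pal)
  pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                      ncol = 2, byrow = TRUE)
  npal_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                         "G", "A", "G", "T", "T", "C", "T", "G"),
                       ncol = 2, byrow = TRUE)
  ea <- oa <- character(n)
  i <- sample(nrow(pal_pairs), n, replace = TRUE)
  j <- sample(nrow(npal_pairs), n, replace = TRUE)
  ea[pal] <- pal_pairs[i[pal], 1]; oa[pal] <- pal_pairs[i[pal], 2]
  ea[!pal] <- npal_pairs[j[!pal], 1]; oa[!pal] <- npal_pairs[j[!pal], 2]
  list(ea = ea, oa = oa)
}

#' Simulate GWAS summary statistics for an exposure-mediator-outcome triple
#'
#' Generates three per-SNP summary-statistics tables (exposure, mediator,
#' outcome), an LD matrix, and the true causal parameters, all reproducible
#' from `config$seed`. Observed betas are the true betas plus
#' `normal(0, se)` noise with the analytic `se = 1/sqrt(2 n maf (1-maf))`;
#' p-values are two-sided normal. A configurable fraction of rows in the
#' mediator and outcome tables is allele-flipped, and a fraction of SNPs is
#' palindromic, so harmonization is genuinely exercised.
#'
#' @param config A [sim_config()].
#' @return List with elements `exposure`, `mediator`, `outcome`
#'   ([summary_stats()] objects), `ld` ([ld_matrix()]), and `truth` (list
#'   `a`, `b`, `c_direct`, `total_effect = a*b + c_direct`,
#'   `pleiotropy_intercept`, `exposure_instruments`,
#'   `mediator_instruments`, plus the per-SNP true betas).
#' @export
simulate_triple <- function(config) {
  stopifnot(inherits(config, "mr_sim_config"))
  with_seed(config$seed, simulate_triple_impl(config))
}

simulate_triple_impl <- function(cfg) {
  n_ie <- cfg$n_snps_instrument
  n_im <- cfg$n_snps_instrument_med
  n_nu <- cfg$n_snps_null
  total <- n_ie + n_im + n_nu
  role <- rep(c("exp_ins", "med_ins", "null"), c(n_ie, n_im, n_nu))
  snp <- sprintf("rs%06d", seq_len(total))

  maf <- stats::runif(total, cfg$maf_range[1], cfg$maf_range[2])
  se_of <- function(n) 1 / sqrt(2 * n * maf * (1 - maf))
  se_exp <- se_of(cfg$n_exp)
  se_med <- se_of(cfg$n_med)
  se_out <- se_of(cfg$n_out)
  z_gws <- stats::qnorm(1 - 2.5e-8)   # two-sided p = 5e-8

  ie <- role == "exp_ins"
  im <- role == "med_ins"
  true_bx <- true_bm <- true_by <- numeric(total)
  true_bx[ie] <- rtrunc_instrument(cfg$beta_gx_scale, z_gws * se_exp[ie])
  true_bm[im] <- rtrunc_instrument(cfg$beta_gx_scale, z_gws * se_med[im])
  het <- function(k) stats::rnorm(k, 0, cfg$heterogeneity_sd)
  true_bm[ie] <- cfg$a * true_bx[ie] + het(sum(ie))
  # Directional pleiotropy is defined relative to the trait-raising allele
  # (sign(beta) orientation); a constant in the arbitrary coded-allele
  # orientation would cancel under the usual sign alignment.
  true_by[ie] <- (cfg$c_direct + cfg$a * cfg$b) * true_bx[ie] +
    cfg$pleiotropy_intercept * sign(true_bx[ie]) + het(sum(ie))
  true_by[im] <- cfg$b * true_bm[im] +
    cfg$pleiotropy_intercept * sign(true_bm[im]) + het(sum(im))

  # Genomic layout: one LD block per `ld_block_size` consecutive SNPs,
  # blocks cycled over 22 chromosomes and spaced far beyond any clumping
  # window; SNPs within a block sit 10 kb apart.
  block <- (seq_len(total) - 1) %/% cfg$ld_block_size
  within <- (seq_len(total) - 1) %% cfg$ld_block_size
  chr <- as.character((block %% 22) + 1)
  pos <- as.integer((block %/% 22) * 2e7 + 1e6 + within * 1e4)

  r2 <- diag(total)
  if (cfg$ld_block_size > 1) {
    for (g in unique(block)) {
      idx <- which(block == g)
      if (length(idx) > 1) {
        r2[idx, idx] <- cfg$ld_block_r2
        diag(r2)[idx] <- 1
      }
    }
  }
  dimnames(r2) <- list(snp, snp)
  ld <- ld_matrix(r2, data.frame(snp = snp, chr = chr, pos = pos,
                                 stringsAsFactors = FALSE))

  eaf <- ifelse(stats::runif(total) < 0.5, maf, 1 - maf)
  pal <- stats::runif(total) < cfg$palindromic_fraction
  al <- sample_alleles(pal)

  make_table <- function(true_beta, se, n, trait, flip) {
    beta <- true_beta + stats::rnorm(total, 0, se)
    ea <- al$ea; oa <- al$oa; f <- eaf
    ea[flip] <- al$oa[flip]; oa[flip] <- al$ea[flip]
    beta[flip] <- -beta[flip]; f[flip] <- 1 - f[flip]
    summary_stats(data.frame(
      snp = snp, chr = chr, pos = pos,
      effect_allele = ea, other_allele = oa,
      eaf = f, beta = beta, se = se,
      pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
      n = n, stringsAsFactors = FALSE), trait_id = trait)
  }
  no_flip <- rep(FALSE, total)
  flip_med <- stats::runif(total) < cfg$allele_flip_fraction
  flip_out <- stats::runif(total) < cfg$allele_flip_fraction

  list(
    exposure = make_table(true_bx, se_exp, cfg$n_exp, "sim-exposure", no_flip),
    mediator = make_table(true_bm, se_med, cfg$n_med, "sim-mediator", flip_med),
    outcome = make_table(true_by, se_out, cfg$n_out, "sim-outcome", flip_out),
    ld = ld,
    truth = list(a = cfg$a, b = cfg$b, c_direct = cfg$c_direct,
                 total_effect = cfg$a * cfg$b + cfg$c_direct,
                 pleiotropy_intercept = cfg$pleiotropy_intercept,
                 exposure_instruments = snp[ie],
                 mediator_instruments = snp[im],
                 true_beta_exposure = true_bx,
                 true_beta_mediator = true_bm,
                 true_beta_outcome = true_by))
}

#' Write a simulated triple to disk
#'
#' Emits `exposure.tsv`, `mediator.tsv`, `outcome.tsv` (the canonical
#' summary-statistics dialect), `ld.tsv` (+ `.pos.tsv`), `truth.json`, and
#' `config.json` under `dir`.
#'
#' @param sim Result of [simulate_triple()].
#' @param dir Output directory (created if needed).
#' @param config Optional [sim_config()] to record alongside.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_stats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_summary_stats(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(sim$ld, file.path(dir, "ld.tsv"))
  truth <- sim$truth
  truth$true_beta_exposure <- NULL
  truth$true_beta_mediator <- NULL
  truth$true_beta_outcome <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
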