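#' Variance in a trait explained by one SNP
#'
#' For a standardized trait the variance explained by a biallelic SNP with
#' per-allele effect `beta` and minor-allele frequency `maf` is
#' `2 * beta^2 * maf * (1 - maf)`. The minor-allele frequency is taken as
#' `min(eaf, 1 - eaf)` (the formula is symmetric in `eaf` either way).
#'
#' @param beta Per-allele effect size.
#' @param eaf Effect-allele frequency in (0,1).
#' @param formula `"standard"` uses `2 * beta^2 * maf * (1-maf)`.
#'   `"as-printed"` is an audit mode evaluating `2 * (1-maf) * maf * 2*beta`
#'   (a published rendering of the formula with a linear beta term that is
#'   dimensionally inconsistent with a variance fraction; kept only so the
#'   two can be compared).
#' @return Variance-explained value(s); under `"standard"` clipped to
#'   `[0, 1)` for downstream use in the F statistic.
#' @export
variance_explained <- function(beta, eaf, formula = c("standard", "as-printed")) {
  formula <- match.arg(formula)
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    stop("eaf must lie in (0,1)", call. = FALSE)
  }
  maf <- pmin(eaf, 1 - eaf)
  if (formula == "as-printed") {
    return(2 * (1 - maf) * maf * 2 * beta)
  }
  pmin(2 * beta^2 * maf * (1 - maf), 1 - 1e-12)
}

#' Instrument-strength F statistic
#'
#' `F = (N - k - 1) / k * R2 / (1 - R2)` where `N` is the exposure sample
#' size, `k` the number of instruments the `R2` refers to, and `R2` the
#' variance in the exposure they explain. `F < 10` conventionally flags weak
#' instruments.
#'
#' @param n Sample size.
#' @param k Number of instruments behind `r2`.
#' @param r2 Variance explained, in `[0, 1)`.
#' @return The F value.
#' @export
f_statistic <- function(n, k, r2) {
  if (any(r2 < 0) || any(r2 >= 1)) stop("r2 must lie in [0,1)", call. = FALSE)
  if (any(n <= k + 1)) stop("need n > k + 1", call. = FALSE)
  (n - k - 1) / k * r2 / (1 - r2)
}

#' Greedy LD clumping of genome-wide-significant SNPs
#'
#' Ranks SNPs with `pval < p_thresh` by ascending p-value (ties broken by
#' lexicographic SNP id) and accepts a SNP iff its r-squared with every
#' already-accepted SNP on the same chromosome within `window_kb` is below
#' `r2_thresh`. SNPs on different chromosomes or farther apart than the
#' window are treated as independent regardless of the matrix entry.
#'
#' @param stats An [summary_stats()] object (or data.frame with `snp`,
#'   `pval` columns and optionally `chr`/`pos`; positions default to the LD
#'   companion table).
#' @param ld An [ld_matrix()] covering every candidate SNP.
#' @param p_thresh Significance threshold, default `5e-8`.
#' @param r2_thresh LD threshold, default `0.001`.
#' @param window_kb Physical window in kilobases, default `10000`.
#' @return Character vector of retained SNP ids (possibly empty), in
#'   selection order.
#' @export
clump <- function(stats, ld, p_thresh = 5e-8, r2_thresh = 0.001,
                  window_kb = 10000) {
  d <- as.data.frame(stats)
  d <- d[d$pval < p_thresh, , drop = FALSE]
  if (nrow(d) == 0) return(character(0))
  absent <- setdiff(d$snp, ld$snp_ids)
  if (length(absent) > 0) {
    stop("SNP(s) absent from LD matrix: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  d <- d[order(d$pval, d$snp), , drop = FALSE]
  pos <- ld$positions[match(d$snp, ld$positions$snp), ]
  window_bp <- window_kb * 1000

  kept <- character(0)
  kept_chr <- character(0)
  kept_pos <- numeric(0)
  for (i in seq_len(nrow(d))) {
    near <- kept_chr == pos$chr[i] & abs(kept_pos - pos$pos[i]) <= window_bp
    if (!any(near) || all(ld$r2[d$snp[i], kept[near]] < r2_thresh)) {
      kept <- c(kept, d$snp[i])
      kept_chr <- c(kept_chr, pos$chr[i])
      kept_pos <- c(kept_pos, pos$pos[i])
    }
  }
  kept
}

#' Select instruments for an exposure
#'
#' Composes the screening pipeline: genome-wide significance filter plus
#' greedy LD clumping ([clump()]), per-SNP variance explained
#' ([variance_explained()]), and an F-statistic strength filter dropping
#' SNPs with `F < f_min` in a single pass (F is not recomputed after
#' removals).
#'
#' @param stats An [summary_stats()] object for the exposure.
#' @param ld An [ld_matrix()] covering the candidates.
#' @param p_thresh,r2_thresh,window_kb Clumping parameters, see [clump()].
#' @param f_min Minimum F, default 10.
#' @param f_k_mode How `k` enters the per-SNP F statistic. `"single"`
#'   (default) scores each SNP on its own (`k = 1`), the usual per-variant
#'   strength check under which any genome-wide-significant SNP is strong.
#'   `"set"` plugs the clumped-set size in as `k` for every SNP; with many
#'   instruments this penalizes each SNP for the size of the whole set and
#'   can empty realistic instrument sets, so it is offered for auditing
#'   only.
#' @param r2_formula Passed to [variance_explained()].
#' @return A list of class `mr_instruments`: `exposure_id`, `snps`
#'   (data.frame `snp`, `beta`, `se`, `eaf`, `pval`, `r2`, `f_stat`), `k`
#'   (retained count), `n` (median exposure sample size), `set_r2` and
#'   `set_f` (set-level variance explained and F with `k` = set size), and a
#'   `report` of counts at each filter stage.
#' @export
select_instruments <- function(stats, ld, p_thresh = 5e-8, r2_thresh = 0.001,
                               window_kb = 10000, f_min = 10,
                               f_k_mode = c("single", "set"),
                               r2_formula = "standard") {
  f_k_mode <- match.arg(f_k_mode)
  d <- as.data.frame(stats)
  n_input <- nrow(d)
  n_sig <- sum(d$pval < p_thresh)
  kept <- clump(d, ld, p_thresh = p_thresh, r2_thresh = r2_thresh,
                window_kb = window_kb)
  d <- d[match(kept, d$snp), , drop = FALSE]
  k_clumped <- nrow(d)

  if (k_clumped > 0) {
    n_med <- stats::median(d$n)
    r2 <- variance_explained(d$beta, d$eaf, formula = r2_formula)
    k_for_f <- if (f_k_mode == "set") k_clumped else 1
    f_stat <- f_statistic(d$n, k_for_f, r2)
    set_r2 <- min(sum(r2), 1 - 1e-12)
    set_f <- f_statistic(n_med, k_clumped, set_r2)
    keep <- f_stat >= f_min
  } else {
    n_med <- NA_real_
    r2 <- f_stat <- numeric(0)
    set_r2 <- set_f <- NA_real_
    keep <- logical(0)
  }

  snps <- data.frame(snp = d$snp, beta = d$beta, se = d$se, eaf = d$eaf,
                     pval = d$pval, n = d$n, r2 = r2, f_stat = f_stat,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(snps) <- NULL
  res <- list(
    exposure_id = trait_id(stats),
    snps = snps,
    k = nrow(snps),
    n = n_med,
    set_r2 = set_r2,
    set_f = set_f,
    report = data.frame(
      stage = c("input", "p_filter", "clump", "f_filter"),
      n = c(n_input, n_sig, k_clumped, nrow(snps))
    )
  )
  class(res) <- "mr_instruments"
  res
}

#' @export
print.mr_instruments <- function(x, ...) {
  cat(sprintf("Instruments for %s: %d SNPs (set R2 = %.3g, set F = %.3g)\n",
              x$exposure_id, x$k, x$set_r2, x$set_f))
  print(x$report, row.names = FALSE)
  invisible(x)
}
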