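# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Convert a log-odds effect to the odds-ratio scale
#'
#' @param beta Effect on the log-odds scale.
#' @param se Standard error (> 0).
#' @param ci_mult Normal multiplier for the 95\% interval; 1.96 by
#'   convention.
#' @return List with `or`, `ci_low`, `ci_high` (`exp(beta +/- ci_mult*se)`)
#'   and two-sided normal `pval`.
#' @export
to_odds_scale <- function(beta, se, ci_mult = 1.96) {
  stopifnot(all(se > 0))
  list(or = exp(beta),
       ci_low = exp(beta - ci_mult * se),
       ci_high = exp(beta + ci_mult * se),
       pval = 2 * stats::pnorm(-abs(beta / se)))
}

new_estimate <- function(method, beta, se, nsnp, extra = list()) {
  odds <- to_odds_scale(beta, se)
  est <- c(list(method = method, nsnp = nsnp, beta = beta, se = se,
                pval = odds$pval, or = odds$or,
                ci_low = odds$ci_low, ci_high = odds$ci_high),
           extra)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.6g (se %.6g), OR = %.6g (%.6g, %.6g), p = %.4g, nsnp = %d\n",
              x$method, x$beta, x$se, x$or, x$ci_low, x$ci_high, x$pval,
              as.integer(x$nsnp)))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.6g (se %.6g), p = %.4g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$nsnp, beta = x$beta, se = x$se,
             pval = x$pval, or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
             intercept = x$intercept %||% NA_real_,
             intercept_se = x$intercept_se %||% NA_real_,
             intercept_pval = x$intercept_pval %||% NA_real_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-SNP Wald ratios and their first-order standard errors.
wald_terms <- function(d) {
  list(ratio = d$beta_out / d$beta_exp,
       se = d$se_out / abs(d$beta_exp))
}

#' Single-SNP Wald ratio estimate
#'
#' Causal effect from one instrument: outcome effect divided by exposure
#' effect, with first-order (delta method) standard error
#' `se_out / |beta_exp|`.
#'
#' @param h Harmonized set (or data.frame) with exactly one estimable row.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(h) {
  d <- harmonized_rows(h)
  if (nrow(d) != 1) stop("wald_ratio expects exactly one row", call. = FALSE)
  if (d$beta_exp == 0) stop("beta_exp = 0: Wald ratio undefined", call. = FALSE)
  w <- wald_terms(d)
  new_estimate("wald_ratio", w$ratio, w$se, 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_out^2`. The fixed-effects standard error fixes
#' the residual variance at 1; the multiplicative random-effects variant
#' inflates it by `max(1, sqrt(Q/(nsnp-1)))` where Q is Cochran's
#' heterogeneity statistic about the fitted slope.
#'
#' @param h Harmonized set with at least one estimable row (a single row
#'   falls back to [wald_ratio()]).
#' @param effects_model `"fixed"` or `"random"`.
#' @return An `mr_estimate` carrying `q`, `q_df`, `q_pval` extras.
#' @export
mr_ivw <- function(h, effects_model = c("fixed", "random")) {
  effects_model <- match.arg(effects_model)
  d <- harmonized_rows(h)
  if (nrow(d) < 1) stop("no estimable rows", call. = FALSE)
  if (nrow(d) == 1) return(wald_ratio(d))
  w <- 1 / d$se_out^2
  beta <- sum(w * d$beta_exp * d$beta_out) / sum(w * d$beta_exp^2)
  se_fixed <- sqrt(1 / sum(w * d$beta_exp^2))
  q <- sum(w * (d$beta_out - beta * d$beta_exp)^2)
  q_df <- nrow(d) - 1
  mult <- max(1, sqrt(q / q_df))
  se <- if (effects_model == "random") se_fixed * mult else se_fixed
  new_estimate(paste0("ivw_", effects_model), beta, se, nrow(d),
               extra = list(q = q, q_df = q_df,
                            q_pval = stats::pchisq(q, q_df, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights `1/se_out^2`), after orienting every row so the
#' exposure beta is non-negative. The slope estimates the causal effect;
#' a non-zero intercept indicates directional pleiotropy. Both standard
#' errors carry the multiplicative heterogeneity inflation
#' `max(1, sqrt(Q_egger/(nsnp-2)))`.
#'
#' @param h Harmonized set with at least three estimable rows.
#' @return An `mr_estimate` with `intercept`, `intercept_se`,
#'   `intercept_pval`, `q`, `q_df`, `q_pval` extras.
#' @export
mr_egger <- function(h) {
  d <- harmonized_rows(h)
  if (nrow(d) < 3) stop("MR-Egger needs >= 3 SNPs", call. = FALSE)
  flip <- sign(d$beta_exp)
  flip[flip == 0] <- 1
  bx <- d$beta_exp * flip
  by <- d$beta_out * flip
  w <- 1 / d$se_out^2

  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  coefs <- drop(solve(xtwx, crossprod(X, w * by)))
  resid <- by - drop(X %*% coefs)
  q <- sum(w * resid^2)
  q_df <- nrow(d) - 2
  mult <- max(1, sqrt(q / q_df))
  ses <- unname(sqrt(diag(solve(xtwx)))) * mult

  new_estimate("mr_egger", unname(coefs[2]), ses[2], nrow(d),
               extra = list(
                 intercept = unname(coefs[1]), intercept_se = ses[1],
                 intercept_pval = 2 * stats::pnorm(-abs(coefs[1] / ses[1])),
                 q = q, q_df = q_df,
                 q_pval = stats::pchisq(q, q_df, lower.tail = FALSE)))
}

# Weighted median of ratios r with weights w: value at cumulative
# normalized weight 0.5, linearly interpolated between bracketing ratios.
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

boot_resample <- function(d, n_boot) {
  n <- nrow(d)
  list(bx = matrix(stats::rnorm(n_boot * n, mean = rep(d$beta_exp, each = n_boot),
                                sd = rep(d$se_exp, each = n_boot)),
                   nrow = n_boot),
       by = matrix(stats::rnorm(n_boot * n, mean = rep(d$beta_out, each = n_boot),
                                sd = rep(d$se_out, each = n_boot)),
                   nrow = n_boot))
}

#' Weighted median estimate
#'
#' Median of the per-SNP Wald ratios weighted by the inverse variance of
#' each ratio; consistent when instruments carrying at least half the
#' weight are valid. The standard error comes from a seeded parametric
#' bootstrap that redraws exposure and outcome betas from normal
#' distributions centred at the observed values.
#'
#' @param h Harmonized set with at least three estimable rows.
#' @param n_boot Bootstrap replicates, default 5000.
#' @param seed Optional seed for the bootstrap (caller RNG state is
#'   restored).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 5000, seed = NULL) {
  d <- harmonized_rows(h)
  if (nrow(d) < 3) stop("weighted median needs >= 3 SNPs", call. = FALSE)
  wt <- wald_terms(d)
  w <- 1 / wt$se^2
  beta <- weighted_median_point(wt$ratio, w)
  se <- with_seed(seed, {
    rs <- boot_resample(d, n_boot)
    ests <- vapply(seq_len(n_boot), function(b) {
      r <- rs$by[b, ] / rs$bx[b, ]
      weighted_median_point(r, w)
    }, numeric(1))
    stats::sd(ests)
  })
  new_estimate("weighted_median", beta, se, nrow(d))
}

# Argmax of the (weighted) normal-kernel density of the ratios. Coarse grid
# scan followed by golden-section refinement in the bracketing interval.
mode_point <- function(r, w, h, grid_n = 512, refine = TRUE) {
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm(xi, mean = r, sd = h)),
           numeric(1))
  }
  lo <- min(r) - 3 * h
  hi <- max(r) + 3 * h
  grid <- seq(lo, hi, length.out = grid_n)
  i <- which.max(dens(grid))
  if (!refine) return(grid[i])
  bracket <- c(grid[max(1, i - 1)], grid[min(grid_n, i + 1)])
  stats::optimize(dens, interval = bracket, maximum = TRUE,
                  tol = .Machine$double.eps^0.5)$maximum
}

# Modified-Silverman spread rule on the ratios. A zero MAD (possible with a
# tight majority cluster) falls back to the SD so the bandwidth only
# vanishes when the ratios are literally constant.
mode_bandwidth <- function(r, bandwidth_factor) {
  spread <- c(stats::sd(r), stats::mad(r))
  spread <- spread[spread > 0]
  if (length(spread) == 0) return(0)
  bandwidth_factor * 0.9 * min(spread) * length(r)^(-1 / 5)
}

#' Mode-based estimate (simple or weighted)
#'
#' The causal estimate is the argmax of a normal-kernel-smoothed density of
#' the per-SNP Wald ratios: unweighted for the simple mode, weighted by the
#' inverse variance of each ratio for the weighted mode. Bandwidth is
#' `bandwidth_factor` times a modified-Silverman spread rule
#' (`0.9 * min(sd, mad) * n^(-1/5)`). Standard error by seeded parametric
#' bootstrap as in [mr_weighted_median()].
#'
#' @param h Harmonized set with at least three estimable rows.
#' @param variant `"simple"` or `"weighted"`.
#' @param bandwidth_factor Multiplier on the bandwidth rule, default 1.
#' @param n_boot Bootstrap replicates, default 5000.
#' @param seed Optional bootstrap seed.
#' @return An `mr_estimate` (method `simple_mode` or `weighted_mode`).
#' @export
mr_mode <- function(h, variant = c("simple", "weighted"),
                    bandwidth_factor = 1, n_boot = 5000, seed = NULL) {
  variant <- match.arg(variant)
  d <- harmonized_rows(h)
  if (nrow(d) < 3) stop("mode estimator needs >= 3 SNPs", call. = FALSE)
  wt <- wald_terms(d)
  w <- if (variant == "weighted") 1 / wt$se^2 else rep(1, nrow(d))
  w <- w / sum(w)

  if (mode_bandwidth(wt$ratio, 1) == 0) {
    # Degenerate spread: the density is a point mass at the common ratio.
    beta <- wt$ratio[1]
    est <- list(method = paste0(variant, "_mode"), nsnp = nrow(d),
                beta = beta, se = 0,
                pval = if (beta == 0) 1 else 0,
                or = exp(beta), ci_low = exp(beta), ci_high = exp(beta))
    class(est) <- "mr_estimate"
    return(est)
  }
  bw <- mode_bandwidth(wt$ratio, bandwidth_factor)
  beta <- mode_point(wt$ratio, w, bw)
  se <- with_seed(seed, {
    rs <- boot_resample(d, n_boot)
    ests <- vapply(seq_len(n_boot), function(b) {
      r <- rs$by[b, ] / rs$bx[b, ]
      s <- mode_bandwidth(r, bandwidth_factor)
      if (!is.finite(s) || s <= 0) return(r[1])
      mode_point(r, w, s, grid_n = 256, refine = FALSE)
    }, numeric(1))
    stats::sd(ests)
  })
  new_estimate(paste0(variant, "_mode"), beta, se, nrow(d))
}

#' Run the full estimator battery on one harmonized set
#'
#' Computes fixed- and random-effects IVW always; MR-Egger, weighted median,
#' simple mode and weighted mode when at least three SNPs are available; the
#' Wald ratio when only one is. The `ivw` row reports the fixed-effects fit
#' unless the Cochran Q p-value falls below `het_p_switch`, in which case the
#' multiplicative random-effects fit is used (both variants are still
#' reported).
#'
#' @param h Harmonized set.
#' @param n_boot,seed,bandwidth_factor Passed to the bootstrap estimators.
#' @param het_p_switch Heterogeneity p-value below which the headline IVW
#'   switches to random effects; default 0.05.
#' @return data.frame with one row per method (`method`, `nsnp`, `beta`,
#'   `se`, `pval`, `or`, `ci_low`, `ci_high`, intercept columns for
#'   MR-Egger).
#' @export
mr_all <- function(h, n_boot = 5000, seed = NULL, bandwidth_factor = 1,
                   het_p_switch = 0.05) {
  d <- harmonized_rows(h)
  if (nrow(d) < 1) stop("no estimable rows", call. = FALSE)
  ests <- list()
  if (nrow(d) == 1) {
    ests$wald <- wald_ratio(d)
  } else {
    fixed <- mr_ivw(d, "fixed")
    random <- mr_ivw(d, "random")
    headline <- if (fixed$q_pval < het_p_switch) random else fixed
    headline$method <- "ivw"
    ests$ivw <- headline
    ests$ivw_fixed <- fixed
    ests$ivw_random <- random
    if (nrow(d) >= 3) {
      ests$egger <- mr_egger(d)
      ests$wm <- mr_weighted_median(d, n_boot = n_boot, seed = seed)
      ests$sm <- mr_mode(d, "simple", bandwidth_factor, n_boot, seed)
      ests$wmode <- mr_mode(d, "weighted", bandwidth_factor, n_boot, seed)
    }
  }
  out <- do.call(rbind, lapply(ests, as.data.frame))
  rownames(out) <- NULL
  out
}
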