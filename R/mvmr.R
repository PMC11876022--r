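#' Select instruments jointly for several exposures
#'
#' Takes the union of every exposure's genome-wide-significant SNPs and
#' re-clumps the union greedily, ranking by the minimum p-value across
#' exposures (ties broken by SNP id), with the same LD window rule as
#' [clump()].
#'
#' @param exposures List of [summary_stats()] objects (>= 2 for a
#'   multivariable model; a single exposure reduces to the univariate
#'   clump).
#' @param ld An [ld_matrix()] covering the candidates.
#' @param p_thresh,r2_thresh,window_kb As in [clump()].
#' @return Character vector of SNP ids.
#' @export
select_mvmr_instruments <- function(exposures, ld, p_thresh = 5e-8,
                                    r2_thresh = 0.001, window_kb = 10000) {
  stopifnot(length(exposures) >= 1)
  per_exp <- lapply(exposures, function(e) {
    d <- as.data.frame(e)
    d[d$pval < p_thresh, c("snp", "pval")]
  })
  all_sig <- do.call(rbind, per_exp)
  if (nrow(all_sig) == 0) {
    stop("no genome-wide-significant SNP in any exposure", call. = FALSE)
  }
  # Minimum p across exposures per SNP, then one joint greedy clump.
  minp <- tapply(all_sig$pval, all_sig$snp, min)
  d <- data.frame(snp = names(minp), pval = as.numeric(minp),
                  stringsAsFactors = FALSE)
  clump(d, ld, p_thresh = p_thresh, r2_thresh = r2_thresh,
        window_kb = window_kb)
}

#' Align several exposures and the outcome at a set of instruments
#'
#' Harmonizes the outcome and every exposure to the first exposure's effect
#' allele at each requested SNP. SNPs missing from any table or with
#' irreconcilable alleles are dropped.
#'
#' @param exposures List of [summary_stats()] objects (order is preserved in
#'   the output matrices).
#' @param outcome [summary_stats()] object.
#' @param snps Character vector of instrument SNP ids.
#' @param ... Passed to [harmonize()] (palindrome policy).
#' @return List of class `mr_mvmr_input`: `snp` ids, `bx`/`sx` matrices
#'   (SNP x exposure), `by`/`sy` outcome vectors, `exposure_ids`,
#'   `outcome_id`.
#' @export
harmonize_mvmr <- function(exposures, outcome, snps, ...) {
  stopifnot(length(exposures) >= 1)
  ref <- exposures[[1]]
  ref_rows <- as.data.frame(ref)
  ref_rows <- ref_rows[ref_rows$snp %in% snps, , drop = FALSE]
  ref_sub <- summary_stats(ref_rows, trait_id = trait_id(ref))

  align_one <- function(tab) {
    h <- harmonize(ref_sub, tab, ...)
    h <- h[h$action %in% c("kept", "flipped"), , drop = FALSE]
    h[, c("snp", "beta_out", "se_out")]
  }
  aligned <- lapply(c(exposures[-1], list(outcome)), align_one)
  shared <- Reduce(intersect, c(list(ref_sub$snp), lapply(aligned, `[[`, "snp")))
  if (length(shared) == 0) stop("no shared instruments after alignment", call. = FALSE)

  k <- length(exposures)
  bx <- matrix(NA_real_, length(shared), k)
  sx <- matrix(NA_real_, length(shared), k)
  i <- match(shared, ref_sub$snp)
  bx[, 1] <- ref_sub$beta[i]
  sx[, 1] <- ref_sub$se[i]
  if (k > 1) {
    for (j in 2:k) {
      a <- aligned[[j - 1]]
      i <- match(shared, a$snp)
      bx[, j] <- a$beta_out[i]
      sx[, j] <- a$se_out[i]
    }
  }
  out_tab <- aligned[[length(aligned)]]
  i <- match(shared, out_tab$snp)
  ids <- vapply(exposures, trait_id, character(1))
  colnames(bx) <- colnames(sx) <- ids
  structure(list(snp = shared, bx = bx, sx = sx,
                 by = out_tab$beta_out[i], sy = out_tab$se_out[i],
                 exposure_ids = ids, outcome_id = trait_id(outcome)),
            class = "mr_mvmr_input")
}

#' Multivariable MR by inverse-variance-weighted multiple regression
#'
#' Regresses the outcome betas on the matrix of exposure betas with no
#' intercept and weights `1/se_out^2`. Each coefficient is the direct
#' effect of that exposure on the outcome, holding the other exposures
#' fixed. Standard errors carry the multiplicative heterogeneity inflation
#' `max(1, sqrt(Q/(nsnp - p)))`; p-values are two-sided normal.
#'
#' @param input An `mr_mvmr_input` from [harmonize_mvmr()], or a list with
#'   elements `bx`, `by`, `sy` (and optionally `sx`, `exposure_ids`,
#'   `snp`).
#' @param model_id Label for the fitted model.
#' @return A list of class `mr_mvmr`: `model_id`, `estimates` (data.frame
#'   `exposure`, `beta`, `se`, `pval`, `conditional_f`), `nsnp`, `q`,
#'   `q_df`, `q_pval`.
#' @export
mvmr_ivw <- function(input, model_id = "mvmr") {
  bx <- as.matrix(input$bx)
  by <- input$by
  sy <- input$sy
  p <- ncol(bx)
  n <- nrow(bx)
  if (n < p + 1) stop("need at least one more instrument than exposures", call. = FALSE)
  ids <- input$exposure_ids %||% colnames(bx) %||% paste0("exposure", seq_len(p))

  qrx <- qr(bx)
  if (qrx$rank < p) {
    dropped <- ids[qrx$pivot[(qrx$rank + 1):p]]
    stop("collinear exposure effects; offending exposure(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  w <- 1 / sy^2
  xtwx <- crossprod(bx, w * bx)
  coefs <- drop(solve(xtwx, crossprod(bx, w * by)))
  resid <- by - drop(bx %*% coefs)
  q <- sum(w * resid^2)
  q_df <- n - p
  mult <- max(1, sqrt(q / q_df))
  ses <- sqrt(diag(solve(xtwx))) * mult

  cond_f <- rep(NA_real_, p)
  if (!is.null(input$sx) && p >= 2) {
    # Heuristic conditional instrument-strength diagnostic: the precision-
    # weighted variation in each exposure's betas left after projecting out
    # the other exposures, per residual degree of freedom.
    sx <- as.matrix(input$sx)
    for (j in seq_len(p)) {
      others <- bx[, -j, drop = FALSE]
      wj <- 1 / sx[, j]^2
      fit <- stats::lm.wfit(others, bx[, j], wj)
      cond_f[j] <- sum(wj * fit$residuals^2) / (n - p + 1)
    }
  } else if (!is.null(input$sx)) {
    cond_f <- colSums((bx / as.matrix(input$sx))^2) / n
  }

  res <- list(
    model_id = model_id,
    estimates = data.frame(
      exposure = ids, beta = coefs, se = ses,
      pval = 2 * stats::pnorm(-abs(coefs / ses)),
      conditional_f = cond_f,
      stringsAsFactors = FALSE, row.names = NULL),
    nsnp = n, q = q, q_df = q_df,
    q_pval = stats::pchisq(q, q_df, lower.tail = FALSE))
  class(res) <- "mr_mvmr"
  res
}

#' @export
print.mr_mvmr <- function(x, ...) {
  cat(sprintf("Multivariable MR '%s' (%d instruments, Q p = %.4g)\n",
              x$model_id, x$nsnp, x$q_pval))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}
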