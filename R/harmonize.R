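ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) ALLELE_COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome effects onto a shared effect allele
#'
#' Two-sample MR requires the exposure and outcome per-allele effects at each
#' SNP to refer to the same effect allele. Rows are intersected on `snp_id`
#' and the outcome coding is aligned to the exposure's: when the outcome's
#' effect/other alleles are swapped the outcome beta is negated and its
#' allele frequency complemented (`action = "flipped"`); strand-complement
#' codings (e.g. A/G reported as T/C) are resolved before giving up.
#' Palindromic SNPs (A/T or C/G) cannot be strand-resolved from alleles
#' alone and are handled per `palindrome_policy`.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param palindrome_policy One of `"drop-ambiguous"` (default: drop
#'   palindromic SNPs whose exposure allele frequency falls inside
#'   `eaf_window`, align the rest using allele frequency), `"drop-all"`, or
#'   `"keep"` (take allele codes at face value).
#' @param eaf_window Ambiguity window on the exposure effect-allele
#'   frequency for `"drop-ambiguous"`; default `c(0.42, 0.58)`.
#' @return A data.frame of class `mr_harmonized` with one row per shared SNP:
#'   `snp`, `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `action` (kept / flipped / dropped-palindromic / dropped-mismatch), plus
#'   exposure-only SNPs as `dropped-missing`. Attributes `exposure_id` and
#'   `outcome_id` carry the trait labels. Rows with a `dropped-*` action are
#'   excluded by all estimators (see [harmonized_rows()]).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop-ambiguous", "drop-all", "keep"),
                      eaf_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  m <- match(ex$snp, ou$snp)

  n <- nrow(ex)
  out <- data.frame(
    snp = ex$snp,
    beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
    pval_exp = ex$pval, n_exp = ex$n,
    beta_out = NA_real_, se_out = NA_real_, eaf_out = NA_real_,
    pval_out = NA_real_, n_out = NA_real_,
    action = "dropped-missing",
    stringsAsFactors = FALSE
  )

  for (i in which(!is.na(m))) {
    j <- m[i]
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[j]; oa_y <- ou$other_allele[j]
    b_y <- ou$beta[j]; eaf_y <- ou$eaf[j]
    pal <- is_palindromic(ea_x, oa_x)

    if (pal && palindrome_policy == "drop-all") {
      out$action[i] <- "dropped-palindromic"
      next
    }
    if (pal && palindrome_policy == "drop-ambiguous" &&
        ex$eaf[i] >= eaf_window[1] && ex$eaf[i] <= eaf_window[2]) {
      out$action[i] <- "dropped-palindromic"
      next
    }

    if (pal) {
      # Alleles alone cannot identify strand; for a palindromic SNP the swap
      # and the strand-complement are the same pair. Align by comparing which
      # side of 0.5 the allele frequencies fall on (policy "keep" trusts the
      # literal codes instead).
      if (!(ea_y %in% c(ea_x, oa_x)) || !(oa_y %in% c(ea_x, oa_x))) {
        out$action[i] <- "dropped-mismatch"
        next
      }
      if (palindrome_policy == "keep") {
        action <- if (ea_y == ea_x) "kept" else "flipped"
      } else {
        same_side <- (ex$eaf[i] < 0.5) == (eaf_y < 0.5)
        action <- if (same_side) "kept" else "flipped"
      }
    } else if (ea_y == ea_x && oa_y == oa_x) {
      action <- "kept"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      action <- "flipped"
    } else if (ea_y == ALLELE_COMPLEMENT[ea_x] && oa_y == ALLELE_COMPLEMENT[oa_x]) {
      action <- "kept"        # opposite strand, same orientation
    } else if (ea_y == ALLELE_COMPLEMENT[oa_x] && oa_y == ALLELE_COMPLEMENT[ea_x]) {
      action <- "flipped"     # opposite strand, swapped
    } else {
      out$action[i] <- "dropped-mismatch"
      next
    }

    if (action == "flipped") {
      b_y <- -b_y
      eaf_y <- 1 - eaf_y
    }
    out$beta_out[i] <- b_y
    out$se_out[i] <- ou$se[j]
    out$eaf_out[i] <- eaf_y
    out$pval_out[i] <- ou$pval[j]
    out$n_out[i] <- ou$n[j]
    out$action[i] <- action
  }

  structure(out,
            exposure_id = trait_id(exposure),
            outcome_id = trait_id(outcome),
            class = c("mr_harmonized", "data.frame"))
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s\n",
              attr(x, "exposure_id"), attr(x, "outcome_id")))
  print(table(x$action))
  invisible(x)
}

#' Rows of a harmonized set usable for estimation
#'
#' @param h An `mr_harmonized` data.frame (rows carrying `dropped-*` actions
#'   are excluded) or a plain data.frame with columns `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` (taken as-is).
#' @return data.frame of estimable rows.
#' @export
harmonized_rows <- function(h) {
  d <- as.data.frame(h)
  if ("action" %in% names(d)) d <- d[d$action %in% c("kept", "flipped"), , drop = FALSE]
  needed <- c("beta_exp", "se_exp", "beta_out", "se_out")
  stopifnot(all(needed %in% names(d)))
  rownames(d) <- NULL
  d
}

#' Write a harmonized set (including dropped rows and actions) as TSV
#' @param h An `mr_harmonized` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) write_tsv(as.data.frame(h), path)
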