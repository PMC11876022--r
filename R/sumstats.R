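#' GWAS summary statistics for one trait
#'
#' Construct a validated per-SNP summary-statistics table. Rows violating the
#' invariants (non-ACGT alleles, identical alleles, `se <= 0`, `eaf` outside
#' (0,1), `pval` outside (0,1], non-positive `n`, duplicated `snp_id`) are
#' rejected; the rejections are recorded with per-row reasons in the
#' `"rejections"` attribute.
#'
#' @param records data.frame with columns `snp`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_id Text label for the trait (e.g. a GWAS dataset id).
#' @return A data.frame of class `mr_sumstats` with attributes `trait_id`
#'   and `rejections` (data.frame of `snp`/`reason`). Input row order is
#'   preserved for retained rows.
#' @export
summary_stats <- function(records, trait_id = "trait") {
  required <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop("empty summary-statistics table", call. = FALSE)

  d <- records[required]
  d$snp <- as.character(d$snp)
  d$chr <- as.character(d$chr)
  d$pos <- as.integer(d$pos)
  d$effect_allele <- toupper(as.character(d$effect_allele))
  d$other_allele <- toupper(as.character(d$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) d[[col]] <- as.numeric(d[[col]])
  d$n <- as.numeric(d$n)

  reason <- rep(NA_character_, nrow(d))
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  acgt <- c("A", "C", "G", "T")
  flag(!(d$effect_allele %in% acgt) | !(d$other_allele %in% acgt),
       "non-ACGT allele")
  flag(d$effect_allele == d$other_allele, "effect allele equals other allele")
  flag(!is.finite(d$se) | d$se <= 0, "se not positive")
  flag(!is.finite(d$eaf) | d$eaf <= 0 | d$eaf >= 1, "eaf outside (0,1)")
  flag(!is.finite(d$beta), "beta not finite")
  flag(!is.finite(d$pval) | d$pval <= 0 | d$pval > 1, "pval outside (0,1]")
  flag(!is.finite(d$n) | d$n <= 0, "n not positive")
  flag(is.na(d$pos) | d$pos < 0, "position invalid")
  flag(duplicated(d$snp), "duplicate snp_id")

  rejected <- data.frame(snp = d$snp[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  d <- d[is.na(reason), , drop = FALSE]
  rownames(d) <- NULL
  structure(d,
            trait_id = trait_id,
            rejections = rejected,
            class = c("mr_sumstats", "data.frame"))
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%d SNPs, %d rejected)\n",
              trait_id(x), nrow(x), nrow(attr(x, "rejections"))))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Trait identifier of a summary-statistics table
#' @param x An `mr_sumstats` object.
#' @return Character scalar.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' Read GWAS summary statistics from a tab-separated file
#'
#' The canonical header is `snp, chr, pos, effect_allele, other_allele, eaf,
#' beta, se, pval, n`. Files using other column names are mapped through
#' `dialect`, a named character vector `c(FILE_NAME = "canonical_name")`.
#'
#' @param path Path to a TSV file with a header row.
#' @param trait_id Trait label; defaults to the file name without extension.
#' @param dialect Optional named character vector remapping file columns to
#'   canonical names, e.g. `c(BETA = "beta", A1 = "effect_allele")`.
#' @return An [summary_stats()] object; invalid rows are dropped and logged
#'   in the `"rejections"` attribute.
#' @export
read_summary_stats <- function(path, trait_id = NULL, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(trait_id)) trait_id <- sub("\\.[^.]*$", "", basename(path))
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), names(d))
    if (length(bad) > 0) {
      stop("dialect refers to absent column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    idx <- match(names(d), names(dialect))
    names(d)[!is.na(idx)] <- dialect[idx[!is.na(idx)]]
  }
  summary_stats(d, trait_id = trait_id)
}

#' Write summary statistics as canonical TSV
#' @param x An `mr_sumstats` object (or plain data.frame with the canonical
#'   columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

# Deterministic TSV writer used for all table outputs.
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
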