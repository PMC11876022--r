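#' Pairwise linkage-disequilibrium (r-squared) matrix
#'
#' Container for the reference LD information clumping needs: a symmetric
#' matrix of pairwise r-squared values with unit diagonal plus per-SNP
#' genomic positions.
#'
#' @param r2 Square numeric matrix of r-squared values in \[0,1\] with unit
#'   diagonal; dimnames give the SNP ids (or supply `snp_ids`).
#' @param positions data.frame with columns `snp`, `chr`, `pos` covering
#'   every SNP in `r2`.
#' @param snp_ids Optional character vector of SNP ids when `r2` lacks
#'   dimnames.
#' @return A list of class `mr_ld` with elements `snp_ids`, `r2`,
#'   `positions`.
#' @export
ld_matrix <- function(r2, positions, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop("SNP ids required (dimnames or snp_ids)", call. = FALSE)
  snp_ids <- as.character(snp_ids)
  if (nrow(r2) != length(snp_ids) || ncol(r2) != length(snp_ids)) {
    stop("r2 matrix dimensions do not match snp_ids", call. = FALSE)
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0,1]", call. = FALSE)
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1", call. = FALSE)
  positions <- as.data.frame(positions)
  stopifnot(all(c("snp", "chr", "pos") %in% names(positions)))
  missing <- setdiff(snp_ids, positions$snp)
  if (length(missing) > 0) {
    stop("positions missing for: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  positions <- positions[match(snp_ids, positions$snp), c("snp", "chr", "pos")]
  positions$chr <- as.character(positions$chr)
  positions$pos <- as.numeric(positions$pos)
  rownames(positions) <- NULL
  structure(list(snp_ids = snp_ids, r2 = r2, positions = positions),
            class = "mr_ld")
}

#' @export
print.mr_ld <- function(x, ...) {
  cat(sprintf("LD matrix: %d SNPs, mean off-diagonal r2 = %.4g\n",
              length(x$snp_ids),
              mean(x$r2[upper.tri(x$r2)])))
  invisible(x)
}

#' Write an LD matrix as a TSV pair
#'
#' Writes `<path>` (header of SNP ids plus square numeric body, first column
#' `snp`) and `<path>.pos.tsv` (snp/chr/pos companion table).
#' @param ld An `mr_ld` object.
#' @param path Output path for the matrix body.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  body <- data.frame(snp = ld$snp_ids, as.data.frame(ld$r2),
                     check.names = FALSE)
  write_tsv(body, path)
  write_tsv(ld$positions, paste0(path, ".pos.tsv"))
  invisible(path)
}

#' Read an LD matrix written by [write_ld_matrix()]
#' @param path Path to the matrix TSV; `<path>.pos.tsv` must exist.
#' @return An `mr_ld` object.
#' @export
read_ld_matrix <- function(path) {
  body <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  pos <- utils::read.table(paste0(path, ".pos.tsv"), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  snps <- body$snp
  m <- as.matrix(body[, -1, drop = FALSE])
  rownames(m) <- snps
  ld_matrix(m, pos, snp_ids = snps)
}
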