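#' SNP panel container
#'
#' A light container for population SNP data: a numeric matrix of
#' chromosomes-by-SNPs (haplotype panels, alleles 0/1) or
#' subjects-by-SNPs (genotype panels, codes 0/1/2 with `NA` for
#' missing), together with strictly increasing 1-based physical
#' positions in base pairs.
#'
#' @param matrix integer matrix; rows are chromosomes (haplotype panel)
#'   or subjects (genotype panel), columns are SNPs.
#' @param positions integer/numeric vector of physical positions (bp,
#'   1-based), strictly increasing, one per SNP column.
#' @param kind `"haplotype"` or `"genotype"`.
#' @param ids optional SNP identifiers (default `snp1..snpP`).
#' @param sample_ids optional row identifiers.
#' @return An object of class `snp_panel`.
#' @export
snp_panel <- function(matrix, positions, kind = c("haplotype", "genotype"),
                      ids = NULL, sample_ids = NULL) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  positions <- as.numeric(positions)
  if (ncol(matrix) != length(positions)) {
    stop("matrix has ", ncol(matrix), " SNP columns but ", length(positions),
         " positions were given")
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop("SNP positions must be strictly increasing")
  }
  vals <- matrix[!is.na(matrix)]
  if (kind == "haplotype") {
    if (anyNA(matrix)) stop("haplotype panels cannot contain missing alleles")
    if (length(vals) && !all(vals %in% c(0L, 1L))) {
      stop("haplotype panel alleles must be 0/1")
    }
  } else {
    if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
      stop("genotype panel codes must be 0/1/2 or NA")
    }
  }
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(matrix)))
  if (is.null(sample_ids)) {
    sample_ids <- paste0(if (kind == "haplotype") "chr" else "subj",
                         seq_len(nrow(matrix)))
  }
  structure(
    list(matrix = matrix, positions = positions, kind = kind,
         ids = as.character(ids), sample_ids = as.character(sample_ids)),
    class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel> %s data: %d %s x %d SNPs, span %.5f Mb\n",
              x$kind, nrow(x$matrix),
              if (x$kind == "haplotype") "chromosomes" else "subjects",
              ncol(x$matrix),
              (max(x$positions) - min(x$positions)) / 1e6))
  invisible(x)
}

#' @export
dim.snp_panel <- function(x) dim(x$matrix)

n_snps <- function(panel) ncol(panel$matrix)

is_haplotype <- function(panel) identical(panel$kind, "haplotype")

#' Minor allele frequencies of a panel
#'
#' Computed from allele counts; for genotype panels missing codes are
#' ignored SNP-wise.
#'
#' @param panel a [snp_panel()].
#' @return Numeric vector of per-SNP minor allele frequencies.
#' @export
panel_maf <- function(panel) {
  m <- panel$matrix
  if (is_haplotype(panel)) {
    p <- colMeans(m)
  } else {
    p <- colMeans(m, na.rm = TRUE) / 2
    p[is.nan(p)] <- 0
  }
  pmin(p, 1 - p)
}

# Integer bitmask codes for an N-SNP block: rows of `mat` restricted to
# columns `cols`, bit j corresponding to cols[j+1].
block_masks <- function(mat, cols) {
  as.integer(mat[, cols, drop = FALSE] %*% (2^(seq_along(cols) - 1)))
}
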