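# All writers go through a temp-file + rename so partial files are
# never left behind.
atomic_write <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Read a SNP panel
#'
#' Two formats are supported.  The TSV dialect has an optional
#' `# kind: haplotype|genotype` comment, a header row of SNP ids
#' (first cell `id`), a second header row of positions (first cell
#' `pos`), then one row per chromosome (alleles 0/1) or subject
#' (genotype codes 0/1/2, missing `NA`).  VCF input (via vcfR) keeps
#' biallelic SNVs only, skipping other records with a message; fully
#' phased GT fields (`|`) yield a haplotype panel with two rows per
#' sample, unphased (`/`) a genotype panel, and mixed phasing is an
#' error naming the first offending record.  `./.` maps to missing.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param kind for TSV input without a kind comment: `"haplotype"`,
#'   `"genotype"`, or `NULL` to infer (codes 2/NA present imply
#'   genotype).
#' @return A [snp_panel()].
#' @export
read_panel <- function(path, format = c("tsv", "vcf"), kind = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") read_panel_tsv(path, kind) else read_panel_vcf(path)
}

read_panel_tsv <- function(path, kind) {
  first <- readLines(path, n = 1)
  skip <- 0L
  if (grepl("^#", first)) {
    skip <- 1L
    m <- regmatches(first, regexec("kind:\\s*(haplotype|genotype)", first))[[1]]
    if (length(m) == 2 && is.null(kind)) kind <- m[2]
  }
  hdr <- utils::read.table(path, sep = "\t", skip = skip, nrows = 2,
                           header = FALSE, colClasses = "character")
  if (hdr[1, 1] != "id" || hdr[2, 1] != "pos") {
    stop("panel TSV must start with an 'id' row and a 'pos' row")
  }
  ids <- as.character(hdr[1, -1])
  positions <- as.numeric(hdr[2, -1])
  if (any(diff(positions) <= 0)) stop("SNP positions must be strictly increasing")
  body <- utils::read.table(path, sep = "\t", skip = skip + 2L, header = FALSE,
                            colClasses = c("character", rep("integer", length(ids))),
                            na.strings = "NA")
  sample_ids <- body[[1]]
  mat <- as.matrix(body[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  if (is.null(kind)) {
    kind <- if (anyNA(mat) || any(mat == 2L, na.rm = TRUE)) "genotype" else "haplotype"
  }
  snp_panel(mat, positions, kind = kind, ids = ids, sample_ids = sample_ids)
}

read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  snv <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"]) & fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skip <- sum(!snv)
  if (n_skip > 0) {
    message("skipped ", n_skip, " non-SNV or multi-allelic record(s)")
  }
  if (!any(snv)) stop("no biallelic SNVs in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[snv, , drop = FALSE]
  positions <- as.numeric(fix[snv, "POS"])
  ids <- fix[snv, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("snp", which(is.na(ids) | ids == "."))
  if (any(diff(positions) <= 0)) stop("SNP positions must be strictly increasing")

  phased <- grepl("\\|", gt)
  unphased <- grepl("/", gt)
  missing <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  if (any(phased & !missing) && any(unphased & !missing)) {
    off <- which(unphased & !missing, arr.ind = TRUE)[1, ]
    stop("mixed phased/unphased genotypes; first unphased record: ",
         rownames(gt)[off[1]], " sample ", colnames(gt)[off[1]])
  }
  samples <- colnames(gt)
  alleles <- function(x) {
    a <- strsplit(x, "[|/]")
    t(vapply(a, function(z) {
      z <- suppressWarnings(as.integer(z))
      if (length(z) != 2) c(NA_integer_, NA_integer_) else z
    }, integer(2)))
  }
  if (any(phased & !missing)) {
    n <- length(samples)
    mat <- matrix(NA_integer_, 2 * n, sum(snv))
    for (s in seq_len(n)) {
      al <- alleles(gt[, s])
      mat[2 * s - 1, ] <- al[, 1]
      mat[2 * s, ] <- al[, 2]
    }
    if (anyNA(mat)) stop("phased VCF contains missing alleles; not supported")
    snp_panel(mat, positions, "haplotype", ids = ids,
              sample_ids = paste0(rep(samples, each = 2), "_", rep(1:2, n)))
  } else {
    n <- length(samples)
    mat <- matrix(NA_integer_, n, sum(snv))
    for (s in seq_len(n)) {
      al <- alleles(gt[, s])
      mat[s, ] <- al[, 1] + al[, 2]
    }
    snp_panel(mat, positions, "genotype", ids = ids, sample_ids = samples)
  }
}

#' Write a SNP panel in the TSV dialect
#'
#' @param panel a [snp_panel()].
#' @param path output file (written atomically).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  mat <- panel$matrix
  lines <- c(
    paste0("# kind: ", panel$kind),
    paste(c("id", panel$ids), collapse = "\t"),
    paste(c("pos", format(panel$positions, scientific = FALSE, trim = TRUE)),
          collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(panel$sample_ids[i], ifelse(is.na(mat[i, ]), "NA", mat[i, ])),
            collapse = "\t")
    }, character(1)))
  atomic_write(lines, path)
}

#' Write a region-of-interest table
#'
#' One region per row with the column set
#' `window LBPmin LBPmax RBPmin RBPmax MaxBic invFreq Ns`;
#' Mb coordinates to 5 decimals, BIC to 2.
#'
#' @param rois tibble from [merge_regions()].
#' @param path output file (written atomically).
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(rois, path) {
  hdr <- paste(c("window", "LBPmin", "LBPmax", "RBPmin", "RBPmax",
                 "MaxBic", "invFreq", "Ns"), collapse = "\t")
  rows <- character(0)
  if (nrow(rois) > 0) {
    rows <- vapply(seq_len(nrow(rois)), function(i) {
      paste(c(sprintf("%.1f", rois$window[i]),
              sprintf("%.5f", rois$LBPmin[i]), sprintf("%.5f", rois$LBPmax[i]),
              sprintf("%.5f", rois$RBPmin[i]), sprintf("%.5f", rois$RBPmax[i]),
              sprintf("%.2f", rois$MaxBic[i]), sprintf("%.2f", rois$invFreq[i]),
              rois$Ns[i]), collapse = "\t")
    }, character(1))
  }
  atomic_write(c(hdr, rows), path)
}

#' Write chromosome or subject calls
#'
#' @param calls tibble from [call_chromosomes()] or [call_subjects()].
#' @param path output file (written atomically).
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  score_col <- if ("r0I" %in% names(calls)) "r0I" else "count"
  hdr <- paste(c("id", "status", score_col, "n_windows_used", "t_B"),
               collapse = "\t")
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    paste(c(calls$id[i],
            ifelse(is.na(calls$status[i]), "no_call", calls$status[i]),
            as.character(calls[[score_col]][i]),
            calls$n_windows_used[i], calls$t_B[i]), collapse = "\t")
  }, character(1))
  atomic_write(c(hdr, rows), path)
}

#' Write a simulated population to a directory
#'
#' Emits `haplotypes.tsv`, `genotypes.tsv`, a `truth.tsv` with
#' per-chromosome orientation labels, and a `config.json` sidecar.
#'
#' @param sim an `inv_sim` from [simulate_population()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "inv_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(sim$haplotypes, file.path(dir, "haplotypes.tsv"))
  write_panel(sim$genotypes, file.path(dir, "genotypes.tsv"))
  atomic_write(c("chromosome_id\torientation",
                 paste(sim$truth$chromosome, sim$truth$orientation, sep = "\t")),
               file.path(dir, "truth.tsv"))
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
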