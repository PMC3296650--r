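#' Encode haplotype blocks as a categorical quartet
#'
#' The mixture model observes, per chromosome (or subject), four
#' haplotype blocks B1..B4 as categorical variables.  This encodes a
#' collection of allele strings column-wise into dense integer codes
#' `0..K_j-1`, remembering the string-to-code bijection so that codes
#' can be decoded back.
#'
#' @param block_strings an m-by-4 character matrix (or data frame) of
#'   N-SNP allele strings over the alphabet `{0,1}`; each column is one
#'   block variable, all strings in a column must have equal length.
#' @return A `block_quartet`: list with `codes` (m-by-4 integer matrix of
#'   dense 0-based codes), `m`, and `category_maps` (per column, the
#'   character vector of strings indexed by code + 1).
#' @examples
#' q <- encode_blocks(cbind(c("00", "00", "11"), c("01", "01", "10"),
#'                          c("11", "00", "11"), c("10", "10", "10")))
#' q$codes
#' @export
encode_blocks <- function(block_strings) {
  block_strings <- as.matrix(block_strings)
  if (ncol(block_strings) != 4) {
    stop("block_strings must have exactly 4 columns (B1..B4)")
  }
  if (nrow(block_strings) < 1) stop("at least one observation is required")
  storage.mode(block_strings) <- "character"
  codes <- matrix(0L, nrow(block_strings), 4)
  maps <- vector("list", 4)
  for (j in 1:4) {
    s <- block_strings[, j]
    if (length(unique(nchar(s))) != 1) {
      stop("ragged allele-string lengths in block column B", j)
    }
    if (any(!grepl("^[01]*$", s))) {
      stop("alleles must be 0/1 in block column B", j)
    }
    lev <- sort(unique(s))
    codes[, j] <- match(s, lev) - 1L
    maps[[j]] <- lev
  }
  structure(list(codes = codes, m = nrow(codes), category_maps = maps),
            class = "block_quartet")
}

#' Decode a block quartet back to allele strings
#'
#' Inverse of [encode_blocks()].
#'
#' @param q a `block_quartet`.
#' @return An m-by-4 character matrix of allele strings.
#' @export
decode_blocks <- function(q) {
  stopifnot(inherits(q, "block_quartet"))
  out <- matrix("", q$m, 4)
  for (j in 1:4) out[, j] <- q$category_maps[[j]][q$codes[, j] + 1L]
  out
}

# Build a block_quartet directly from 0-based integer code columns
# (internal fast path used by the scan; category maps carry the raw
# underlying values, typically block bitmasks, as strings).
quartet_from_codes <- function(b1, b2, b3, b4, raw = NULL) {
  recode <- function(v) {
    lev <- sort(unique(v))
    list(code = match(v, lev) - 1L, lev = lev)
  }
  r1 <- recode(b1); r2 <- recode(b2); r3 <- recode(b3); r4 <- recode(b4)
  structure(
    list(codes = cbind(r1$code, r2$code, r3$code, r4$code),
         m = length(b1),
         category_maps = list(as.character(r1$lev), as.character(r2$lev),
                              as.character(r3$lev), as.character(r4$lev))),
    class = "block_quartet")
}

n_categories <- function(q) {
  vapply(q$category_maps, length, integer(1))
}
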