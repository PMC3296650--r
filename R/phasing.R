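#' Phase a short genotype window by haplotype-frequency EM
#'
#' Estimates multilocus haplotype frequencies for a window of at most
#' 16 SNPs by EM over the enumerable haplotype space (the classical
#' haplotype-frequency EM), then assigns each subject the compatible
#' haplotype pair with the highest posterior probability.  Missing
#' genotypes are imputed by the same maximization.  Windows are short
#' by construction: the scan phases `2N` SNPs centred on one candidate
#' breakpoint at a time, so the enumeration stays exact.
#'
#' @param genotypes n-by-S integer matrix of genotype codes 0/1/2 with
#'   `NA` for missing; `S` must be even and at most 16.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @return A `local_haplotypes` object: `hap1`, `hap2` (n-by-S 0/1
#'   matrices, `hap1` the numerically smaller haplotype of the pair),
#'   `posterior` (probability of the selected configuration),
#'   `flagged` (subjects with no usable genotype in the window, to be
#'   excluded downstream), and the fitted haplotype frequencies.
#' @export
phase_window <- function(genotypes, tol = 1e-6, max_iter = 500) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (ncol(genotypes) > 16) {
    stop("phase_window supports at most 16 SNPs (2N <= 16); got ",
         ncol(genotypes))
  }
  res <- phase_em_cpp(genotypes, tol, max_iter)
  # consistency guard: hap1 + hap2 must reproduce every non-missing genotype
  ok <- !res$flagged
  if (any(ok)) {
    g <- genotypes[ok, , drop = FALSE]
    h <- res$hap1[ok, , drop = FALSE] + res$hap2[ok, , drop = FALSE]
    stopifnot(all(h[!is.na(g)] == g[!is.na(g)]))
  }
  structure(list(hap1 = res$hap1, hap2 = res$hap2,
                 posterior = res$posterior, flagged = res$flagged,
                 hap_mask = res$hap_mask, hap_freq = res$hap_freq,
                 n_iter = res$n_iter, converged = res$converged,
                 loglik = res$loglik, n_snps = ncol(genotypes)),
            class = "local_haplotypes")
}

#' Pair left and right haplotype blocks across a trial segment
#'
#' First application of the inversion model: given each subject's two
#' phased haplotypes around the left breakpoint (`L1`, `L2`) and around
#' the right breakpoint (`R1`, `R2`), decide which left haplotype
#' travels with which right haplotype on the same chromosome.  The
#' mixture is fitted on the quartet `B1 = L1, B2 = R1, B3 = R2,
#' B4 = L2` with `m` = number of subjects; a subject's pairing follows
#' its dominant responsibility: forward responsibility `>= 0.5` selects
#' the parallel pairing `(L1 R1, L2 R2)` (ties, e.g. subjects
#' homozygous on either side, deterministically resolve to it),
#' otherwise the crossed pairing `(L1 R2, L2 R1)`.
#'
#' @param left,right `local_haplotypes` for the same subjects in the
#'   same order (from [phase_window()]), or lists with `hap1`/`hap2`
#'   0/1 matrices.
#' @param tol,max_iter EM controls for the pairing fit.
#' @return A `chromosome_blocks` object: `HL`, `HR` (2n-by-2N allele
#'   matrices, chromosomes `2i-1`, `2i` belonging to subject `i`),
#'   `pairing_resp` (per-subject forward responsibility), `parallel`
#'   (chosen pairing), `flagged` (per-chromosome exclusion flag) and
#'   `N`.
#' @export
pair_blocks <- function(left, right, tol = 1e-6, max_iter = 1000) {
  n <- nrow(left$hap1)
  if (is.null(n) || n < 2) stop("pairing requires at least 2 subjects")
  stopifnot(nrow(right$hap1) == n)
  lf <- if (!is.null(left$flagged)) left$flagged else rep(FALSE, n)
  rf <- if (!is.null(right$flagged)) right$flagged else rep(FALSE, n)
  flagged <- lf | rf
  ok <- which(!flagged)
  if (length(ok) < 2) stop("fewer than 2 subjects with usable data on both sides")

  ncl <- ncol(left$hap1); ncr <- ncol(right$hap1)
  l1 <- block_masks(left$hap1[ok, , drop = FALSE], seq_len(ncl))
  l2 <- block_masks(left$hap2[ok, , drop = FALSE], seq_len(ncl))
  r1 <- block_masks(right$hap1[ok, , drop = FALSE], seq_len(ncr))
  r2 <- block_masks(right$hap2[ok, , drop = FALSE], seq_len(ncr))

  q <- quartet_from_codes(l1, r1, r2, l2)
  fit <- fit_mixture(q, tol = tol, max_iter = max_iter)
  r0 <- fit$resp_fwd
  # subjects homozygous on either side are pairing-invariant: both
  # configurations assemble the same chromosomes, so assign the
  # parallel one deterministically
  parallel_ok <- r0 >= 0.5 | l1 == l2 | r1 == r2

  N2 <- ncl
  HL <- matrix(NA_integer_, 2 * n, N2)
  HR <- matrix(NA_integer_, 2 * n, ncr)
  pairing_resp <- rep(NA_real_, n)
  parallel <- rep(NA, n)
  pairing_resp[ok] <- r0
  parallel[ok] <- parallel_ok
  for (k in seq_along(ok)) {
    i <- ok[k]
    HL[2 * i - 1, ] <- left$hap1[i, ]
    HL[2 * i, ] <- left$hap2[i, ]
    if (parallel_ok[k]) {
      HR[2 * i - 1, ] <- right$hap1[i, ]
      HR[2 * i, ] <- right$hap2[i, ]
    } else {
      HR[2 * i - 1, ] <- right$hap2[i, ]
      HR[2 * i, ] <- right$hap1[i, ]
    }
  }
  structure(list(HL = HL, HR = HR, N = N2 / 2,
                 pairing_resp = pairing_resp, parallel = parallel,
                 flagged = rep(flagged, each = 2),
                 subject = rep(seq_len(n), each = 2),
                 pairing_fit = fit),
            class = "chromosome_blocks")
}

#' Split paired chromosome haplotypes into the detection quartet
#'
#' Second application of the inversion model: each chromosome's left
#' 2N-SNP haplotype is split into the two N-SNP blocks flanking the
#' left breakpoint, `(H_LL, H_LR)`, and likewise `(H_RL, H_RR)` on the
#' right, giving the quartet `B1 = H_LL, B2 = H_LR, B3 = H_RL,
#' B4 = H_RR` with `m` = number of chromosomes.
#'
#' @param cb a `chromosome_blocks` object from [pair_blocks()].
#' @return A `block_quartet` over the unflagged chromosomes, with
#'   attribute `rows` giving their chromosome indices (rows of
#'   `cb$HL`).
#' @export
split_blocks <- function(cb) {
  stopifnot(inherits(cb, "chromosome_blocks"))
  N <- cb$N
  keep <- which(!cb$flagged)
  HL <- cb$HL[keep, , drop = FALSE]
  HR <- cb$HR[keep, , drop = FALSE]
  b1 <- block_masks(HL, 1:N)
  b2 <- block_masks(HL, (N + 1):(2 * N))
  b3 <- block_masks(HR, 1:N)
  b4 <- block_masks(HR, (N + 1):(2 * N))
  q <- quartet_from_codes(b1, b2, b3, b4)
  attr(q, "rows") <- keep
  q
}
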