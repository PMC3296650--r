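#' Remove SNPs with excessive missingness
#'
#' Genotype panels only (haplotype panels are returned unchanged):
#' SNPs missing in more than `max_missing` of the subjects are dropped.
#'
#' @param panel a [snp_panel()].
#' @param max_missing maximum tolerated fraction of missing genotypes
#'   per SNP.
#' @return The filtered panel, with attribute `n_removed`.
#' @export
filter_snps <- function(panel, max_missing = 0.10) {
  stopifnot(inherits(panel, "snp_panel"))
  if (is_haplotype(panel)) {
    attr(panel, "n_removed") <- 0L
    return(panel)
  }
  frac <- colMeans(is.na(panel$matrix))
  keep <- frac <= max_missing
  if (!any(keep)) stop("all SNPs exceed the missingness threshold")
  out <- snp_panel(panel$matrix[, keep, drop = FALSE], panel$positions[keep],
                   kind = panel$kind, ids = panel$ids[keep],
                   sample_ids = panel$sample_ids)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Candidate inversion breakpoints
#'
#' A candidate breakpoint is the gap between two consecutive SNPs,
#' kept when at least one of the flanking SNPs has minor allele
#' frequency `>= maf_min`.  The breakpoint coordinate is the midpoint
#' between the two SNP positions.
#'
#' @param panel a [snp_panel()].
#' @param maf_min minimum MAF required of at least one flanking SNP.
#' @return A tibble with `left_snp_index`, `right_snp_index` (1-based,
#'   consecutive) and `midpoint_bp`.
#' @export
candidate_breakpoints <- function(panel, maf_min = 0.10) {
  stopifnot(inherits(panel, "snp_panel"))
  P <- n_snps(panel)
  if (P < 2) {
    return(tibble::tibble(left_snp_index = integer(), right_snp_index = integer(),
                          midpoint_bp = numeric()))
  }
  maf <- panel_maf(panel)
  keep <- pmax(maf[-P], maf[-1]) >= maf_min
  k <- which(keep)
  tibble::tibble(left_snp_index = k, right_snp_index = k + 1L,
                 midpoint_bp = (panel$positions[k] + panel$positions[k + 1L]) / 2)
}

#' Enumerate fixed-length trial windows
#'
#' For each candidate left breakpoint, the right breakpoint is the
#' candidate whose midpoint is closest to `left midpoint +
#' window_size_bp`, provided the resulting span is within
#' `tol_frac * window_size_bp` of the requested size; at most one
#' window per left breakpoint, so the scan is linear in the number of
#' candidates.
#'
#' @param breakpoints tibble from [candidate_breakpoints()].
#' @param window_size_bp requested trial-segment length in base pairs.
#' @param tol_frac tolerated relative deviation of the realized span.
#' @return A tibble with `left` and `right` (row indices into
#'   `breakpoints`), `left_mid` and `right_mid` (bp).
#' @export
enumerate_windows <- function(breakpoints, window_size_bp, tol_frac = 0.25) {
  stopifnot(window_size_bp > 0)
  mids <- breakpoints$midpoint_bp
  nb <- length(mids)
  if (nb < 2) {
    return(tibble::tibble(left = integer(), right = integer(),
                          left_mid = numeric(), right_mid = numeric()))
  }
  target <- mids + window_size_bp
  # nearest candidate midpoint to each target (ties -> earlier candidate)
  j <- findInterval(target, mids)
  j_lo <- pmax(pmin(j, nb), 1L)
  j_hi <- pmin(j + 1L, nb)
  pick <- ifelse(abs(mids[j_lo] - target) <= abs(mids[j_hi] - target), j_lo, j_hi)
  span <- mids[pick] - mids
  ok <- pick > seq_len(nb) & abs(span - window_size_bp) <= tol_frac * window_size_bp
  tibble::tibble(left = which(ok), right = pick[ok],
                 left_mid = mids[ok], right_mid = mids[pick[ok]])
}

# per-breakpoint block caches ---------------------------------------------

# Haplotype panel: N-SNP bitmask of the block left of breakpoint k
# (SNPs k-N+1..k) and right of it (k+1..k+N), per chromosome.
bp_blocks_haplotype <- function(panel, bp_index, N) {
  mat <- panel$matrix
  nb <- length(bp_index)
  A <- matrix(0L, nrow(mat), nb)
  B <- matrix(0L, nrow(mat), nb)
  for (j in seq_len(nb)) {
    k <- bp_index[j]
    A[, j] <- block_masks(mat, (k - N + 1L):k)
    B[, j] <- block_masks(mat, (k + 1L):(k + N))
  }
  list(A = A, B = B)
}

# Genotype panel: phase the 2N-SNP window around each breakpoint once,
# caching per-subject half-block masks of both haplotypes.
bp_blocks_genotype <- function(panel, bp_index, N, tol, max_iter) {
  geno <- panel$matrix
  n <- nrow(geno)
  nb <- length(bp_index)
  h1A <- matrix(0L, n, nb); h1B <- matrix(0L, n, nb)
  h2A <- matrix(0L, n, nb); h2B <- matrix(0L, n, nb)
  flagged <- matrix(FALSE, n, nb)
  # haplotype-pair selection is an argmax; a coarse EM tolerance is
  # ample for the frequency estimates it rests on
  phase_tol <- max(tol, 1e-3)
  for (j in seq_len(nb)) {
    k <- bp_index[j]
    ph <- phase_em_cpp(geno[, (k - N + 1L):(k + N), drop = FALSE],
                       phase_tol, max_iter)
    fl <- ph$flagged
    flagged[, j] <- fl
    hap1 <- ph$hap1; hap2 <- ph$hap2
    if (any(fl)) {
      hap1[fl, ] <- 0L
      hap2[fl, ] <- 0L
    }
    h1A[, j] <- block_masks(hap1, 1:N)
    h1B[, j] <- block_masks(hap1, (N + 1L):(2L * N))
    h2A[, j] <- block_masks(hap2, 1:N)
    h2B[, j] <- block_masks(hap2, (N + 1L):(2L * N))
  }
  list(h1A = h1A, h1B = h1B, h2A = h2A, h2B = h2B, flagged = flagged)
}

#' Score a single trial window
#'
#' Reference single-window pipeline: on haplotype input the four N-SNP
#' blocks flanking the two breakpoints are fitted directly with the
#' null and mixture models; on genotype input the window is first
#' locally phased around each breakpoint ([phase_window()]), the
#' left/right haplotypes paired across the segment ([pair_blocks()])
#' and split into the detection quartet ([split_blocks()]).
#'
#' @param panel a [snp_panel()].
#' @param left_index,right_index left SNP index of the left and right
#'   candidate breakpoints (the breakpoint is between this SNP and the
#'   next).
#' @param N flanking block size in SNPs.
#' @param tol,max_iter EM controls.
#' @return A `window_result` list: breakpoint midpoints, `bic`,
#'   `pi_hat`, per-observation forward responsibilities `resp`,
#'   `n_used`, and the underlying fits.
#' @export
score_window <- function(panel, left_index, right_index, N = 5,
                         tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(panel, "snp_panel"))
  P <- n_snps(panel)
  if (left_index < N || left_index + N > P ||
      right_index < N || right_index + N > P) {
    stop("insufficient flanking SNPs (need ", N, " on each side of each breakpoint)")
  }
  pos <- panel$positions
  left_mid <- (pos[left_index] + pos[left_index + 1]) / 2
  right_mid <- (pos[right_index] + pos[right_index + 1]) / 2

  if (is_haplotype(panel)) {
    mat <- panel$matrix
    b1 <- block_masks(mat, (left_index - N + 1L):left_index)
    b2 <- block_masks(mat, (left_index + 1L):(left_index + N))
    b3 <- block_masks(mat, (right_index - N + 1L):right_index)
    b4 <- block_masks(mat, (right_index + 1L):(right_index + N))
    q <- quartet_from_codes(b1, b2, b3, b4)
    subject <- NULL
  } else {
    left <- phase_window(panel$matrix[, (left_index - N + 1L):(left_index + N),
                                      drop = FALSE], tol, max_iter)
    right <- phase_window(panel$matrix[, (right_index - N + 1L):(right_index + N),
                                       drop = FALSE], tol, max_iter)
    cb <- pair_blocks(left, right, tol, max_iter)
    q <- split_blocks(cb)
    subject <- cb$subject[attr(q, "rows")]
  }
  null <- fit_null(q)
  alt <- fit_mixture(q, null, tol = tol, max_iter = max_iter)
  sc <- score_models(null, alt, q)
  structure(list(left_mid = left_mid, right_mid = right_mid,
                 left_index = left_index, right_index = right_index,
                 bic = sc$bic, pi_hat = alt$pi, resp = alt$resp_fwd,
                 n_used = q$m, subject = subject,
                 null = null, fit = alt, score = sc),
            class = "window_result")
}

#' Sliding-window inversion scan
#'
#' Scans a chromosome with fixed-length trial segments: SNPs are
#' filtered for missingness (genotype input), candidate breakpoints
#' selected by MAF, windows of the requested physical size enumerated
#' (one per left breakpoint), and each window scored with the
#' forward/inverted mixture model against the no-inversion null.  For
#' genotype input each breakpoint's 2N-SNP neighbourhood is phased
#' once and reused across windows.
#'
#' @param panel a [snp_panel()].
#' @param window_size trial segment length in bp.
#' @param N flanking block size in SNPs per breakpoint side (2N <= 16).
#' @param maf_min breakpoint MAF threshold.
#' @param max_missing per-SNP missingness threshold (genotype input).
#' @param window_tol tolerated relative deviation of realized window
#'   span.
#' @param tol,max_iter EM controls.
#' @return An `inv_scan` tibble, one row per scored window, with
#'   columns `left_snp_index`, `right_snp_index`, `left_mid`,
#'   `right_mid` (bp), `bic`, `pi_hat`, `n_used` and `converged`.
#'   Attributes carry the classification votes: for haplotype input a
#'   chromosomes-by-windows logical matrix of per-window inverted
#'   calls; for genotype input a subjects-by-windows integer matrix of
#'   inverted-chromosome counts (0/1/2, NA when a subject was not
#'   usable in a window).
#' @export
scan_inversions <- function(panel, window_size, N = 5, maf_min = 0.10,
                            max_missing = 0.10, window_tol = 0.25,
                            tol = 1e-4, max_iter = 1000) {
  stopifnot(inherits(panel, "snp_panel"))
  if (2 * N > 16) stop("block size N too large: 2N must be <= 16")
  panel <- filter_snps(panel, max_missing)
  bps <- candidate_breakpoints(panel, maf_min)
  P <- n_snps(panel)
  bps <- bps[bps$left_snp_index >= N & bps$left_snp_index + N <= P, ,
             drop = FALSE]
  win <- enumerate_windows(bps, window_size, window_tol)

  empty <- tibble::tibble(left_snp_index = integer(), right_snp_index = integer(),
                          left_mid = numeric(), right_mid = numeric(),
                          bic = numeric(), pi_hat = numeric(),
                          n_used = integer(), converged = logical())
  if (nrow(win) == 0) {
    return(new_inv_scan(empty, panel, window_size, N,
                        votes = NULL, bps = bps))
  }

  bp_used <- sort(unique(c(win$left, win$right)))
  li <- match(win$left, bp_used) - 1L
  ri <- match(win$right, bp_used) - 1L
  bp_index <- bps$left_snp_index[bp_used]

  if (is_haplotype(panel)) {
    cache <- bp_blocks_haplotype(panel, bp_index, N)
    res <- scan_windows_hap_cpp(cache$A, cache$B, li, ri,
                                0.5, tol, max_iter, 1e-12)
    votes <- res$inverted
    n_used <- rep(nrow(panel$matrix), nrow(win))
  } else {
    cache <- bp_blocks_genotype(panel, bp_index, N, tol, max_iter)
    res <- scan_windows_geno_cpp(cache$h1A, cache$h1B, cache$h2A, cache$h2B,
                                 cache$flagged, li, ri, N,
                                 0.5, tol, max_iter, 1e-12)
    votes <- res$count
    n_used <- res$n_used
  }
  out <- tibble::tibble(
    left_snp_index = bps$left_snp_index[win$left],
    right_snp_index = bps$left_snp_index[win$right],
    left_mid = win$left_mid, right_mid = win$right_mid,
    bic = res$bic, pi_hat = res$pi, n_used = as.integer(n_used),
    converged = res$converged)
  keep <- !is.na(out$bic)
  new_inv_scan(out[keep, , drop = FALSE], panel, window_size, N,
               votes = votes[, keep, drop = FALSE], bps = bps)
}

new_inv_scan <- function(tbl, panel, window_size, N, votes, bps) {
  structure(tbl,
            class = unique(c("inv_scan", class(tbl))),
            kind = panel$kind,
            votes = votes,
            sample_ids = panel$sample_ids,
            window_size = window_size,
            N = N,
            n_breakpoints = nrow(bps))
}

#' @export
print.inv_scan <- function(x, ...) {
  cat(sprintf("<inv_scan> %s pathway, window %.5g bp, %d window(s), %d with BIC > 0\n",
              attr(x, "kind"), attr(x, "window_size"), nrow(x),
              sum(x$bic > 0)))
  NextMethod()
}

#' Merge significant overlapping windows into regions of interest
#'
#' Windows with `bic > t_B` are grouped into maximal chains of mutually
#' overlapping `[left_mid, right_mid]` intervals; each group becomes a
#' region of interest bounded by the extreme left/right breakpoint
#' midpoints of its windows, with the group's maximum BIC, its size,
#' and the majority-vote inversion frequency over the group's windows.
#'
#' @param scan an `inv_scan` from [scan_inversions()].
#' @param t_B BIC threshold (strict).
#' @return A tibble with one region per row: `window` (scan window
#'   size, Mb), `LBPmin`, `LBPmax`, `RBPmin`, `RBPmax` (Mb), `MaxBic`,
#'   `invFreq`, `Ns`, ordered by `LBPmin`.
#' @export
merge_regions <- function(scan, t_B = 0) {
  stopifnot(inherits(scan, "inv_scan"))
  sel <- which(scan$bic > t_B)
  empty <- tibble::tibble(window = numeric(), LBPmin = numeric(),
                          LBPmax = numeric(), RBPmin = numeric(),
                          RBPmax = numeric(), MaxBic = numeric(),
                          invFreq = numeric(), Ns = integer())
  if (length(sel) == 0) return(empty)
  lm <- scan$left_mid[sel]
  rm_ <- scan$right_mid[sel]
  o <- order(lm, rm_)
  sel <- sel[o]; lm <- lm[o]; rm_ <- rm_[o]
  # chain mutually overlapping intervals
  grp <- integer(length(sel))
  g <- 1L
  grp[1] <- g
  max_right <- rm_[1]
  for (i in seq_along(sel)[-1]) {
    if (lm[i] > max_right) g <- g + 1L
    grp[i] <- g
    max_right <- max(max_right, rm_[i])
  }
  rois <- lapply(split(seq_along(sel), grp), function(ii) {
    w <- sel[ii]
    tibble::tibble(
      window = attr(scan, "window_size") / 1e6,
      LBPmin = min(lm[ii]) / 1e6, LBPmax = max(lm[ii]) / 1e6,
      RBPmin = min(rm_[ii]) / 1e6, RBPmax = max(rm_[ii]) / 1e6,
      MaxBic = max(scan$bic[w]),
      invFreq = group_inv_frequency(scan, w),
      Ns = length(w))
  })
  out <- dplyr::bind_rows(rois)
  out[order(out$LBPmin), , drop = FALSE]
}

# Majority-vote inversion frequency over a set of window indices (all
# already above the merge threshold).
group_inv_frequency <- function(scan, windows) {
  votes <- attr(scan, "votes")
  if (identical(attr(scan, "kind"), "haplotype")) {
    v <- votes[, windows, drop = FALSE]
    r0I <- rowMeans(!v)            # forward vote share per chromosome
    mean(r0I < 0.5)
  } else {
    cnt <- votes[, windows, drop = FALSE]
    callable <- rowSums(!is.na(cnt)) >= 1
    if (!any(callable)) return(NA_real_)
    subj_count <- apply(cnt[callable, , drop = FALSE], 1, majority_count)
    sum(subj_count) / (2 * sum(callable))
  }
}

# Majority vote over per-window inverted-chromosome counts; ties go to
# the smaller (more conservative) count.
majority_count <- function(counts) {
  counts <- counts[!is.na(counts)]
  tab <- tabulate(counts + 1L, 3L)
  which.max(tab) - 1L             # which.max takes the first (smaller) on ties
}

#' Segmental sensitivity and false discovery rate of a region call
#'
#' Sensitivity is the fraction of the true segment covered by the
#' called segment; FDR the fraction of the called segment outside the
#' truth.  The called segment is, by default, the region's outer
#' envelope `[LBPmin, RBPmax]` — the union of the contributing
#' windows, which is how overlapping probe windows reconstruct an
#' inversion whose length exceeds the window size.  `interval =
#' "inner"` instead scores the conservative core `[LBPmax, RBPmin]`,
#' the part of the region confidently interior to both breakpoints.
#'
#' @param roi one region (a one-row tibble or list with `LBPmin`,
#'   `LBPmax`, `RBPmin`, `RBPmax` in Mb, as produced by
#'   [merge_regions()]).
#' @param truth_segment numeric `c(start, end)` of the true inverted
#'   segment in bp.
#' @param interval `"outer"` (default) or `"inner"`.
#' @return Named numeric vector `c(sensitivity, fdr)`.
#' @export
segmental_metrics <- function(roi, truth_segment,
                              interval = c("outer", "inner")) {
  interval <- match.arg(interval)
  called <- if (interval == "outer") c(roi$LBPmin, roi$RBPmax) * 1e6
            else c(roi$LBPmax, roi$RBPmin) * 1e6
  truth <- as.numeric(truth_segment)
  stopifnot(length(truth) == 2, truth[2] > truth[1])
  clen <- called[2] - called[1]
  if (!is.finite(clen) || clen <= 0) {
    return(c(sensitivity = 0, fdr = 0))
  }
  ov <- max(0, min(called[2], truth[2]) - max(called[1], truth[1]))
  c(sensitivity = ov / (truth[2] - truth[1]),
    fdr = (clen - ov) / clen)
}
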