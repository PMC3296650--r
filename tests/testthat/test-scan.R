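make_geno_panel <- function(mat, positions = NULL) {
  if (is.null(positions)) positions <- seq_len(ncol(mat)) * 100
  snp_panel(mat, positions, kind = "genotype")
}

test_that("missingness filtering removes only over-threshold SNPs", {
  set.seed(2)
  n <- 100
  mat <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
  # 7 SNPs with 11% missing, the rest with at most 10%
  miss11 <- sample(100, 7)
  for (j in miss11) mat[sample(n, 11), j] <- NA
  clean <- setdiff(seq_len(100), miss11)
  for (j in sample(clean, 20)) mat[sample(n, 10), j] <- NA
  panel <- make_geno_panel(mat)
  filtered <- filter_snps(panel, max_missing = 0.10)
  expect_equal(ncol(filtered$matrix), 93)
  expect_equal(attr(filtered, "n_removed"), 7L)
  # no missing data: identity
  full <- make_geno_panel(matrix(rbinom(500, 2, 0.4), 10, 50))
  expect_equal(filter_snps(full)$matrix, full$matrix)
  # all SNPs removed
  allna <- make_geno_panel(matrix(NA_integer_, 10, 5))
  expect_error(filter_snps(allna), "all SNPs")
})

test_that("candidate breakpoints follow the pairwise MAF rule", {
  # 20 chromosomes with allele counts 1, 4, 1, 1, 6 -> MAFs .05 .2 .05 .05 .3
  counts <- c(1, 4, 1, 1, 6)
  mat <- sapply(counts, function(k) c(rep(1L, k), rep(0L, 20 - k)))
  panel <- snp_panel(mat, (1:5) * 1000, "haplotype")
  expect_equal(panel_maf(panel), counts / 20)
  bp <- candidate_breakpoints(panel, maf_min = 0.10)
  expect_equal(bp$left_snp_index, c(1L, 2L, 4L))
  expect_equal(bp$midpoint_bp, c(1500, 2500, 4500))
  # all below threshold: empty; all above: n - 1 breakpoints
  low <- snp_panel(sapply(rep(1, 5), function(k) c(1L, rep(0L, 19))),
                   (1:5) * 1000, "haplotype")
  expect_equal(nrow(candidate_breakpoints(low)), 0)
  hi <- snp_panel(sapply(rep(8, 5), function(k) c(rep(1L, 8), rep(0L, 12))),
                  (1:5) * 1000, "haplotype")
  expect_equal(nrow(candidate_breakpoints(hi)), 4)
})

test_that("window enumeration picks the span closest to the probe size", {
  # uniform grid: each left breakpoint maps to the one ~400 kb away
  bp <- tibble::tibble(left_snp_index = 1:50, right_snp_index = 2:51,
                       midpoint_bp = (1:50) * 1e4)
  win <- enumerate_windows(bp, 4e5)
  # away from the chromosome end every left breakpoint pairs with the
  # candidate exactly 400 kb away; nearer the end the span shrinks but
  # stays within the +/-25% band
  full <- win$left <= 10
  expect_true(all(win$right_mid[full] - win$left_mid[full] == 4e5))
  spans <- win$right_mid - win$left_mid
  expect_true(all(abs(spans - 4e5) <= 1e5))
  expect_equal(nrow(win), 20)
  # no candidate within the tolerance band
  bp2 <- tibble::tibble(left_snp_index = 1:2, right_snp_index = 2:3,
                        midpoint_bp = c(0, 1e6))
  expect_equal(nrow(enumerate_windows(bp2, 4e5)), 0)
  # irregular positions against an exhaustive search
  set.seed(6)
  mids <- sort(sample(1:2e6, 120))
  bp3 <- tibble::tibble(left_snp_index = seq_along(mids),
                        right_snp_index = seq_along(mids) + 1L,
                        midpoint_bp = mids)
  win3 <- enumerate_windows(bp3, 3e5)
  for (i in seq_along(mids)) {
    spans <- mids - mids[i]
    ok <- which(spans > 0 & abs(spans - 3e5) <= 0.25 * 3e5)
    j <- win3$right[win3$left == i]
    if (length(ok) == 0) {
      expect_length(j, 0)
    } else {
      best <- ok[which.min(abs(spans[ok] - 3e5))]
      expect_equal(j, best)
    }
  }
  # one window per left breakpoint at most (linear scan)
  expect_lte(nrow(win3), nrow(bp3))
})

test_that("regions of interest merge overlapping significant windows", {
  votes <- matrix(FALSE, 4, 2) # 4 chromosomes, none inverted
  sc <- fake_scan(left_mid = c(0.70e6, 0.75e6), right_mid = c(1.10e6, 1.15e6),
                  bic = c(120, 90), votes = votes)
  roi <- merge_regions(sc, t_B = 50)
  expect_equal(nrow(roi), 1)
  expect_equal(roi$LBPmin, 0.70)
  expect_equal(roi$LBPmax, 0.75)
  expect_equal(roi$RBPmin, 1.10)
  expect_equal(roi$RBPmax, 1.15)
  expect_equal(roi$MaxBic, 120)
  expect_equal(roi$Ns, 2L)
  expect_equal(roi$invFreq, 0)

  # threshold excludes everything
  expect_equal(nrow(merge_regions(sc, t_B = 150)), 0)

  # two disjoint clusters, ordered by LBPmin, invariant to row order
  votes4 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 4)
  sc2 <- fake_scan(left_mid = c(2.0e6, 0.5e6, 0.55e6, 2.05e6),
                   right_mid = c(2.4e6, 0.9e6, 0.95e6, 2.45e6),
                   bic = c(80, 70, 60, 90), votes = votes4)
  roi2 <- merge_regions(sc2, t_B = 0)
  expect_equal(nrow(roi2), 2)
  expect_equal(roi2$LBPmin, c(0.5, 2.0))
  expect_equal(roi2$Ns, c(2L, 2L))
  expect_equal(roi2$invFreq, c(0.5, 0.5))
  perm <- c(3, 1, 4, 2)
  sc3 <- fake_scan(left_mid = sc2$left_mid[perm], right_mid = sc2$right_mid[perm],
                   bic = sc2$bic[perm], votes = votes4[, perm])
  expect_equal(merge_regions(sc3, t_B = 0), roi2)
})

test_that("segmental sensitivity and FDR follow interval arithmetic", {
  roi <- list(LBPmin = 0.75, LBPmax = 0.95, RBPmin = 1.05, RBPmax = 1.25)
  expect_equal(segmental_metrics(roi, c(0.75e6, 1.25e6)),
               c(sensitivity = 1, fdr = 0))
  # the conservative core only covers the confidently interior part
  expect_equal(segmental_metrics(roi, c(0.75e6, 1.25e6), "inner"),
               c(sensitivity = 0.2, fdr = 0))
  half <- list(LBPmin = 0.875, RBPmax = 1.125)
  expect_equal(segmental_metrics(half, c(0.75e6, 1.25e6)),
               c(sensitivity = 0.5, fdr = 0))
  off <- list(LBPmin = 1.0, RBPmax = 1.5)
  expect_equal(segmental_metrics(off, c(0.75e6, 1.25e6)),
               c(sensitivity = 0.5, fdr = 0.5))
  degenerate <- list(LBPmax = 1.3, RBPmin = 1.2)
  expect_equal(segmental_metrics(degenerate, c(0.75e6, 1.25e6), "inner"),
               c(sensitivity = 0, fdr = 0))
})

test_that("score_window rejects breakpoints without full flanks", {
  sim <- small_sim()
  expect_error(score_window(sim$haplotypes, 2, 100, N = 5), "flanking")
})

test_that("batch scan agrees with the single-window reference pipeline", {
  sim <- small_sim()
  scan <- scan_inversions(sim$haplotypes, 2e5, N = 5)
  expect_gt(nrow(scan), 0)
  for (i in unique(c(1, which.max(scan$bic)))) {
    w <- score_window(sim$haplotypes, scan$left_snp_index[i],
                      scan$right_snp_index[i], N = 5, tol = 1e-4)
    expect_equal(w$bic, scan$bic[i], tolerance = 1e-6)
    expect_equal(w$pi_hat, scan$pi_hat[i], tolerance = 1e-6)
  }
  # window count never exceeds the candidate-breakpoint count
  expect_lte(nrow(scan), attr(scan, "n_breakpoints"))
})

test_that("genotype and haplotype scans share the window grid", {
  sim <- small_sim()
  sg <- scan_inversions(sim$genotypes, 2e5, N = 5)
  sh <- scan_inversions(sim$haplotypes, 2e5, N = 5)
  expect_equal(sg$left_snp_index, sh$left_snp_index)
  expect_equal(attr(sg, "kind"), "genotype")
  cnt <- attr(sg, "votes")
  expect_true(all(cnt[!is.na(cnt)] %in% 0:2))
})
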