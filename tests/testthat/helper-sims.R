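# Expensive simulation/scan results shared across test files.  Each
# accessor computes lazily on first use and memoizes compact summaries
# only (never whole panels or vote matrices), so the suite fits the
# session's memory and time budget.
.sim_cache <- new.env(parent = emptyenv())

# small panel for plumbing tests: short segment, few subjects
small_sim <- function(seed = 11, inv_freq = 0.5) {
  key <- paste0("small_", seed, "_", inv_freq)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_population(
      sim_config(segment_length_bp = 6e5, inv_start_bp = 2e5, inv_end_bp = 4e5,
                 inv_freq = inv_freq, n_subjects = 150, snp_spacing_kb = 1),
      seed = seed)
  }
  .sim_cache[[key]]
}

# Detection round-trip replicates: default study conditions
# (2 Mb segment, 0.5 Mb inversion at 0.75-1.25 Mb, pi = 0.4, 1000
# subjects), haplotype-pathway scan at window 0.3 Mb, N = 5.
roundtrip_replicates <- function(n_seeds = 20) {
  if (!is.null(.sim_cache$roundtrip)) return(.sim_cache$roundtrip)
  res <- lapply(seq_len(n_seeds), function(s) {
    sim <- simulate_population(sim_config(inv_freq = 0.4), seed = s)
    pos <- sim$haplotypes$positions
    density <- (max(pos) - min(pos)) / 1000 / length(pos)
    scan <- scan_inversions(sim$haplotypes, 0.3e6, N = 5)
    rois <- merge_regions(scan, t_B = 0)
    best <- if (nrow(rois)) rois[which.max(rois$MaxBic), ] else NULL
    sm <- if (!is.null(best)) segmental_metrics(best, sim$segment) else
      c(sensitivity = 0, fdr = 0)
    inside <- scan$left_mid >= sim$segment[1] & scan$right_mid <= sim$segment[2]
    prof <- accuracy_profile(scan, sim$truth$orientation)
    list(density = density,
         sensitivity = unname(sm["sensitivity"]),
         fdr = unname(sm["fdr"]),
         n_inside = sum(inside),
         n_inside_pos = sum(scan$bic[inside] > 0),
         n_windows = nrow(scan),
         n_breakpoints = attr(scan, "n_breakpoints"),
         inv_freq_roi = if (!is.null(best)) best$invFreq else NA_real_,
         max_accuracy = max(prof$accuracy, na.rm = TRUE))
  })
  .sim_cache$roundtrip <- res
  res
}

# Subject-genotyping replicates: pi = 0.6, genotype pathway, window
# 0.6 x inversion length = 0.3 Mb, N = 5.
genotype_replicates <- function(n_seeds = 20) {
  if (!is.null(.sim_cache$genotype)) return(.sim_cache$genotype)
  res <- lapply(seq_len(n_seeds), function(s) {
    sim <- simulate_population(sim_config(inv_freq = 0.6), seed = s)
    scan <- scan_inversions(sim$genotypes, 0.3e6, N = 5)
    grid <- unique(c(0, stats::quantile(scan$bic, 0.9, names = FALSE),
                     stats::quantile(scan$bic[scan$bic > 0],
                                     seq(0.1, 0.9, 0.1), names = FALSE)))
    prof <- accuracy_profile(scan, sim$subject_truth, t_grid = grid)
    out <- list(max_accuracy = max(prof$accuracy, na.rm = TRUE),
                acc_t0 = prof$accuracy[prof$t_B == 0],
                acc_q90 = prof$accuracy[which.min(abs(
                  prof$t_B - stats::quantile(scan$bic, 0.9, names = FALSE)))])
    if (s == 1) {
      # retained for the pathway-concordance check
      hap_scan <- scan_inversions(sim$haplotypes, 0.3e6, N = 5)
      hprof <- accuracy_profile(hap_scan, sim$truth$orientation)
      key_g <- paste(scan$left_snp_index, scan$right_snp_index)
      key_h <- paste(hap_scan$left_snp_index, hap_scan$right_snp_index)
      shared <- intersect(key_g, key_h)
      out$hap_max_accuracy <- max(hprof$accuracy, na.rm = TRUE)
      out$bic_cor <- stats::cor(scan$bic[match(shared, key_g)],
                                hap_scan$bic[match(shared, key_h)])
    }
    out
  })
  .sim_cache$genotype <- res
  res
}

# Null-specificity replicates: no-inversion populations, haplotype
# pathway, window 0.4 Mb; retains per-seed window BIC summaries.
null_replicates <- function(n_seeds = 20) {
  if (!is.null(.sim_cache$nulls)) return(.sim_cache$nulls)
  res <- lapply(seq_len(n_seeds), function(s) {
    sim <- simulate_null(sim_config(), seed = s)
    scan <- scan_inversions(sim$haplotypes, 0.4e6, N = 5)
    list(max_bic = max(scan$bic), bic = scan$bic)
  })
  .sim_cache$nulls <- res
  res
}

# fabricate a minimal inv_scan for vote/merge unit tests
fake_scan <- function(left_mid, right_mid, bic, votes, kind = "haplotype",
                      window_size = 4e5) {
  stopifnot(ncol(votes) == length(bic))
  tbl <- tibble::tibble(
    left_snp_index = seq_along(bic), right_snp_index = seq_along(bic) + 1L,
    left_mid = left_mid, right_mid = right_mid, bic = bic,
    pi_hat = rep(0.5, length(bic)), n_used = nrow(votes),
    converged = TRUE)
  structure(tbl, class = unique(c("inv_scan", class(tbl))),
            kind = kind, votes = votes,
            sample_ids = paste0(if (kind == "haplotype") "chr" else "subj",
                                seq_len(nrow(votes))),
            window_size = window_size, N = 5L,
            n_breakpoints = length(bic) + 1L)
}
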