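#' Simulation configuration for a synthetic inversion population
#'
#' Defaults describe a 2 Mb segment carrying a 0.5 Mb inversion at
#' 0.75-1.25 Mb segregating at frequency 0.40 in 1000 subjects, with
#' SNP density calibrated to ~0.33 kb/SNP and per-SNP heterozygosity
#' around one third (typical of dense SNP panels).
#'
#' @param segment_length_bp simulated segment length (bp).
#' @param inv_start_bp,inv_end_bp inverted segment boundaries (bp).
#' @param inv_freq population frequency of the inverted arrangement.
#' @param n_subjects number of diploid subjects (chromosomes = 2x).
#' @param snp_spacing_kb mean SNP spacing in kb.
#' @param divergence_mutations number of fixed differences between the
#'   two arrangements inside the inverted segment.
#' @param recomb_rate_per_bp per-bp crossover (template switch) rate of
#'   the founder-mosaic copying process.
#' @param background_mutation_diversity per-site, per-chromosome fresh
#'   mutation probability.
#' @param n_founders founder haplotypes in the background pool (also
#'   the forward-arrangement pool inside the segment).
#' @param n_inv_founders founder haplotypes of the inverted
#'   arrangement inside the segment (fewer: a younger clade).
#' @param seed optional RNG seed applied by [simulate_population()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(segment_length_bp = 2e6,
                       inv_start_bp = 0.75e6,
                       inv_end_bp = 1.25e6,
                       inv_freq = 0.4,
                       n_subjects = 1000,
                       snp_spacing_kb = 0.33,
                       divergence_mutations = 30,
                       recomb_rate_per_bp = 1e-5,
                       background_mutation_diversity = 0.002,
                       n_founders = 10,
                       n_inv_founders = 4,
                       seed = NULL) {
  cfg <- list(segment_length_bp = segment_length_bp,
              inv_start_bp = inv_start_bp, inv_end_bp = inv_end_bp,
              inv_freq = inv_freq, n_subjects = n_subjects,
              snp_spacing_kb = snp_spacing_kb,
              divergence_mutations = divergence_mutations,
              recomb_rate_per_bp = recomb_rate_per_bp,
              background_mutation_diversity = background_mutation_diversity,
              n_founders = n_founders, n_inv_founders = n_inv_founders,
              seed = seed)
  stopifnot(cfg$segment_length_bp > 0, cfg$snp_spacing_kb > 0,
            cfg$inv_freq >= 0, cfg$inv_freq <= 1,
            cfg$inv_start_bp >= 0, cfg$inv_end_bp > cfg$inv_start_bp,
            cfg$inv_end_bp <= cfg$segment_length_bp, cfg$n_subjects >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a population carrying an inversion polymorphism
#'
#' Generates haplotypes, genotypes, SNP positions and per-chromosome
#' orientation truth for a population segregating an inversion with
#' the linkage-disequilibrium signature the detector assumes.  Each
#' chromosome is a recombinant mosaic over founder haplotypes; inside
#' the inverted segment the two arrangements draw from separate
#' founder pools differing at `divergence_mutations` fixed sites,
#' crossovers between arrangements are suppressed (a crossover inside
#' the segment survives with probability equal to its arrangement's
#' population frequency, mimicking suppression in heterokaryotypes),
#' and inverted chromosomes recombine along their inverted physical
#' order.  Allele storage order is never reversed: SNP arrays report
#' reference-strand coordinates regardless of orientation, so the
#' detectable signal is LD, not coordinate reversal.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (overrides `cfg$seed`).
#' @return An `inv_sim` list: `haplotypes` and `genotypes`
#'   ([snp_panel()]s), `truth` (tibble with `chromosome`, `subject`,
#'   `orientation`), `subject_truth` (tibble with `id`, `count`,
#'   `status`), `segment` (`c(start, end)` bp) and `config`.
#' @export
simulate_population <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- cfg$segment_length_bp
  spacing <- cfg$snp_spacing_kb * 1000
  nc <- 2L * cfg$n_subjects
  if (cfg$inv_freq > 0 && cfg$inv_freq * nc < 1) {
    warning("inv_freq * 2n < 1: the inversion may be absent from the sample")
  }

  # SNP positions at exponential spacings (min 1 bp apart)
  gaps <- pmax(1, round(stats::rexp(ceiling(L / spacing * 1.4) + 50, 1 / spacing)))
  pos <- cumsum(gaps)
  while (max(pos) < L) {
    gaps <- pmax(1, round(stats::rexp(200, 1 / spacing)))
    pos <- c(pos, max(pos) + cumsum(gaps))
  }
  pos <- pos[pos <= L]
  P <- length(pos)
  if (P < 2) stop("segment too short for the requested SNP spacing")

  # per-SNP allele frequencies: MAF law chosen so that the median
  # per-SNP heterozygote fraction lands near one third
  maf <- 0.05 + 0.45 * stats::runif(P)^1.2
  p <- ifelse(stats::runif(P) < 0.5, maf, 1 - maf)

  Fb <- cfg$n_founders
  founders <- matrix(stats::rbinom(Fb * P, 1L, rep(p, each = Fb)), Fb, P)
  founders <- fix_monomorphic(founders)

  use_segment <- cfg$inv_freq > 0 || cfg$divergence_mutations > 0
  idx_in <- which(pos >= cfg$inv_start_bp & pos <= cfg$inv_end_bp)
  templates_fwd <- founders
  templates_inv <- NULL

  if (use_segment && length(idx_in) > 0) {
    p_in <- p[idx_in]
    Pi_ <- length(idx_in)
    # forward arrangement: standing variation (the background founders)
    pool_f <- founders[, idx_in, drop = FALSE]
    # inverted arrangement: a young clade copied from one ancestral
    # segment haplotype with light within-clade mutation noise
    Fi <- cfg$n_inv_founders
    ancestor <- stats::rbinom(Pi_, 1L, p_in)
    nd <- min(cfg$divergence_mutations, Pi_)
    if (nd > 0) {
      ds <- sort(sample.int(Pi_, nd))
      # fixed differences: ancestor carries the allele opposite to the
      # forward-pool majority at the divergence sites
      maj <- as.integer(colMeans(pool_f[, ds, drop = FALSE]) >= 0.5)
      ancestor[ds] <- 1L - maj
    }
    clade_mu <- 0.02   # per-site within-clade divergence from the ancestor
    pool_i <- matrix(rep(ancestor, each = Fi), Fi, Pi_)
    flips <- matrix(stats::runif(Fi * Pi_) < clade_mu, Fi, Pi_)
    pool_i[flips] <- 1L - pool_i[flips]
    templates_fwd[, idx_in] <- pool_f
    templates_inv <- founders
    templates_inv[, idx_in] <- pool_i[((seq_len(Fb) - 1L) %% Fi) + 1L, ,
                                      drop = FALSE]
  }

  orientation <- stats::runif(nc) < cfg$inv_freq
  # traversal order of SNPs on an inverted chromosome: interior reversed
  pos_inv <- pos
  pos_inv[idx_in] <- cfg$inv_start_bp + cfg$inv_end_bp - pos[idx_in]
  ord_inv <- order(pos_inv)
  pt_inv <- pos_inv[ord_inv]

  hap <- matrix(0L, nc, P)
  rho <- cfg$recomb_rate_per_bp
  for (i in seq_len(nc)) {
    inv_i <- orientation[i] && !is.null(templates_inv)
    keep_prob <- if (inv_i) cfg$inv_freq else 1 - cfg$inv_freq
    if (!use_segment) keep_prob <- 1
    nx <- stats::rpois(1, rho * L)
    xs <- sort(stats::runif(nx, 0, L))
    if (length(xs) && use_segment) {
      inside <- xs >= cfg$inv_start_bp & xs <= cfg$inv_end_bp
      xs <- xs[!inside | stats::runif(length(xs)) < keep_prob]
    }
    tid <- sample.int(Fb, length(xs) + 1L, replace = TRUE)
    if (inv_i) {
      seg <- findInterval(pt_inv, xs) + 1L
      hap[i, ord_inv] <- templates_inv[cbind(tid[seg], ord_inv)]
    } else {
      seg <- findInterval(pos, xs) + 1L
      hap[i, ] <- templates_fwd[cbind(tid[seg], seq_len(P))]
    }
  }

  # fresh mutations
  mu <- cfg$background_mutation_diversity
  if (mu > 0) {
    n_flip <- stats::rbinom(1, nc * P, mu)
    if (n_flip > 0) {
      cells <- sample.int(nc * P, n_flip)
      hap[cells] <- 1L - hap[cells]
    }
  }

  geno <- hap[seq(1, nc, by = 2), , drop = FALSE] +
    hap[seq(2, nc, by = 2), , drop = FALSE]
  subj_ids <- paste0("subj", seq_len(cfg$n_subjects))
  chrom_ids <- paste0(rep(subj_ids, each = 2), "_", rep(1:2, cfg$n_subjects))
  truth <- tibble::tibble(
    chromosome = chrom_ids,
    subject = rep(subj_ids, each = 2),
    orientation = ifelse(orientation, "inverted", "forward"))
  cnt <- as.integer(orientation[seq(1, nc, 2)]) +
    as.integer(orientation[seq(2, nc, 2)])
  subject_truth <- tibble::tibble(
    id = subj_ids, count = cnt,
    status = c("hom_ref", "het_inv", "hom_inv")[cnt + 1L])

  structure(list(
    haplotypes = snp_panel(hap, pos, "haplotype", sample_ids = chrom_ids),
    genotypes = snp_panel(geno, pos, "genotype", sample_ids = subj_ids),
    truth = truth, subject_truth = subject_truth,
    segment = c(cfg$inv_start_bp, cfg$inv_end_bp),
    config = cfg), class = "inv_sim")
}

#' Simulate a population without an inversion
#'
#' The same founder-mosaic process with no inverted arrangement, no
#' arrangement divergence and free recombination everywhere; all
#' chromosomes are labelled forward.
#'
#' @param cfg a [sim_config()] (its `inv_freq` and
#'   `divergence_mutations` are overridden to zero).
#' @param seed RNG seed.
#' @return An `inv_sim`, as [simulate_population()].
#' @export
simulate_null <- function(cfg = sim_config(), seed = cfg$seed) {
  cfg$inv_freq <- 0
  cfg$divergence_mutations <- 0L
  simulate_population(cfg, seed)
}

# ensure every column is polymorphic across founder rows
fix_monomorphic <- function(f) {
  cs <- colSums(f)
  mono <- which(cs == 0L | cs == nrow(f))
  if (length(mono)) {
    rows <- sample.int(nrow(f), length(mono), replace = TRUE)
    f[cbind(rows, mono)] <- 1L - f[cbind(rows, mono)]
  }
  f
}

#' Summary statistics of a SNP panel
#'
#' SNP density (kb per SNP, segment span over SNP count), the
#' heterozygote fraction (computed both per SNP across subjects and
#' per subject across SNPs; the per-SNP median is the calibration
#' quantity), and a binned r-squared LD decay profile.
#'
#' @param panel a [snp_panel()]; haplotype rows are paired
#'   consecutively into subjects for the heterozygosity computation.
#' @param max_pairs maximum number of SNP pairs sampled for the LD
#'   profile.
#' @param bin_kb LD profile distance bin width (kb).
#' @return A list with `snp_density_kb_per_snp`, `median_het_snp`,
#'   `median_het_subject`, and `r2_profile` (tibble with `dist_kb`,
#'   `mean_r2`, `n_pairs`).
#' @export
summary_stats <- function(panel, max_pairs = 20000, bin_kb = 25) {
  stopifnot(inherits(panel, "snp_panel"))
  P <- n_snps(panel)
  if (P < 2) stop("summary statistics require at least 2 SNPs")
  pos <- panel$positions
  density <- (max(pos) - min(pos)) / 1000 / P

  if (is_haplotype(panel)) {
    h <- panel$matrix
    geno <- h[seq(1, nrow(h), 2), , drop = FALSE] +
      h[seq(2, nrow(h), 2), , drop = FALSE]
  } else {
    geno <- panel$matrix
    h <- NULL
  }
  het_snp <- colMeans(geno == 1L, na.rm = TRUE)
  het_subj <- rowMeans(geno == 1L, na.rm = TRUE)

  i <- sample.int(P - 1, min(max_pairs, 5 * P), replace = TRUE)
  off <- 1L + stats::rgeom(length(i), 2 / 50)   # mix of short/long ranges
  j <- pmin(i + off, P)
  ok <- j > i
  i <- i[ok]; j <- j[ok]
  m <- if (!is.null(h)) h else geno
  r2 <- vapply(seq_along(i), function(k) {
    suppressWarnings(stats::cor(m[, i[k]], m[, j[k]],
                                use = "complete.obs")^2)
  }, numeric(1))
  d <- (pos[j] - pos[i]) / 1000
  bin <- floor(d / bin_kb) * bin_kb + bin_kb / 2
  prof <- stats::aggregate(r2, list(dist_kb = bin),
                           function(x) mean(x, na.rm = TRUE))
  counts <- as.integer(table(bin))
  list(snp_density_kb_per_snp = density,
       median_het_snp = stats::median(het_snp),
       median_het_subject = stats::median(het_subj),
       r2_profile = tibble::tibble(dist_kb = prof$dist_kb,
                                   mean_r2 = prof$x,
                                   n_pairs = counts))
}
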