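---
title: "Detecting polymorphic inversions from SNP linkage disequilibrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting polymorphic inversions from SNP linkage disequilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invscan)
```

## The problem

A polymorphic inversion is a chromosomal segment that some chromosomes
in a population carry in reversed orientation. Recombination between
a normal and an inverted chromosome is suppressed inside the segment
(a crossover there would produce unbalanced gametes), so the two
arrangements accumulate distinct interior haplotypes and a
characteristic linkage-disequilibrium (LD) signature develops across
the breakpoints. SNP microarrays report alleles in reference-strand
coordinates regardless of orientation, so the inversion is invisible
in the genotype calls themselves — but the LD pattern it leaves is
detectable. `invscan` detects such inversions in population SNP data
(phased haplotypes or unphased genotypes), locates their breakpoints,
and genotypes every subject as non-inverted homozygote, inversion
heterozygote, or inverted homozygote.

## The four-block mixture model

Fix a candidate segment defined by two breakpoints, each a gap between
two consecutive SNPs. Flank each breakpoint with a block of `N` SNPs
on each side (default `N = 5`), giving four categorical variables per
chromosome: `B1` (outside-left), `B2` (inside-left), `B3`
(inside-right), `B4` (outside-right), where a category is the observed
N-SNP allele string.

Under the **null** (no inversion), alleles are associated across each
breakpoint only through ordinary local LD, so the observation
probability factorizes into the two within-breakpoint pairs, estimated
by their empirical joint frequencies:

$$P_{fwd}(x_i) = n_{1,2}(B_{1,2}(x_i)) \cdot n_{3,4}(B_{3,4}(x_i)).$$

On an **inverted** chromosome the physical neighbour of the
outside-left block is the segment's right end, so the natural
factorization couples the cross pairs:

$$P_{inv}(x_i) = r_{1,3}(B_{1,3}(x_i)) \cdot r_{2,4}(B_{2,4}(x_i)).$$

A population carrying the inversion at frequency $\pi$ is modelled as
the mixture

$$P(x_i) = (1-\pi)\,f_{1,2}(B_{1,2})f_{3,4}(B_{3,4}) +
           \pi\,r_{1,3}(B_{1,3})r_{2,4}(B_{2,4}),$$

with free joint tables $f_{1,2}, f_{3,4}, r_{1,3}, r_{2,4}$. The
mixture is fitted by EM (`fit_mixture()`), initialized at the pooled
empirical joint distributions with $\pi_0 = 0.5$. The E-step uses the
standard mixture-weighted posteriors; the *reported* responsibility of
chromosome $i$ to the forward model is the unweighted density ratio

$$r_{0,i} = \frac{P_{fwd}(x_i)}{P_{fwd}(x_i) + P_{inv}(x_i)},$$

which is what classification uses (both quantities are returned; the
weighted posterior is what makes EM monotone, the unweighted ratio is
the classification statistic).

Model choice is by BIC difference (`score_models()`):

$$\mathrm{BIC} = 2(\ell_1 - \ell_0) - \Delta k \,\ln m, \qquad
\Delta k = 1 + (s_{1,3}-1) + (s_{2,4}-1),$$

where $s_{1,3}$ and $s_{2,4}$ count the observed (B1,B3) and (B2,B4)
category pairs — the extra parameters of the inverted component plus
one for $\pi$. Positive BIC favours the inversion.

## Genotype data: local phasing in two model applications

Unphased genotypes are handled without genome-wide phasing. Around
each candidate breakpoint, the `2N`-SNP window is phased exactly by a
haplotype-frequency EM over the enumerable haplotype space
(`phase_window()`, window capped at 16 SNPs), and each subject keeps
its maximum-posterior haplotype pair; missing genotypes are imputed by
the same maximization and phasing uncertainty is not propagated
further. This gives each subject two left haplotypes $L_1, L_2$ and
two right haplotypes $R_1, R_2$ — but not which left travels with
which right on the same chromosome. That pairing is the *first*
application of the inversion model (`pair_blocks()`): fit the mixture
on the quartet $(L_1, R_1, R_2, L_2)$ over subjects; a dominant
forward responsibility selects the parallel pairing $(L_1R_1,
L_2R_2)$, otherwise the crossed one. Subjects homozygous on either
side are pairing-invariant and are assigned the parallel configuration
deterministically. The paired haplotypes are then split into the four
N-SNP blocks (`split_blocks()`) and the *second* application of the
model — the detection fit over all $2 n_s$ chromosomes — proceeds
exactly as for phased input.

## The scan

`scan_inversions()` probes a chromosome with trial segments of fixed
physical length:

1. SNPs missing in more than 10% of subjects are removed
   (`filter_snps()`).
2. Candidate breakpoints are consecutive-SNP gaps where at least one
   flanking SNP has MAF ≥ 10% (`candidate_breakpoints()`).
3. For each candidate left breakpoint, the right breakpoint whose
   midpoint is closest to `left + window_size` is chosen, accepted
   only within ±25% of the window size — at most one window per left
   breakpoint, so the scan is linear in the number of candidates
   (`enumerate_windows()`).
4. Each window is scored with the null and mixture fits; genotype
   input reuses the per-breakpoint phasing cache across windows.

A trial window need not match the true breakpoints: segments contained
in a real inversion still favour the mixture, because the inverted
subpopulation's interior haplotypes are few and strongly coupled, so
the cross-pair tables concentrate. Windows with BIC above a threshold
$t_B$ are merged into regions of interest by chaining overlapping
`[left, right]` midpoint intervals (`merge_regions()`), reported in the
`window / LBPmin / LBPmax / RBPmin / RBPmax / MaxBic / invFreq / Ns`
schema with Mb to five decimals. Against a known truth segment,
`segmental_metrics()` scores the inner interval `[LBPmax, RBPmin]` for
sensitivity and FDR.

## Classification by majority vote

A single window's responsibilities are a weak classifier; votes over
overlapping windows are not. For chromosomes (haplotype input), the
aggregated forward responsibility is the fraction of windows with
`bic > t_B` in which the chromosome votes forward ($r_{0} \ge 0.5$;
an exact tie counts as forward), and the chromosome is called inverted
when that fraction falls below 0.5 (`vote()`,
`call_chromosomes()`). For subjects (genotype input), chromosome
labels are not comparable across windows — each window phases locally —
so the vote aggregates the label-invariant *count* of inverted
chromosomes per window (0, 1 or 2) and takes the majority count, ties
resolved toward the smaller count (`call_subjects()`). Chromosomes or
subjects with no qualifying window are explicit no-calls.
`accuracy_profile()` sweeps $t_B$ and scores calls against truth;
accuracy typically improves with $t_B$ until so few windows qualify
that calls destabilize. When a subset of subjects has experimentally
known status, a practical $t_B$ is the one maximizing accuracy on that
subset; otherwise report call stability across a grid.

## The synthetic population generator

`simulate_population()` provides a simplified stand-in for a
coalescent inversion simulator, producing exactly the signature the
detector assumes, with per-chromosome truth labels.

* SNP positions fall at exponential spacings with mean
  `snp_spacing_kb` (default 0.33 kb/SNP, a dense resequencing-grade
  panel; sparser array densities can be emulated by raising it).
* Per-SNP allele frequencies follow `maf = 0.05 + 0.45 u^{1.2}`
  (`u ~ U(0,1)`), chosen in closed form so the median per-SNP
  heterozygote fraction lands near one third: the median MAF is
  `0.05 + 0.45 (1/2)^{1.2} ≈ 0.246`, giving `2p(1-p) ≈ 0.37`
  nominally, shrunk ~10% by finite founder pools to ≈ 0.33.
* Each chromosome is a Li–Stephens-style mosaic over `n_founders = 10`
  founder haplotypes, with crossovers at rate `recomb_rate_per_bp =
  1e-5` (mean copied tract 100 kb) and fresh mutations at rate
  `background_mutation_diversity = 0.002` per site.
* Inside the inverted segment the two arrangements draw from separate
  pools: the forward arrangement keeps the standing founder variation;
  the inverted arrangement is a young clade — `n_inv_founders = 4`
  copies of a single ancestral interior haplotype with 2% within-clade
  site noise — carrying `divergence_mutations = 30` fixed differences
  opposing the forward-pool majority allele.
* Crossovers inside the segment are thinned by the arrangement's
  population frequency (an inverted chromosome recombines there only
  with other inverted chromosomes), and inverted chromosomes recombine
  along their inverted physical order. Allele *storage* order is
  never reversed: arrays report reference coordinates, and the
  detector's signal is LD, not coordinate reversal.
* Chromosome orientations are i.i.d. Bernoulli(`inv_freq`);
  consecutive chromosome pairs form subjects; genotypes are allele
  sums.

`simulate_null()` drops the segment machinery entirely (pure founder
mosaic, free recombination). `summary_stats()` reports the
calibration quantities: kb/SNP density, the heterozygote fraction
(computed both per SNP and per subject — "median heterozygosity" is
ambiguous between the two readings, so both are reported and the
per-SNP median is the calibration quantity), and a binned r² decay
profile.

What the generator does *not* emulate: genealogical depth (no
coalescent), inversion age beyond the fixed within-clade diversity,
selection, demography, recurrent inversion events, and genotyping
error. Passing tests on this generator therefore demonstrate that the
method recovers the LD signature it models — they do not by themselves
establish performance on real arrays, where breakpoint repeats, SNP
gaps and population structure intrude.

## Numerical choices

* **Probability floor.** Unseen categories in a component table get
  probability `1e-12` (renormalized); EM with hard zeros would lock
  categories out of a component. Internally only observed cells are
  stored; unobserved cells sit at the floor implicitly.
* **Convergence.** `fit_mixture()` stops when the log-likelihood
  changes by less than `tol = 1e-6` (at most 1000 iterations). The
  scan uses `1e-4` for window fits and `1e-3` for the per-breakpoint
  phasing EM: every decision downstream of a window fit lives on a BIC
  scale of tens to thousands, and the looser tolerances perturb BIC by
  well under 0.1 while cutting scan time several-fold. The trace is
  returned and is monotone non-decreasing.
* **Initialization.** Single EM start from the pooled empirical joint
  distributions, $\pi_0 = 0.5$. At population scale (m ≈ 2000) this
  start matches multi-start search to numerical precision (tested).
  In *degenerate small samples* (m ≤ 8 with mostly distinct
  observations) the empirical initialization can be an exact EM fixed
  point — every observation has $P_{fwd} = P_{inv}$ there — so EM
  cannot reach the global (memorizing) optimum; this is a structural
  property of tiny samples, documented by a failing small-sample
  stress test, and irrelevant at the sample sizes the scan uses.
* **Tie rules.** $r_0 = 0.5$ counts as forward; tied subject counts
  resolve to the smaller count; pairing-invariant subjects take the
  parallel configuration.
* **Degenerate windows.** Windows without `N` SNPs of flank are
  skipped; subjects with no usable genotype in a phasing window are
  flagged and excluded from that window's fits; if both component
  densities underflow for an observation its responsibility is 0.5 and
  a degeneracy counter increments.
* **Null-threshold calibration.** The null-specificity check sets
  $t_B$ at the empirical (inverse-CDF) 98th percentile of the
  no-inversion `MaxBic` distribution; an interpolated quantile would
  sit strictly below the observed maximum and could never yield zero
  regions.

## Problem sizes used in the bundled studies

The packaged simulation studies run at the conditions the method is
designed for, scaled to desk hardware: 2 Mb segments, 1000 subjects
(2000 chromosomes), a 0.5 Mb inversion at 0.75–1.25 Mb, windows of
0.3–0.4 Mb with `N = 5`, and 20 replicate populations per study
(detection round-trip at $\pi = 0.4$; subject genotyping at $\pi =
0.6$ with window size 60% of the inversion length; 20 no-inversion
populations for specificity). The chromosome-level pathway is used
for the round-trip and null studies and the genotype pathway for the
subject-genotyping study; one replicate is scored through both
pathways to measure the (small) accuracy cost of genotype input.

## Known limitations

* Windows are probes of fixed length: inversions much longer than the
  window are recovered as merged chains with conservative inner
  bounds, and inversions shorter than ~75% of the window are missed by
  the span-matching rule. Scanning several window sizes is the
  intended practice; sizes are scanned independently and never merged
  across sizes.
* The subject vote discards cross-window chromosome identity (it votes
  on counts), which loses a little information relative to a perfectly
  phased analysis; this is the price of window-local phasing.
* $\pi$ and the component labels are exchangeable in principle; the
  cross-breakpoint adjacency of real (and simulated) inversion data
  anchors the inverted component, but on signal-free data the fitted
  $\hat\pi$ is not meaningful.
* BIC thresholds are not p-values; genome-wide error control beyond
  the $t_B$ threshold (and its null calibration) is out of scope.
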