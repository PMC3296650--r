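#' Majority vote over qualifying windows (chromosome level)
#'
#' Aggregates per-window forward responsibilities into a per-chromosome
#' vote: among windows with `bic > t_B` (optionally restricted to those
#' overlapping `region`), the aggregated forward responsibility is the
#' fraction of windows voting forward.  Chromosomes with no qualifying
#' window are uncallable (`NA`).
#'
#' @param scan an `inv_scan` from a haplotype-pathway
#'   [scan_inversions()].
#' @param t_B BIC threshold (strict).
#' @param region optional `c(start, end)` in bp; only windows whose
#'   `[left_mid, right_mid]` interval intersects it are counted.
#' @return A tibble with `id`, `r0I`, `n_windows_used`, `t_B`.
#' @export
vote <- function(scan, t_B = 0, region = NULL) {
  stopifnot(inherits(scan, "inv_scan"))
  if (!identical(attr(scan, "kind"), "haplotype")) {
    stop("vote() aggregates chromosome-level calls; use call_subjects() for genotype scans")
  }
  sel <- qualifying_windows(scan, t_B, region)
  inv <- attr(scan, "votes")
  ids <- attr(scan, "sample_ids")
  if (length(sel) == 0) {
    return(tibble::tibble(id = ids, r0I = NA_real_, n_windows_used = 0L,
                          t_B = t_B))
  }
  v <- inv[, sel, drop = FALSE]
  tibble::tibble(id = ids, r0I = rowMeans(!v),
                 n_windows_used = length(sel), t_B = t_B)
}

qualifying_windows <- function(scan, t_B, region = NULL) {
  sel <- scan$bic > t_B
  if (!is.null(region)) {
    sel <- sel & scan$left_mid <= region[2] & scan$right_mid >= region[1]
  }
  which(sel)
}

#' Call chromosome orientation from a vote
#'
#' A chromosome is called inverted when its aggregated forward
#' responsibility is strictly below 0.5; a tie at exactly 0.5 is
#' called forward.  Uncallable chromosomes get `NA`.
#'
#' @param v a tibble from [vote()].
#' @return `v` with a `status` column (`"forward"`/`"inverted"`).
#' @export
call_chromosomes <- function(v) {
  v$status <- ifelse(is.na(v$r0I), NA_character_,
                     ifelse(v$r0I < 0.5, "inverted", "forward"))
  v
}

#' Call subject inversion genotypes (genotype pathway)
#'
#' For each qualifying window (`bic > t_B`) the subject's
#' inverted-chromosome count (0, 1 or 2) comes from its two paired
#' chromosomes' responsibilities; window-level phasing makes
#' chromosome labels arbitrary across windows, so the vote aggregates
#' the label-invariant count.  The subject call is the majority count
#' over qualifying windows, ties resolved toward the smaller count;
#' subjects with no qualifying window are uncallable.
#'
#' @param scan an `inv_scan` from a genotype-pathway
#'   [scan_inversions()].
#' @param t_B BIC threshold (strict).
#' @param region optional `c(start, end)` bp restriction, as in
#'   [vote()].
#' @return A tibble with `id`, `count`, `status` (`"hom_ref"`,
#'   `"het_inv"`, `"hom_inv"` or `NA`), `n_windows_used`, `t_B`.
#' @export
call_subjects <- function(scan, t_B = 0, region = NULL) {
  stopifnot(inherits(scan, "inv_scan"))
  if (!identical(attr(scan, "kind"), "genotype")) {
    stop("call_subjects() requires a genotype-pathway scan")
  }
  sel <- qualifying_windows(scan, t_B, region)
  cnt <- attr(scan, "votes")
  ids <- attr(scan, "sample_ids")
  lab <- c("hom_ref", "het_inv", "hom_inv")
  if (length(sel) == 0) {
    return(tibble::tibble(id = ids, count = NA_integer_,
                          status = NA_character_, n_windows_used = 0L,
                          t_B = t_B))
  }
  cw <- cnt[, sel, drop = FALSE]
  n_used <- rowSums(!is.na(cw))
  count <- rep(NA_integer_, length(ids))
  count[n_used > 0] <- apply(cw[n_used > 0, , drop = FALSE], 1, majority_count)
  tibble::tibble(id = ids, count = count,
                 status = ifelse(is.na(count), NA_character_, lab[count + 1L]),
                 n_windows_used = as.integer(n_used), t_B = t_B)
}

#' Classification accuracy against known truth
#'
#' Fraction of callable individuals (or chromosomes) whose called
#' status matches the truth exactly; no-calls are excluded and
#' reported via the `n_no_call` attribute.
#'
#' @param calls tibble from [call_chromosomes()] or [call_subjects()]
#'   (any tibble with `id` and `status`).
#' @param truth a character vector aligned with `calls` rows, or a
#'   tibble with `id` and `status` to join on.
#' @return Accuracy in `[0, 1]`, with attributes `n_used` and
#'   `n_no_call`.
#' @export
classification_accuracy <- function(calls, truth) {
  if (is.data.frame(truth)) {
    truth <- truth$status[match(calls$id, truth$id)]
  }
  stopifnot(length(truth) == nrow(calls))
  ok <- !is.na(calls$status) & !is.na(truth)
  if (!any(ok)) stop("no callable individuals overlap the truth set")
  acc <- mean(calls$status[ok] == truth[ok])
  attr(acc, "n_used") <- sum(ok)
  attr(acc, "n_no_call") <- sum(is.na(calls$status))
  acc
}

#' Inversion frequency from chromosome-level calls
#'
#' Fraction of callable chromosomes called inverted (for genotype
#' calls, inverted-chromosome counts over twice the callable
#' subjects).
#'
#' @param calls tibble from [call_chromosomes()] or [call_subjects()].
#' @return Frequency in `[0, 1]`.
#' @export
inversion_frequency <- function(calls) {
  if ("count" %in% names(calls)) {
    ok <- !is.na(calls$count)
    if (!any(ok)) stop("no callable subjects")
    return(sum(calls$count[ok]) / (2 * sum(ok)))
  }
  ok <- !is.na(calls$status)
  if (!any(ok)) stop("no callable chromosomes")
  mean(calls$status[ok] == "inverted")
}

#' Classification accuracy across a grid of BIC thresholds
#'
#' Computes the classification accuracy against truth for each
#' threshold in `t_grid` (default: 0 plus deciles of the positive BIC
#' values), using the pathway-appropriate caller.
#'
#' @param scan an `inv_scan`.
#' @param truth truth labels: orientation per chromosome (haplotype
#'   pathway) or subject status (genotype pathway); vector aligned
#'   with samples or tibble with `id`, `status`.
#' @param t_grid numeric thresholds; default derived from the scan's
#'   positive BIC values.
#' @param region optional bp restriction passed to the caller.
#' @return An `inv_accuracy_profile` tibble with `t_B`, `accuracy`,
#'   `n_callable`.
#' @export
accuracy_profile <- function(scan, truth, t_grid = NULL, region = NULL) {
  stopifnot(inherits(scan, "inv_scan"))
  if (is.null(t_grid)) {
    pos <- scan$bic[scan$bic > 0]
    t_grid <- if (length(pos) == 0) 0 else
      unique(c(0, stats::quantile(pos, seq(0.1, 0.9, by = 0.1), names = FALSE)))
  }
  hap <- identical(attr(scan, "kind"), "haplotype")
  rows <- lapply(t_grid, function(tb) {
    calls <- if (hap) call_chromosomes(vote(scan, tb, region))
             else call_subjects(scan, tb, region)
    if (all(is.na(calls$status))) {
      return(tibble::tibble(t_B = tb, accuracy = NA_real_, n_callable = 0L))
    }
    acc <- classification_accuracy(calls, truth)
    tibble::tibble(t_B = tb, accuracy = as.numeric(acc),
                   n_callable = attr(acc, "n_used"))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("inv_accuracy_profile", class(out)))
  out
}
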