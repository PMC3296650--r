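#' Fit the no-inversion null model
#'
#' Under the null (no inversion in the population), the four block
#' variables factor as the product of the two within-breakpoint pairs:
#' the probability of an observation is the empirical joint frequency
#' of its (B1,B2) pair times that of its (B3,B4) pair.
#'
#' @param q a `block_quartet` from [encode_blocks()].
#' @return An `inv_null_fit`: list with joint frequency tables `n12`,
#'   `n34`, the total log-likelihood `loglik0`, and the free-parameter
#'   count `k0` (occupied cells minus one, per table).
#' @export
fit_null <- function(q) {
  stopifnot(inherits(q, "block_quartet"))
  K <- n_categories(q)
  b <- q$codes
  n12 <- table(factor(b[, 1], levels = 0:(K[1] - 1)),
               factor(b[, 2], levels = 0:(K[2] - 1))) / q$m
  n34 <- table(factor(b[, 3], levels = 0:(K[3] - 1)),
               factor(b[, 4], levels = 0:(K[4] - 1))) / q$m
  n12 <- unclass(n12); n34 <- unclass(n34)
  loglik0 <- sum(log(n12[cbind(b[, 1] + 1L, b[, 2] + 1L)])) +
    sum(log(n34[cbind(b[, 3] + 1L, b[, 4] + 1L)]))
  k0 <- (sum(n12 > 0) - 1L) + (sum(n34 > 0) - 1L)
  structure(list(n12 = n12, n34 = n34, loglik0 = loglik0, k0 = k0, m = q$m),
            class = "inv_null_fit")
}

#' Fit the forward/inverted mixture model by EM
#'
#' The alternative model is a two-component mixture: with probability
#' `1 - pi` an observation comes from the forward subpopulation, whose
#' block pairs (B1,B2) and (B3,B4) have free joint distributions `f12`
#' and `f34`; with probability `pi` it comes from the inverted
#' subpopulation, whose cross pairs (B1,B3) and (B2,B4) have joints
#' `r13` and `r24`.  All four tables are initialized at the pooled
#' empirical joint distributions and `pi` at `pi0`; the EM E-step uses
#' the standard mixture-weighted posteriors.  Unseen table cells are
#' floored at `floor_p` (then renormalized) so log-likelihoods stay
#' finite and EM cannot lock a category out of a component.
#'
#' @param q a `block_quartet`.
#' @param init optional [fit_null()] result for the same quartet (the
#'   empirical initialization is recomputed internally either way;
#'   passing it merely avoids recomputation of `loglik0` by callers).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @param pi0 initial mixture frequency.
#' @param floor_p probability floor for table cells.
#' @return An `inv_mixture_fit`: list with `pi`, tables `f12`, `f34`,
#'   `r13`, `r24`, `loglik1`, the per-iteration log-likelihood `trace`,
#'   `resp_fwd` (classification responsibilities, the unweighted ratio
#'   `P_fwd / (P_fwd + P_inv)`), `resp_post_fwd` (mixture-weighted EM
#'   posteriors), `n_iter` and `converged`.
#' @export
fit_mixture <- function(q, init = NULL, tol = 1e-6, max_iter = 1000,
                        pi0 = 0.5, floor_p = 1e-12) {
  stopifnot(inherits(q, "block_quartet"))
  stopifnot(tol > 0, max_iter >= 1)
  K <- n_categories(q)
  fit <- mixture_em_cpp(q$codes[, 1], q$codes[, 2], q$codes[, 3], q$codes[, 4],
                        K[1], K[2], K[3], K[4], pi0, tol, max_iter, floor_p)
  fit$loglik1 <- fit$loglik
  fit$loglik <- NULL
  class(fit) <- "inv_mixture_fit"
  fit
}

#' Evaluate the mixture log-likelihood at fixed parameters
#'
#' @param q a `block_quartet`.
#' @param pi mixture (inversion) frequency.
#' @param f12,f34,r13,r24 component joint tables, dimensioned to the
#'   quartet's category counts.
#' @return The log-likelihood of `q` under the mixture at the given
#'   parameters.
#' @export
mixture_loglik <- function(q, pi, f12, f34, r13, r24) {
  stopifnot(inherits(q, "block_quartet"))
  mixture_loglik_cpp(q$codes[, 1], q$codes[, 2], q$codes[, 3], q$codes[, 4],
                     pi, as.matrix(f12), as.matrix(f34),
                     as.matrix(r13), as.matrix(r24))
}

#' Forward responsibilities under a fitted mixture
#'
#' The responsibility of observation i to the forward model is the
#' unweighted relative density `P_fwd(x_i) / (P_fwd(x_i) + P_inv(x_i))`;
#' the responsibility to the inversion model is its complement.  When
#' both densities vanish (possible only below the table floor) the
#' responsibility is 0.5 and the observation is counted in the
#' `degenerate` attribute.
#'
#' @param fit an `inv_mixture_fit`.
#' @param q a `block_quartet` whose categories are covered by the fit's
#'   tables.
#' @return Numeric vector of forward responsibilities `r0` in `[0,1]`,
#'   with attribute `degenerate` counting zero-density observations.
#' @export
responsibilities <- function(fit, q) {
  stopifnot(inherits(fit, "inv_mixture_fit"), inherits(q, "block_quartet"))
  K <- n_categories(q)
  if (nrow(fit$f12) < K[1] || ncol(fit$f12) < K[2] ||
      nrow(fit$r13) < K[1] || ncol(fit$r13) < K[3] ||
      ncol(fit$f34) < K[4] || ncol(fit$r24) < K[4]) {
    stop("fitted tables do not cover the quartet's categories")
  }
  b <- q$codes + 1L
  pf <- fit$f12[cbind(b[, 1], b[, 2])] * fit$f34[cbind(b[, 3], b[, 4])]
  pinv <- fit$r13[cbind(b[, 1], b[, 3])] * fit$r24[cbind(b[, 2], b[, 4])]
  den <- pf + pinv
  bad <- den < 1e-300
  r0 <- ifelse(bad, 0.5, pf / den)
  if (any(bad)) {
    warning(sum(bad), " observation(s) had zero density under both components")
  }
  attr(r0, "degenerate") <- sum(bad)
  r0
}

#' BIC comparison of the mixture against the null
#'
#' Computes the Bayesian Information Criterion difference favouring the
#' inversion (mixture) model, `bic = 2 * (loglik1 - loglik0) -
#' delta_k * ln(m)`, where `delta_k` is the extra parameter count of
#' the mixture: one for `pi` plus the occupied-cell counts (minus one
#' each) of the two inverted-subpopulation tables, supports being the
#' distinct observed (B1,B3) and (B2,B4) category pairs.  Positive
#' values favour the inversion model.
#'
#' @param null an `inv_null_fit`.
#' @param alt an `inv_mixture_fit` from the same quartet.
#' @param q the `block_quartet` both were fitted on.
#' @return An `inv_model_score`: list with `bic`, `delta_k` and `m`.
#' @export
score_models <- function(null, alt, q) {
  stopifnot(inherits(null, "inv_null_fit"), inherits(alt, "inv_mixture_fit"),
            inherits(q, "block_quartet"))
  m <- q$m
  if (m < 2) stop("BIC comparison requires at least 2 observations")
  b <- q$codes
  s13 <- nrow(unique(b[, c(1, 3), drop = FALSE]))
  s24 <- nrow(unique(b[, c(2, 4), drop = FALSE]))
  delta_k <- 1L + (s13 - 1L) + (s24 - 1L)
  bic <- 2 * (alt$loglik1 - null$loglik0) - delta_k * log(m)
  structure(list(bic = bic, delta_k = delta_k, m = m),
            class = "inv_model_score")
}

#' @export
print.inv_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<inv_mixture_fit> pi = %.4f, loglik = %.4f, %d iteration(s)%s\n",
    x$pi, x$loglik1, x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted inversion mixture
#'
#' One row per occupied table cell, long format.
#'
#' @param x an `inv_mixture_fit`.
#' @param ... unused.
#' @return A tibble with columns `table` (f12/f34/r13/r24), `row`,
#'   `col` (0-based category codes) and `probability`.
#' @export
tidy.inv_mixture_fit <- function(x, ...) {
  one <- function(tab, name) {
    idx <- which(tab > 1e-9, arr.ind = TRUE)
    tibble::tibble(table = name, row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                   probability = tab[idx])
  }
  dplyr::bind_rows(one(x$f12, "f12"), one(x$f34, "f34"),
                   one(x$r13, "r13"), one(x$r24, "r24"))
}

#' Glance at a fitted inversion mixture
#'
#' @param x an `inv_mixture_fit`.
#' @param ... unused.
#' @return A one-row tibble with `pi`, `loglik`, `n_iter`, `converged`.
#' @export
glance.inv_mixture_fit <- function(x, ...) {
  tibble::tibble(pi = x$pi, loglik = x$loglik1, n_iter = x$n_iter,
                 converged = x$converged)
}
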