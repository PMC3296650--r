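test_that("null fit reproduces enumerated empirical log-likelihoods", {
  # two categories per pair, two observations of each combination
  s <- cbind(c("0", "0", "1", "1"), c("0", "0", "1", "1"),
             c("1", "1", "0", "0"), c("1", "1", "0", "0"))
  q <- encode_blocks(s)
  n <- fit_null(q)
  expect_equal(n$loglik0, 8 * log(0.5), tolerance = 1e-12)
  expect_equal(sum(n$n12), 1, tolerance = 1e-9)
  expect_equal(sum(n$n34), 1, tolerance = 1e-9)

  # all observations identical: probability-1 categories
  q1 <- encode_blocks(matrix(rep(c("01", "10", "00", "11"), each = 5), 5, 4))
  expect_equal(fit_null(q1)$loglik0, 0)

  # random m = 6 quartet against direct enumeration
  set.seed(3)
  q6 <- rand_tiny_quartet(6)
  n6 <- fit_null(q6)
  b <- q6$codes
  p12 <- table(paste(b[, 1], b[, 2])) / 6
  p34 <- table(paste(b[, 3], b[, 4])) / 6
  expected <- sum(log(p12[paste(b[, 1], b[, 2])])) +
    sum(log(p34[paste(b[, 3], b[, 4])]))
  expect_equal(n6$loglik0, unname(expected), tolerance = 1e-10)
  expect_equal(n6$k0, (length(p12) - 1) + (length(p34) - 1))
})

test_that("EM collapses the mixture on forward-factorized data", {
  set.seed(21)
  m <- 2000
  # dependent within-breakpoint pairs, independence across breakpoints
  c12 <- sample(1:3, m, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  c34 <- sample(1:3, m, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  pair <- rbind(c("0", "0"), c("1", "1"), c("0", "1"))
  s <- cbind(pair[c12, 1], pair[c12, 2], pair[c34, 1], pair[c34, 2])
  q <- encode_blocks(s)
  nf <- fit_null(q)
  fit <- fit_mixture(q, nf)
  expect_lt(fit$pi, 0.05)
  expect_gte(fit$loglik1, nf$loglik0 - 1e-9)
  expect_lt(fit$loglik1 - nf$loglik0, 0.02 * abs(nf$loglik0))
  expect_lt(score_models(nf, fit, q)$bic, 0)
})

test_that("EM log-likelihood trace is monotone non-decreasing", {
  set.seed(7)
  for (r in 1:20) {
    q <- rand_tiny_quartet(sample(c(6, 20, 50), 1))
    fit <- fit_mixture(q)
    expect_true(all(diff(fit$trace) >= -1e-8))
    expect_gte(fit$loglik1, fit_null(q)$loglik0 - 1e-9)
  }
})

test_that("degenerate one-category quartets collapse to the null", {
  q <- encode_blocks(matrix(rep(c("00", "01", "10", "11"), each = 4), 4, 4))
  nf <- fit_null(q)
  fit <- fit_mixture(q, nf)
  expect_true(fit$converged)
  expect_equal(fit$loglik1, nf$loglik0, tolerance = 1e-9)
})

test_that("the mixture likelihood is symmetric under component relabelling", {
  set.seed(14)
  q <- rand_tiny_quartet(8)
  K <- vapply(q$category_maps, length, integer(1))
  rnd <- function(a, b) { x <- matrix(stats::rexp(a * b), a, b); x / sum(x) }
  f12 <- rnd(K[1], K[2]); f34 <- rnd(K[3], K[4])
  r13 <- rnd(K[1], K[3]); r24 <- rnd(K[2], K[4])
  pi <- 0.3
  ll <- mixture_loglik(q, pi, f12, f34, r13, r24)
  expect_equal(ll, r_mixture_loglik(q, pi, f12, f34, r13, r24),
               tolerance = 1e-9)
  # exchanging component roles with pi <-> 1 - pi leaves the value fixed
  b <- q$codes + 1L
  pf <- f12[cbind(b[, 1], b[, 2])] * f34[cbind(b[, 3], b[, 4])]
  pv <- r13[cbind(b[, 1], b[, 3])] * r24[cbind(b[, 2], b[, 4])]
  ll_swapped <- sum(log((1 - (1 - pi)) * pv + (1 - pi) * pf))
  expect_equal(ll, ll_swapped, tolerance = 1e-9)
})

test_that("responsibilities follow the unweighted forward/inverted ratio", {
  q <- encode_blocks(cbind(c("0", "0", "1"), c("0", "1", "1"),
                           c("0", "1", "0"), c("0", "0", "1")))
  f12 <- matrix(c(0.5, 0.2, 0.1, 0.2), 2, 2)
  f34 <- matrix(c(0.3, 0.2, 0.3, 0.2), 2, 2)
  r13 <- matrix(c(0.4, 0.3, 0.1, 0.2), 2, 2)
  r24 <- matrix(c(0.1, 0.3, 0.4, 0.2), 2, 2)
  fit <- structure(list(pi = 0.4, f12 = f12, f34 = f34, r13 = r13, r24 = r24),
                   class = "inv_mixture_fit")
  r0 <- responsibilities(fit, q)
  b <- q$codes + 1L
  pf <- f12[cbind(b[, 1], b[, 2])] * f34[cbind(b[, 3], b[, 4])]
  pv <- r13[cbind(b[, 1], b[, 3])] * r24[cbind(b[, 2], b[, 4])]
  expect_equal(as.numeric(r0), pf / (pf + pv), tolerance = 1e-12)
  expect_true(all(r0 >= 0 & r0 <= 1))

  # equal densities give 0.5; a zero inverted density gives ~1
  fit2 <- structure(list(pi = 0.5,
                         f12 = matrix(0.25, 2, 2), f34 = matrix(0.25, 2, 2),
                         r13 = matrix(0.25, 2, 2), r24 = matrix(0.25, 2, 2)),
                    class = "inv_mixture_fit")
  expect_equal(as.numeric(responsibilities(fit2, q)), rep(0.5, 3))
  r13z <- matrix(c(1e-12, 1e-12, 1e-12, 1 - 3e-12), 2, 2)
  fit3 <- structure(list(pi = 0.5, f12 = f12, f34 = f34, r13 = r13z,
                         r24 = r24), class = "inv_mixture_fit")
  expect_gt(responsibilities(fit3, q)[1], 0.999)
})

test_that("BIC scoring applies the penalized likelihood difference", {
  # quartet with exactly 2 observed (B1,B3) and 2 observed (B2,B4) pairs
  q <- encode_blocks(matrix(rep(c("0", "1"), each = 4), 8, 4))
  expect_equal(nrow(unique(q$codes[, c(1, 3)])), 2)
  nf <- list(loglik0 = -5)
  class(nf) <- "inv_null_fit"
  alt <- list(loglik1 = 0)
  class(alt) <- "inv_mixture_fit"
  sc <- score_models(nf, alt, q)
  expect_equal(sc$delta_k, 3L)
  expect_equal(sc$bic, 2 * 5 - 3 * log(8), tolerance = 1e-12)

  # collapsed mixture: bic = -delta_k * ln(m) < 0
  alt0 <- list(loglik1 = -5)
  class(alt0) <- "inv_mixture_fit"
  expect_equal(score_models(nf, alt0, q)$bic, -3 * log(8), tolerance = 1e-12)

  q1 <- encode_blocks(matrix(c("0", "1", "0", "1"), 1, 4))
  expect_error(score_models(nf, alt, q1), "at least 2")
})

test_that("a genuine mixture is favoured by BIC at population scale", {
  set.seed(31)
  hits <- 0
  for (r in 1:20) {
    d <- rquartet_disjoint(2000, 0.4)
    nf <- fit_null(d$q)
    fit <- fit_mixture(d$q, nf)
    if (score_models(nf, fit, d$q)$bic > 0) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("pi is recovered from disjoint-support mixtures", {
  set.seed(8)
  for (pi in c(0.3, 0.7)) {
    errs <- vapply(1:3, function(r) {
      d <- rquartet_disjoint(2000, pi)
      abs(fit_mixture(d$q)$pi - pi)
    }, numeric(1))
    expect_lte(stats::median(errs), 0.05)
  }
})

test_that("the default start is never beaten by alternative starts at scale", {
  set.seed(77)
  d <- rquartet_disjoint(2000, 0.35)
  base <- fit_mixture(d$q)
  best <- max(vapply(c(0.1, 0.35, 0.6, 0.9), function(p0) {
    fit_mixture(d$q, pi0 = p0)$loglik1
  }, numeric(1)))
  expect_lte(best - base$loglik1, 1e-4)
})

test_that("tidy and glance summarize a fitted mixture", {
  set.seed(5)
  d <- rquartet_disjoint(400, 0.5)
  fit <- fit_mixture(d$q)
  td <- tidy(fit)
  expect_true(all(c("table", "row", "col", "probability") %in% names(td)))
  expect_true(all(td$probability > 0 & td$probability <= 1))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
})
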