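# Independent brute-force maximizer of the mixture likelihood for tiny
# quartets: grid over pi, multi-start EM on the tables with pi held
# fixed.  Deliberately written in plain R with its own likelihood
# arithmetic, independent of the package's EM path.
oracle_loglik1 <- function(q, pi_grid = seq(0, 1, by = 0.025), n_starts = 4,
                           iters = 120, tol = 1e-9) {
  b <- q$codes
  K <- vapply(q$category_maps, length, integer(1))
  m <- q$m
  j12 <- b[, 1] * K[2] + b[, 2] + 1L; j34 <- b[, 3] * K[4] + b[, 4] + 1L
  j13 <- b[, 1] * K[3] + b[, 3] + 1L; j24 <- b[, 2] * K[4] + b[, 4] + 1L
  n12 <- K[1] * K[2]; n34 <- K[3] * K[4]; n13 <- K[1] * K[3]; n24 <- K[2] * K[4]
  fl <- function(p) { p <- pmax(p, 1e-12); p / sum(p) }
  acc <- function(j, w, n) {
    v <- numeric(n)
    for (i in seq_along(j)) v[j[i]] <- v[j[i]] + w[i]
    v
  }
  best <- -Inf
  for (pi in pi_grid) {
    for (s in seq_len(n_starts + 1)) {
      if (s == 1) { # empirical start
        f12 <- fl(acc(j12, rep(1, m), n12)); f34 <- fl(acc(j34, rep(1, m), n34))
        r13 <- fl(acc(j13, rep(1, m), n13)); r24 <- fl(acc(j24, rep(1, m), n24))
      } else {
        f12 <- fl(stats::rexp(n12)); f34 <- fl(stats::rexp(n34))
        r13 <- fl(stats::rexp(n13)); r24 <- fl(stats::rexp(n24))
      }
      ll_prev <- -Inf
      for (it in seq_len(iters)) {
        pf <- f12[j12] * f34[j34]
        pv <- r13[j13] * r24[j24]
        mix <- (1 - pi) * pf + pi * pv
        ll <- sum(log(mix))
        if (it > 1 && ll - ll_prev < tol) break
        ll_prev <- ll
        w <- pi * pv / mix
        f12 <- fl(acc(j12, 1 - w, n12)); f34 <- fl(acc(j34, 1 - w, n34))
        r13 <- fl(acc(j13, w, n13)); r24 <- fl(acc(j24, w, n24))
      }
      pf <- f12[j12] * f34[j34]; pv <- r13[j13] * r24[j24]
      ll <- sum(log((1 - pi) * pf + pi * pv))
      if (ll > best) best <- ll
    }
  }
  best
}

# plain-R evaluation of the mixture log-likelihood (reference for the
# package's evaluator and for symmetry checks)
r_mixture_loglik <- function(q, pi, f12, f34, r13, r24) {
  b <- q$codes + 1L
  pf <- f12[cbind(b[, 1], b[, 2])] * f34[cbind(b[, 3], b[, 4])]
  pv <- r13[cbind(b[, 1], b[, 3])] * r24[cbind(b[, 2], b[, 4])]
  sum(log((1 - pi) * pf + pi * pv))
}

rand_tiny_quartet <- function(m = sample(2:8, 1)) {
  encode_blocks(matrix(sample(c("0", "1"), m * 4, replace = TRUE), m, 4))
}

# Sample a quartet from the two-component mixture with disjoint
# category supports.  Forward observations draw strings from
# {"00","01"} with the within-breakpoint pairs coupled (B1 = B2,
# B3 = B4); inverted ones draw from {"10","11"} with the
# cross-breakpoint pairs coupled (B1 = B3, B2 = B4).  The coupling
# makes the component labels identifiable, so pi itself (not just the
# partition) is recoverable.
rquartet_disjoint <- function(m, pi) {
  z <- stats::runif(m) < pi
  s <- matrix("", m, 4)
  nf <- sum(!z); ni <- sum(z)
  if (nf > 0) {
    x <- sample(c("00", "01"), nf, replace = TRUE)
    y <- sample(c("00", "01"), nf, replace = TRUE)
    s[!z, 1] <- x; s[!z, 2] <- x
    s[!z, 3] <- y; s[!z, 4] <- y
  }
  if (ni > 0) {
    x <- sample(c("10", "11"), ni, replace = TRUE)
    y <- sample(c("10", "11"), ni, replace = TRUE)
    s[z, 1] <- x; s[z, 3] <- x
    s[z, 2] <- y; s[z, 4] <- y
  }
  list(q = encode_blocks(s), z = z)
}
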