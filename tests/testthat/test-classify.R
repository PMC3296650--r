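test_that("the chromosome vote counts forward calls over qualifying windows", {
  # one chromosome, three windows with r0 = 0.9, 0.2, 0.3
  votes <- matrix(c(FALSE, TRUE, TRUE), 1, 3) # inverted iff r0 < 0.5
  sc <- fake_scan(left_mid = c(1e5, 1.2e5, 1.4e5),
                  right_mid = c(5e5, 5.2e5, 5.4e5),
                  bic = c(100, 300, 250), votes = votes)
  v200 <- vote(sc, t_B = 200)
  expect_equal(v200$r0I, 0)
  expect_equal(v200$n_windows_used, 2L)
  expect_equal(call_chromosomes(v200)$status, "inverted")
  v50 <- vote(sc, t_B = 50)
  expect_equal(v50$r0I, 1 / 3, tolerance = 1e-12)
  expect_equal(call_chromosomes(v50)$status, "inverted")
  # unanimity in the forward direction
  fwd <- fake_scan(left_mid = c(1e5, 1.2e5), right_mid = c(5e5, 5.2e5),
                   bic = c(100, 100), votes = matrix(FALSE, 1, 2))
  expect_equal(vote(fwd, 0)$r0I, 1)
  expect_equal(call_chromosomes(vote(fwd, 0))$status, "forward")
})

test_that("chromosome calls use a strict 0.5 threshold", {
  v <- tibble::tibble(id = c("a", "b", "c", "d"),
                      r0I = c(0.49, 0.5, 1, NA),
                      n_windows_used = c(3L, 3L, 3L, 0L), t_B = 0)
  out <- call_chromosomes(v)
  expect_equal(out$status, c("inverted", "forward", "forward", NA))
})

test_that("no qualifying window yields explicit no-calls", {
  sc <- fake_scan(left_mid = 1e5, right_mid = 5e5, bic = -10,
                  votes = matrix(TRUE, 2, 1))
  v <- vote(sc, t_B = 0)
  expect_true(all(is.na(v$r0I)))
  expect_equal(v$n_windows_used, c(0L, 0L))
  expect_true(all(is.na(call_chromosomes(v)$status)))
})

test_that("subject calls take the majority inverted-chromosome count", {
  counts <- rbind(c(2L, 2L, 2L),   # unanimously hom_inv
                  c(1L, 1L, 0L),   # majority het
                  c(0L, 1L, NA),   # tie 0/1 -> conservative 0
                  c(NA, NA, NA))   # never usable
  sc <- fake_scan(left_mid = c(1e5, 1.2e5, 1.4e5),
                  right_mid = c(5e5, 5.2e5, 5.4e5),
                  bic = c(10, 20, 30), votes = counts, kind = "genotype")
  calls <- call_subjects(sc, t_B = 0)
  expect_equal(calls$status, c("hom_inv", "het_inv", "hom_ref", NA))
  expect_equal(calls$count, c(2L, 1L, 0L, NA))
  expect_equal(calls$n_windows_used, c(3L, 3L, 2L, 0L))
})

test_that("votes ignore duplicated sub-threshold windows", {
  votes <- matrix(c(TRUE, FALSE), 1, 2)
  sc <- fake_scan(left_mid = c(1e5, 1.2e5), right_mid = c(5e5, 5.2e5),
                  bic = c(100, 5), votes = votes)
  base <- vote(sc, t_B = 50)
  dup <- fake_scan(left_mid = c(1e5, 1.2e5, 1.2e5, 1.2e5),
                   right_mid = c(5e5, 5.2e5, 5.2e5, 5.2e5),
                   bic = c(100, 5, 5, 5),
                   votes = votes[, c(1, 2, 2, 2), drop = FALSE])
  expect_equal(vote(dup, t_B = 50)$r0I, base$r0I)
})

test_that("classification accuracy counts exact status matches", {
  calls <- tibble::tibble(id = paste0("s", 1:10),
                          status = c(rep("forward", 7), rep("inverted", 3)))
  truth <- c(rep("forward", 7), "forward", "forward", "forward")
  acc <- classification_accuracy(calls, truth)
  expect_equal(as.numeric(acc), 0.7)
  expect_equal(attr(acc, "n_used"), 10L)
  # perfect calls
  expect_equal(as.numeric(classification_accuracy(calls, calls$status)), 1)
  # truth as a joinable tibble, with a no-call excluded
  calls2 <- calls
  calls2$status[1] <- NA
  truth_tbl <- tibble::tibble(id = calls$id, status = calls$status)
  acc2 <- classification_accuracy(calls2, truth_tbl)
  expect_equal(attr(acc2, "n_used"), 9L)
  expect_equal(attr(acc2, "n_no_call"), 1L)
  # no overlap at all
  none <- tibble::tibble(id = "x", status = NA_character_)
  expect_error(classification_accuracy(none, tibble::tibble(id = "x",
                                                            status = NA)),
               "no callable")
})

test_that("inversion frequency is the inverted fraction of callable calls", {
  chrom <- tibble::tibble(id = paste0("c", 1:10),
                          status = c(rep("inverted", 4), rep("forward", 6)))
  expect_equal(inversion_frequency(chrom), 0.4)
  chrom$status <- "forward"
  expect_equal(inversion_frequency(chrom), 0)
  subj <- tibble::tibble(id = paste0("s", 1:4), count = c(2L, 1L, 0L, NA))
  expect_equal(inversion_frequency(subj), 3 / 6)
})

test_that("accuracy profiles evaluate the caller across thresholds", {
  counts <- rbind(c(0L, 0L), c(2L, 2L), c(1L, 0L))
  sc <- fake_scan(left_mid = c(1e5, 1.2e5), right_mid = c(5e5, 5.2e5),
                  bic = c(100, 40), votes = counts, kind = "genotype")
  truth <- tibble::tibble(id = paste0("subj", 1:3),
                          status = c("hom_ref", "hom_inv", "het_inv"))
  prof <- accuracy_profile(sc, truth, t_grid = c(0, 50))
  expect_s3_class(prof, "inv_accuracy_profile")
  expect_equal(prof$t_B, c(0, 50))
  # at t_B = 0 both windows vote: subject 3 ties 1/0 -> hom_ref (miss);
  # at t_B = 50 only the first window votes and all three calls are exact
  expect_equal(prof$accuracy, c(2 / 3, 1))
})
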