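test_that("channel order is the fixed 96-channel pyrimidine convention", {
  ch <- sbs_channels()
  expect_length(ch, 96)
  expect_equal(anyDuplicated(ch), 0)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[17], "A[C>G]A")
  expect_equal(ch[96], "T[T>G]T")
})

test_that("catalog building collapses purine-reference mutations by strand", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACGTACGTA"))
  # C>T at pos 3 context ACG; G>A at pos 8 context CGT -> revcomp ACG
  snvs <- variant_records("chr1", c(3, 8), c("C", "G"), c("T", "A"),
                          sample = "s1")
  cat_m <- build_catalog(snvs, ref)
  expect_equal(sum(cat_m), 2)
  expect_equal(unname(cat_m["A[C>T]G", "s1"]), 2)
})

test_that("catalog conserves counts and tallies skipped records", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACGTACGTA"))
  snvs <- variant_records("chr1", c(3, 1, 5), c("C", "A", "TA"),
                          c("T", "T", "T"), sample = "s1")
  cat_m <- build_catalog(snvs, ref)   # pos 1 has no 5' context; TA>T is an indel
  expect_equal(sum(cat_m), 1)
  sk <- attr(cat_m, "skipped")
  expect_equal(unname(sk["no_context"]), 1L)
  expect_equal(unname(sk["non_snv"]), 1L)
})

test_that("opportunity adjustment is identity under uniform weights and invertible", {
  sig <- simulate_signature_bank(3, seed = 41)
  expect_equal(adjust_for_opportunities(sig, rep(2, 96)), sig)
  opp <- runif(96, 0.2, 5)
  adj <- adjust_for_opportunities(sig, opp)
  expect_equal(rowSums(adj), rep(1, 3), ignore_attr = TRUE)
  back <- adjust_for_opportunities(adj, 1 / opp)
  expect_equal(back, sig, tolerance = 1e-10)
  # zero opportunity zeroes the channel; doubling changes nothing
  opp0 <- opp; opp0[5] <- 0
  expect_equal(adjust_for_opportunities(sig, opp0)[, 5], c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(adjust_for_opportunities(sig, 2 * opp), adj)
})

test_that("EM exposure fit recovers degenerate and orthogonal mixtures", {
  set.seed(42)
  sig <- simulate_signature_bank(2, seed = 42)
  pure <- simulate_signature_catalog(c(1, 0), sig, 5000, seed = 1)
  fit <- fit_exposures(pure, sig, n_boot = 50, seed = 2)
  expect_gt(fit$exposures[1, 1], 0.99)
  # disjoint-support signatures mixed 60/40
  orth <- matrix(0, 2, 96)
  orth[1, 1:48] <- 1 / 48
  orth[2, 49:96] <- 1 / 48
  cat2 <- simulate_signature_catalog(c(0.6, 0.4), orth, 10000, seed = 3)
  fit2 <- fit_exposures(cat2, orth, n_boot = 50, seed = 4)
  expect_lt(max(abs(fit2$exposures[, 1] - c(0.6, 0.4))), 0.02)
  expect_true(all(fit2$lower <= fit2$exposures & fit2$exposures <= fit2$upper))
})

test_that("EM log-likelihood is non-decreasing and hits the direct maximizer", {
  set.seed(43)
  for (i in 1:5) {
    sig <- simulate_signature_bank(2, seed = 50 + i)
    truth <- runif(1, 0.1, 0.9)
    cat_m <- simulate_signature_catalog(c(truth, 1 - truth), sig, 500)
    fit <- fit_exposures(cat_m, sig, n_boot = 10, seed = i)
    expect_true(all(diff(fit$loglik_trace[[1]]) >= -1e-9))
    # independent 1-D maximizer over the K=2 simplex
    counts <- as.vector(unclass(cat_m))
    nll <- function(e1) {
      p <- e1 * sig[1, ] + (1 - e1) * sig[2, ]
      -sum(counts * log(pmax(p, 1e-300)))
    }
    opt <- stats::optimize(nll, c(0, 1))$minimum
    expect_lt(abs(fit$exposures[1, 1] - opt), 1e-4)
  }
})

test_that("select-and-refit drops zero signatures and renormalizes", {
  set.seed(44)
  sig <- simulate_signature_bank(4, seed = 60)
  # signature 4 has true exposure 0 in both samples
  ex <- rbind(c(0.5, 0.3, 0.2, 0), c(0.1, 0.6, 0.3, 0))
  cat_m <- simulate_signature_catalog(ex, sig, 20000, seed = 5)
  fit <- fit_exposures(cat_m, sig, n_boot = 100, seed = 6)
  sel <- select_and_refit(fit, cat_m, sig, n_boot = 100, seed = 7)
  expect_setequal(attr(sel, "selected"), c("SBSsim1", "SBSsim2", "SBSsim3"))
  expect_equal(colSums(sel$exposures), c(1, 1), ignore_attr = TRUE)
  expect_error(select_and_refit(fit, cat_m, sig, floor = 2), "no signature")
})

test_that("signature matrices are validated", {
  sig <- simulate_signature_bank(2, seed = 70)
  bad <- sig; bad[1, 1] <- bad[1, 1] + 0.01
  expect_error(fit_exposures(simulate_signature_catalog(c(1, 0), sig, 100, seed = 1),
                             bad), "sum to 1")
  zero <- simulate_signature_catalog(c(1, 0), sig, 0, seed = 1)
  expect_error(fit_exposures(zero, sig), ">= 1 mutation")
})
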