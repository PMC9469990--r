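test_that("Hudson FST matches closed-form hand computations", {
  expect_equal(hudson_fst(1, 50, 0, 50), 1.0)
  # p1=0.8, p2=0.2, n=10: num = 0.36 - 2*(0.16/9), den = 0.68
  num <- 0.36 - 2 * 0.16 / 9
  expect_equal(hudson_fst(0.8, 10, 0.2, 10), num / 0.68)
  expect_equal(hudson_fst(0.8, 10, 0.2, 10), 0.4771, tolerance = 1e-4)
  # equal frequencies: estimate <= 0 in finite samples
  expect_lte(hudson_fst(0.5, 100, 0.5, 100), 0)
  expect_true(abs(hudson_fst(0.5, 1e6, 0.5, 1e6)) < 1e-5)
  # monomorphic same allele -> undefined, excluded from aggregation
  expect_true(is.na(hudson_fst(0, 10, 0, 10)))
  agg <- hudson_fst(c(1, 0), c(50, 50), c(0, 0), c(50, 50), aggregate = TRUE)
  expect_equal(agg, 1.0)   # the undefined site drops out
  expect_error(hudson_fst(0.5, 1, 0.5, 10), "sample sizes")
})

test_that("FST is monotone in frequency difference at fixed sample size", {
  d <- seq(0, 0.4, by = 0.05)
  vals <- hudson_fst(0.5 + d, 50, 0.5 - d, 50)
  expect_true(all(diff(vals) > 0))
})

test_that("marker selection drops high-missingness SNPs and finds informative ones", {
  set.seed(51)
  n_per <- 15
  # SNP1 fixed-different in breed A; SNP2 uninformative; SNP3 12% missing
  geno <- cbind(
    c(rep(2, n_per), rep(0, 2 * n_per)),
    rbinom(3 * n_per, 2, 0.5),
    rbinom(3 * n_per, 2, 0.5))
  geno[sample.int(3 * n_per, ceiling(0.12 * 3 * n_per)), 3] <- NA
  gm <- genotype_matrix(geno, chrom = rep("chr1", 3), pos = c(1, 2, 3) * 1e5,
                        labels = rep(c("A", "B", "C"), each = n_per))
  sel <- select_markers(gm)
  expect_true(1 %in% sel)
  expect_false(3 %in% sel)
  expect_error(select_markers(genotype_matrix(geno, rep("chr1", 3),
                                              1:3, rep("A", 3 * n_per))),
               ">= 2 labeled breeds")
  # oracle recount: selection equals direct recomputation
  freq <- function(rows) colMeans(geno[rows, , drop = FALSE], na.rm = TRUE) / 2
  labs <- rep(c("A", "B", "C"), each = n_per)
  any_hit <- rep(FALSE, 3)
  for (b in c("A", "B", "C")) {
    p1 <- freq(labs == b); p2 <- freq(labs != b)
    n1 <- 2 * colSums(!is.na(geno[labs == b, , drop = FALSE]))
    n2 <- 2 * colSums(!is.na(geno[labs != b, , drop = FALSE]))
    f <- hudson_fst(p1, pmax(n1, 2), p2, pmax(n2, 2))
    any_hit <- any_hit | (!is.na(f) & f > 0.15)
  }
  miss_ok <- colMeans(is.na(geno)) < 0.10
  expect_equal(sel, sort(which(any_hit & miss_ok)))
})

test_that("LD pruning removes within-window correlated pairs deterministically", {
  set.seed(52)
  base <- rbinom(40, 2, 0.5)
  geno <- cbind(base, base, rbinom(40, 2, 0.5))   # SNP2 duplicates SNP1
  gm <- genotype_matrix(geno, chrom = rep("chr1", 3),
                        pos = c(1000, 2000, 3000))
  kept <- ld_prune(gm)
  expect_equal(kept, c(1, 3))   # tie on missingness removes the higher index
  # r^2 below threshold: both kept
  a <- rbinom(200, 2, 0.5)
  noise <- rbinom(200, 2, 0.5)
  b <- ifelse(runif(200) < 0.5, a, noise)
  r2 <- cor(a, b)^2
  gm2 <- genotype_matrix(cbind(a, b), rep("chr1", 2), c(100, 200))
  kept2 <- ld_prune(gm2)
  if (r2 <= 0.5) expect_equal(kept2, c(1, 2)) else expect_equal(kept2, 1)
  # outside the window nothing is pruned even at r^2 = 1
  gm3 <- genotype_matrix(cbind(base, base), rep("chr1", 2), c(0, 60000))
  expect_equal(ld_prune(gm3), c(1, 2))
})

test_that("pruned sets never retain a violating pair (exhaustive post-check)", {
  set.seed(53)
  for (trial in 1:5) {
    n_snp <- 30
    base <- matrix(rbinom(50 * n_snp, 2, 0.5), 50, n_snp)
    # induce blocks of correlation
    for (j in seq(2, n_snp, by = 3)) base[, j] <- base[, j - 1]
    gm <- genotype_matrix(base, rep("chr1", n_snp),
                          pos = sort(sample.int(2e5, n_snp)))
    kept <- ld_prune(gm)
    for (a in seq_along(kept)) for (b in seq_along(kept)) {
      if (b <= a) next
      i <- kept[a]; j <- kept[b]
      if (abs(gm$pos[j] - gm$pos[i]) >= 50000) next
      r <- suppressWarnings(cor(base[, i], base[, j]))
      if (!is.na(r)) expect_lte(r^2, 0.5)
    }
  }
})

test_that("supervised ancestry recovers purebred and admixed truth", {
  set.seed(54)
  f <- simulate_breed_freqs(3, 5000, drift = 0.15)
  panel <- structure(list(freqs = f, counts = rep(15L, 3)),
                     class = "allele_frequency_panel")
  pure <- simulate_admixed_genotypes(f, c(0, 1, 0), seed = 1)
  a1 <- supervised_ancestry(pure, panel)
  expect_gte(a1$q[1, 2], 0.95)
  adm <- simulate_admixed_genotypes(f, c(0.7, 0.3, 0), seed = 2)
  a2 <- supervised_ancestry(adm, panel)
  expect_lt(max(abs(a2$q[1, ] - c(0.7, 0.3, 0))), 0.03)
  expect_true(all(vapply(a2$trace, function(t) all(diff(t) >= -1e-8), TRUE)))
  expect_equal(unname(rowSums(a2$q)), 1)
  all_na <- genotype_matrix(matrix(NA_real_, 1, ncol(f)),
                            rep("chr1", ncol(f)), seq_len(ncol(f)) * 100)
  expect_error(supervised_ancestry(all_na, panel), "all genotypes missing")
})

test_that("EM matches a fine grid search on two-breed toys", {
  set.seed(55)
  for (i in 1:3) {
    f <- simulate_breed_freqs(2, 400, drift = 0.2)
    q_true <- runif(1, 0.2, 0.8)
    g <- simulate_admixed_genotypes(f, c(q_true, 1 - q_true))
    panel <- structure(list(freqs = f, counts = c(15L, 15L)),
                       class = "allele_frequency_panel")
    fit <- supervised_ancestry(g, panel)
    grid <- seq(0, 1, by = 0.001)
    ll <- vapply(grid, function(q1) {
      p <- q1 * f[1, ] + (1 - q1) * f[2, ]
      sum(g$geno[1, ] * log(p) + (2 - g$geno[1, ]) * log(1 - p), na.rm = TRUE)
    }, numeric(1))
    expect_lt(abs(fit$q[1, 1] - grid[which.max(ll)]), 1e-3 + 5e-4)
  }
})

test_that("consensus breed calls dominant fractions and flags village-dog spread", {
  q <- rbind(a = c(0.9, 0.05, 0.05), b = c(0.4, 0.35, 0.25),
             c = c(0.5, 0.3, 0.2))
  colnames(q) <- c("A", "B", "C")
  calls <- consensus_breed(q)
  expect_equal(calls$call, c("A", "mixed/village", "A"))  # 0.5 inclusive
  spread <- matrix(1 / 20, 1, 20, dimnames = list("v", paste0("b", 1:20)))
  expect_equal(consensus_breed(spread)$call, "mixed/village")
})

test_that("frequency panel enforces the minimum breed size", {
  set.seed(56)
  f <- simulate_breed_freqs(2, 50)
  g <- simulate_admixed_genotypes(f, diag(2)[rep(1:2, c(12, 5)), ])
  g$labels <- rep(c("A", "B"), c(12, 5))
  panel <- allele_frequency_panel(g)
  expect_equal(rownames(panel$freqs), "A")   # breed B is below 12 samples
  expect_error(allele_frequency_panel(
    genotype_matrix(g$geno, g$chrom, g$pos, rep(NA_character_, 17))),
    "minimum panel size")
})
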