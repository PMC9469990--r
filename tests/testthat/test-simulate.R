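test_that("the generator is deterministic: same config + seed, same bundle", {
  c1 <- simulate_cohort(cohort_config(), seed = 17)
  c2 <- simulate_cohort(cohort_config(), seed = 17)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$tumors$tumor1$mutect2, c2$tumors$tumor1$mutect2)
  expect_identical(c1$sv$truth, c2$sv$truth)
  expect_identical(c1$ancestry$freqs, c2$ancestry$freqs)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("truth bookkeeping matches the configured class counts", {
  cfg <- cohort_config()
  co <- simulate_cohort(cfg, seed = 23)
  expect_equal(nrow(co$truth), cfg$n_tumors * sum(cfg$snv_counts))
  tab <- table(co$truth$class[co$truth$sample == "tumor1"])
  expect_equal(as.integer(tab[names(cfg$snv_counts)]),
               unname(cfg$snv_counts))
  expect_equal(sum(co$truth$eligible),
               cfg$n_tumors * sum(cfg$snv_counts[c("somatic_eligible",
                                                   "somatic_rescued_mutect2",
                                                   "somatic_rescued_platypus")]))
  # PON bookkeeping: distinct planted germline-PON sites
  pon <- build_site_pon(co$normals)
  planted <- unique(site_key(co$truth[co$truth$class == "germline_pon", ]))
  expect_true(all(planted %in% site_key(pon$records)))
})

test_that("every emitted file parses through the package readers", {
  co <- simulate_cohort(cohort_config(), seed = 29)
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)
  expect_no_warning({
    m2 <- read_vcf(paths$tumor1_mutect2, "mutect2")
    pl <- read_vcf(paths$tumor1_platypus, "platypus")
    nv <- read_vcf(paths$normal01_platypus, "platypus")
    sv <- read_sv_vcf(paths$tumor1_sv)
    seg <- read_segments(paths$tumor1_segments)
    bed <- read_bed(paths$centromeres)
    gm <- read_gene_model(paths$gtf)
    ev <- read_evidence(paths$evidence)
    cov <- read_coverage(paths$tumor1_coverage)
  })
  expect_equal(nrow(m2), nrow(co$tumors$tumor1$mutect2))
  expect_equal(sort(site_key(pl)), sort(site_key(co$tumors$tumor1$platypus)))
  expect_setequal(sv$sv_id, co$sv$tumors$tumor1$sv_id)
  expect_equal(sort(seg$start), sort(co$segments$tumor1$start))
  expect_equal(nrow(bed), nrow(co$sv$centromeres))
  expect_equal(sort(unique(gm$genes$gene_id)), paste0("GENE", 1:6))
  expect_equal(nrow(ev), nrow(co$evidence))
  expect_equal(cov, co$coverage$tumor1$depths)
})

test_that("signature catalog sampling follows the mixture law of large numbers", {
  sig <- simulate_signature_bank(1, seed = 31)
  cat_m <- simulate_signature_catalog(1, sig, 1e5, seed = 32)
  expect_equal(sum(cat_m), 1e5)
  emp <- as.vector(unclass(cat_m)) / 1e5
  expect_lt(max(abs(emp - sig[1, ])), 0.01)
  zero <- simulate_signature_catalog(1, sig, 0, seed = 33)
  expect_true(all(zero == 0))
  expect_identical(unclass(simulate_signature_catalog(1, sig, 500, seed = 34)),
                   unclass(simulate_signature_catalog(1, sig, 500, seed = 34)))
})

test_that("admixed genotypes match their generating frequencies and missingness", {
  set.seed(35)
  f <- simulate_breed_freqs(2, 4000)
  g <- simulate_admixed_genotypes(f, c(1, 0), missing_rate = 0.12, seed = 36)
  miss <- mean(is.na(g$geno))
  expect_lt(abs(miss - 0.12), 0.02)
  emp <- colMeans(g$geno, na.rm = TRUE) / 2
  expect_lt(mean(abs(emp - f[1, ]), na.rm = TRUE), 0.4)  # binomial n=2 noise
  expect_error(simulate_admixed_genotypes(f, c(0.5, 0.6)), "not")
})

test_that("support grids straddle every filtering threshold", {
  co <- simulate_cohort(cohort_config(), seed = 37)
  m2 <- co$tumors$tumor1$mutect2
  truth <- co$tumors$tumor1$truth
  low <- m2[site_key(m2) %in%
              site_key(truth[truth$class == "somatic_lowsupport", ]), ]
  expect_true(all(low$af < 0.05 | low$dp < 10 | low$alt_depth < 3))
  elig <- m2[site_key(m2) %in% site_key(truth[truth$eligible, ]), ]
  expect_true(all(elig$af >= 0.05 & elig$dp >= 10 & elig$alt_depth >= 3))
  expect_true(any(elig$af == 0.05) && any(elig$dp == 10) &&
                any(elig$alt_depth == 3))
})
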