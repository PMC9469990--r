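test_that("rescue resets only records flagged solely by the rescue flag", {
  r <- rec("chr1", c(100, 200, 300),
           filter = c("germline", "germline;weak_evidence", "germline"))
  removed <- data.frame(chrom = "chr1", pos = c(100, 200))
  out <- rescue_flag(r, removed, "germline")
  expect_equal(out$records$filter, c("", "germline;weak_evidence", "germline"))
  expect_equal(out$audit$rescued, 1L)
  expect_equal(out$audit$removed, 0L)
})

test_that("panel of normals is a position-only union over normal call sets", {
  n1 <- rec("chr1", c(100, 200), alt = "T", sample = "n1")
  n2 <- rec("chr1", c(100, 300), alt = "G", sample = "n2")
  pon <- build_site_pon(list(n1, n2))
  expect_equal(nrow(pon$records), 3)   # chr1:100 shared despite A>T vs A>G
  expect_setequal(pon$provenance, c("n1", "n2"))
  expect_error(build_site_pon(list()), "at least one")
})

test_that("site removal ignores alternate alleles and handles indel footprints", {
  tumor <- rec("chr1", c(100, 200), alt = c("G", "C"))
  resource <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "T")
  out <- remove_sites(tumor, resource)
  expect_equal(out$records$pos, 200L)
  # 3 bp deletion listed 1 bp away in the resource: footprints intersect
  del <- variant_records("chr1", 500, "TAA", "T")
  res2 <- data.frame(chrom = "chr1", pos = 501, ref = "AAC")
  expect_equal(nrow(remove_sites(del, res2)$records), 0)
  # SNV one base away does not match
  snv <- rec("chr1", 500)
  expect_equal(nrow(remove_sites(snv, res2[, c("chrom", "pos")])$records), 1)
})

test_that("removal steps are idempotent and allele-permutation invariant", {
  set.seed(11)
  tumor <- rec("chr1", sample.int(1e5, 50))
  sites <- data.frame(chrom = "chr1", pos = tumor$pos[1:20],
                      ref = "A", alt = sample(c("T", "G", "C"), 20, TRUE))
  once <- remove_sites(tumor, sites)$records
  twice <- remove_sites(once, sites)$records
  expect_equal(once, twice)
  sites2 <- sites; sites2$alt <- rev(sites2$alt)
  expect_equal(remove_sites(tumor, sites2)$records, once)
})

test_that("consensus keeps primary-caller records at shared positions only", {
  a <- rec("chr1", c(100, 200, 300), alt = "T", sample = "t1")
  b <- rec("chr1", c(100, 300, 400), alt = "G", caller = "platypus", sample = "t1")
  out <- consensus_intersect(a, b)
  expect_equal(out$records$pos, c(100L, 300L))
  expect_equal(out$records$alt, c("T", "T"))   # representation from caller A
  expect_equal(out$records$caller, c("mutect2", "mutect2"))
  expect_error(consensus_intersect(a, rec("chr1", 1, sample = "t2")), "different samples")
})

test_that("consensus equals the brute-force site-key intersection", {
  set.seed(12)
  for (i in 1:5) {
    a <- rec("chr1", sample.int(500, 200), sample = "t1")
    b <- rec("chr1", sample.int(500, 200), caller = "platypus", sample = "t1")
    got <- sort(unique(site_key(consensus_intersect(a, b)$records)))
    want <- sort(intersect(unique(site_key(a)), unique(site_key(b))))
    expect_equal(got, want)
  }
})

test_that("support thresholds keep boundary values and drop strict failures", {
  grid <- expand.grid(af = c(0.049, 0.05), dp = c(9, 10), alt = c(2, 3))
  r <- variant_records("chr1", seq_len(nrow(grid)), "A", "T",
                       af = grid$af, dp = grid$dp, alt_depth = grid$alt)
  kept <- apply_support_thresholds(r)$records
  want <- grid$af >= 0.05 & grid$dp >= 10 & grid$alt >= 3
  expect_equal(sort(kept$pos), which(want))
})

test_that("regenotyping screen removes any-normal-support sites, errors on gaps", {
  r <- rec("chr1", c(100, 200))
  ev <- data.frame(chrom = "chr1", pos = rep(c(100, 200), each = 2),
                   sample = rep(c("n1", "n2"), 2),
                   support = c(TRUE, FALSE, FALSE, FALSE))
  out <- regenotype_screen(r, ev)
  expect_equal(out$records$pos, 200L)
  expect_error(regenotype_screen(rec("chr1", 999), ev), "no regenotyping evidence")
})

test_that("rescue must precede non-PASS removal; resource and support steps commute", {
  r <- rec("chr1", 100, filter = "germline")
  removed <- data.frame(chrom = "chr1", pos = 100)
  rescued_first <- drop_non_pass(rescue_flag(r, removed, "germline")$records)$records
  dropped_first <- rescue_flag(drop_non_pass(r)$records, removed, "germline")$records
  expect_equal(nrow(rescued_first), 1)
  expect_equal(nrow(dropped_first), 0)

  set.seed(13)
  rr <- variant_records("chr1", sample.int(1e4, 100), "A", "T",
                        af = sample(c(0.03, 0.2), 100, TRUE),
                        dp = sample(c(9, 30), 100, TRUE),
                        alt_depth = 3)
  sites <- data.frame(chrom = "chr1", pos = rr$pos[1:40])
  ab <- apply_support_thresholds(remove_sites(rr, sites)$records)$records
  ba <- remove_sites(apply_support_thresholds(rr)$records, sites)$records
  expect_equal(ab[order(ab$pos), ], ba[order(ba$pos), ], ignore_attr = TRUE)
})

test_that("audit rows conserve counts and chains validate", {
  co <- simulate_cohort(cohort_config(), seed = 3)
  res <- run_snv_pipeline(snv_pipeline_config(co, "tumor1"))
  a <- res$audit
  expect_true(all(a$n_out == a$n_in - a$removed))
  # the platypus branch chains from its rescue through the PON screen
  expect_equal(a$n_in[a$step == "step3_platypus_pon"],
               a$n_out[a$step == "step2_rescue_alleleBias"])
  # consensus output chains into the resource, support and regenotype steps
  tail_steps <- a[grepl("step[678]", a$step), ]
  expect_true(all(tail_steps$n_in[-1] == tail_steps$n_out[-nrow(tail_steps)]))
  expect_true(validate_audit(tail_steps))
})
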