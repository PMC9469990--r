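test_that("nonlinear merge distance follows min(max_dist, sv length)", {
  # 5 kb deletions 200 bp apart: d = 1000, one cluster
  a <- sv_records(c("a", "b"), "DEL", "chr1", c(10000L, 10200L),
                  pos2 = c(15000L, 15200L), svlen = 5000)
  expect_equal(length(unique(merge_svs(a)$cluster)), 1)
  # different types never merge
  b <- sv_records(c("a", "b"), c("DEL", "DUP"), "chr1", 10000L,
                  pos2 = 15000L, svlen = 5000)
  expect_equal(length(unique(merge_svs(b)$cluster)), 2)
  # 300 bp deletions 600 bp apart: d = min(1000, 300) = 300, two clusters
  c3 <- sv_records(c("a", "b"), "DEL", "chr1", c(10000L, 10600L),
                   pos2 = c(10300L, 10900L), svlen = 300)
  expect_equal(length(unique(merge_svs(c3)$cluster)), 2)
})

test_that("merge partition is invariant to input order", {
  set.seed(21)
  for (i in 1:10) {
    sv <- random_sv_fixture(n_pairs = 5, n_del = 8)
    sv$sv_id <- paste0("s", seq_len(nrow(sv)))
    m1 <- merge_svs(sv)
    perm <- sv[sample.int(nrow(sv)), ]
    class(perm) <- class(sv)
    m2 <- merge_svs(perm)
    expect_equal(cluster_signature(m1), cluster_signature(m2))
  }
})

test_that("PON screen removes only SVs clustering with a normal", {
  tumor <- sv_records(c("t1", "t2"), "DEL", "chr1", c(10000L, 500000L),
                      pos2 = c(15000L, 505000L), svlen = 5000, pr = 30L,
                      sample = "tum")
  normal <- sv_records("n1", "DEL", "chr1", 10100L, pos2 = 15100L,
                       svlen = 5000, pr = 20L, sample = "norm")
  out <- pon_screen(tumor, list(normal))
  expect_equal(out$records$sv_id, "t2")
  # no normal within 10 kb: everything survives
  far <- sv_records("n2", "INS", "chr2", 1000L, pos2 = 1000L, sample = "norm")
  out2 <- pon_screen(tumor, list(far))
  expect_equal(nrow(out2$records), 2)
})

test_that("quality filter applies PASS, IMPRECISE and PR/SR >= 15 rules", {
  sv <- sv_records(paste0("s", 1:4), "DEL", "chr1", 1000L, pos2 = 2000L,
                   svlen = 1000,
                   pr = c(14L, 0L, 40L, 15L), sr = c(14L, 15L, 40L, 0L),
                   imprecise = c(FALSE, FALSE, TRUE, FALSE))
  out <- apply_sv_quality_filters(sv)
  expect_setequal(out$records$sv_id, c("s2", "s4"))
})

test_that("centromere flagging matches the naive overlap oracle", {
  set.seed(22)
  windows <- random_intervals(30, chroms = c("chr1", "chr2"), max_pos = 5e5)
  sv <- random_sv_fixture(n_pairs = 6, n_del = 10)
  flagged <- flag_centromeric(sv, windows)$centromeric
  # oracle: breakend points for BND, spanned interval otherwise
  for (i in seq_len(nrow(sv))) {
    if (sv$sv_type[i] == "BND") {
      iv <- genomic_intervals(c(sv$chrom1[i], sv$chrom2[i]),
                              c(sv$pos1[i] - 1, sv$pos2[i] - 1),
                              c(sv$pos1[i], sv$pos2[i]))
    } else {
      iv <- genomic_intervals(sv$chrom1[i], sv$pos1[i] - 1, sv$pos2[i])
    }
    expect_equal(flagged[i], nrow(naive_overlap_pairs(iv, windows)) > 0)
  }
})

test_that("SV regenotyping screen removes any-support records, errors on gaps", {
  sv <- random_sv_fixture(n_pairs = 2, n_del = 2)
  ev <- data.frame(sv_id = rep(sv$sv_id, 2),
                   sample = rep(c("n1", "n2"), each = nrow(sv)),
                   support = FALSE)
  ev$support[ev$sv_id == "del_01" & ev$sample == "n2"] <- TRUE
  out <- regenotype_screen_sv(sv, ev)
  expect_false("del_01" %in% out$records$sv_id)
  expect_equal(nrow(out$records), nrow(sv) - 1)
  expect_error(regenotype_screen_sv(sv, ev[ev$sv_id != "del_02", ]),
               "no SV regenotyping evidence")
})

test_that("orphan breakend removal restores mate closure", {
  sv <- random_sv_fixture(n_pairs = 3, n_del = 1)
  filtered <- sv[sv$sv_id != "bnd_02_2", ]   # one mate lost upstream
  class(filtered) <- class(sv)
  out <- drop_orphan_breakends(filtered, original_ids = sv$sv_id)
  bnd <- out$records[out$records$sv_type == "BND", ]
  expect_true(all(bnd$mate_id %in% bnd$sv_id))
  expect_false("bnd_02_1" %in% out$records$sv_id)
  expect_true("del_01" %in% out$records$sv_id)
  # mate id never present in the original input is malformed
  bad <- sv; bad$mate_id[bad$sv_id == "bnd_01_1"] <- "ghost"
  expect_error(drop_orphan_breakends(bad), "malformed")
})

test_that("full SV pipeline recovers planted truth on the synthetic cohort", {
  co <- simulate_cohort(cohort_config(), seed = 5)
  for (tn in names(co$sv$tumors)) {
    res <- run_sv_pipeline(sv_pipeline_config(co, tn))
    truth <- co$sv$truth[co$sv$truth$sample == tn, ]
    expect_setequal(res$records$sv_id, truth$sv_id[truth$eligible])
    bnd <- res$records[res$records$sv_type == "BND", ]
    expect_true(all(bnd$mate_id %in% bnd$sv_id))
    expect_equal(sum(res$records$centromeric),
                 sum(truth$class == "centromeric"))
    validate_audit(res$audit)
  }
})
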