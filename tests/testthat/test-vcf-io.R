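write_lines_vcf <- function(lines, fileext = ".vcf") {
  path <- withr::local_tempfile(fileext = fileext, .local_envir = parent.frame())
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               lines), path)
  path
}

test_that("filter field tokenizes into a flag set; PASS and . are empty", {
  p <- write_lines_vcf(c(
    "chr1\t100\t.\tA\tT\t.\tgermline;weak_evidence\t.\tGT:AF:DP:AD\t0/1:0.4:30:18,12",
    "chr1\t200\t.\tA\tT\t.\tPASS\t.\tGT:AF:DP:AD\t0/1:0.4:30:18,12",
    "chr1\t300\t.\tA\tT\t.\t.\t.\tGT:AF:DP:AD\t0/1:0.4:30:18,12"))
  r <- read_vcf(p, "mutect2")
  toks <- filter_tokens(r)
  expect_equal(toks[[1]], c("germline", "weak_evidence"))
  expect_length(toks[[2]], 0)
  expect_length(toks[[3]], 0)
  expect_equal(r$filter[2], "")
})

test_that("multiallelic rows split into one record per alt, conserving alts", {
  p <- write_lines_vcf(
    "chr1\t100\t.\tA\tT,G\t.\tPASS\t.\tGT:AF:DP:AD\t0/1:0.3,0.1:50:30,15,5")
  r <- read_vcf(p, "mutect2")
  expect_equal(nrow(r), 2)
  expect_equal(unique(site_key(r)), "chr1:100")
  expect_equal(sort(r$alt), c("G", "T"))
  expect_equal(r$alt_depth[r$alt == "T"], 15)
  expect_equal(r$alt_depth[r$alt == "G"], 5)
  expect_equal(r$af[r$alt == "T"], 0.3)
})

test_that("platypus dialect reads NR/NV and recomputes AF", {
  p <- write_lines_vcf(
    "chr2\t500\t.\tC\tG\t.\talleleBias\t.\tGT:NR:NV\t0/1:40:6")
  r <- read_vcf(p, "platypus")
  expect_equal(r$dp, 40)
  expect_equal(r$alt_depth, 6)
  expect_equal(r$af, 0.15)
  expect_equal(r$filter, "alleleBias")
  expect_equal(r$caller, "platypus")
})

test_that("missing AF falls back to alt_depth/DP; fully unsupported stays NA", {
  p <- write_lines_vcf(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP:AD\t0/1:40:30,10",
    "chr1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t0/1"))
  r <- read_vcf(p, "mutect2")
  expect_equal(r$af[1], 0.25)
  expect_true(is.na(r$af[2]))
  kept <- apply_support_thresholds(r)$records
  expect_equal(nrow(kept), 1)  # unsupported record fails thresholds
})

test_that("VCF round trip preserves positions, alleles and filter tokens", {
  r <- rec("chr1", c(100, 200, 300), ref = c("A", "CT", "G"),
           alt = c("T", "C", "GAA"),
           filter = c("", "germline;weak_evidence", "alleleBias"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(r, path, contigs = c(chr1 = 1e6))
  back <- read_vcf(path, "mutect2")
  expect_equal(back$chrom, r$chrom)
  expect_equal(back$pos, r$pos)
  expect_equal(back$ref, r$ref)
  expect_equal(back$alt, r$alt)
  expect_equal(filter_tokens(back), filter_tokens(r))
  expect_equal(back$af, r$af)
})

test_that("variant_records rejects inconsistent support fields", {
  expect_error(rec("chr1", 1, af = 1.5), "fraction")
  expect_error(rec("chr1", 1, dp = 10, alt_depth = 12), "exceeds")
})

test_that("gene model reader returns CDS nested in gene bodies", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttoy\tgene\t1001\t3000\t.\t+\t.\tgene_id "G1";',
    'chr1\ttoy\tCDS\t1101\t1500\t.\t+\t.\tgene_id "G1";',
    'chr1\ttoy\tCDS\t2001\t2400\t.\t+\t.\tgene_id "G1";'), gtf)
  gm <- read_gene_model(gtf)
  expect_equal(gm$genes$start, 1000)   # converts to 0-based half-open
  expect_equal(gm$genes$end, 3000)
  expect_equal(nrow(gm$cds), 2)
  expect_equal(gm$cds$gene_id, c("G1", "G1"))
})

test_that("SV VCF round trip preserves type, support, mates and flags", {
  svs <- sv_records(c("sv1", "b1", "b2"), c("DEL", "BND", "BND"),
                    chrom1 = c("chr1", "chr1", "chr2"),
                    pos1 = c(1000L, 5000L, 7000L),
                    chrom2 = c("chr1", "chr2", "chr1"),
                    pos2 = c(2000L, 7000L, 5000L),
                    svlen = c(1000, NA, NA), pr = c(20L, 16L, 16L),
                    sr = c(0L, 3L, 3L), imprecise = c(TRUE, FALSE, FALSE),
                    filter = c("MaxDepth", "", ""),
                    mate_id = c(NA, "b2", "b1"), sample = "t1")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(svs, path)
  back <- read_sv_vcf(path)
  back <- back[match(svs$sv_id, back$sv_id), ]
  expect_equal(back$sv_type, svs$sv_type)
  expect_equal(back$pos2, svs$pos2)
  expect_equal(back$chrom2, svs$chrom2)
  expect_equal(back$pr, svs$pr)
  expect_equal(back$imprecise, svs$imprecise)
  expect_equal(back$mate_id, svs$mate_id)
  expect_equal(back$filter, svs$filter)
})
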