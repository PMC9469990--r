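# Caller dialects: which VCF fields carry per-sample support.
#   mutect2  - FORMAT AF (fraction per alt), DP, AD (ref,alt1,alt2,...)
#   platypus - FORMAT NR (reads covering site, per alt), NV (reads supporting
#              alt); AF is recomputed as NV/NR
.dialects <- c("mutect2", "platypus")

#' Build a variant-record table
#'
#' One row per chrom/pos/alt. `filter` holds the raw FILTER tokens joined by
#' ";" with the VCF conventions `"."` and `"PASS"` normalized to the empty
#' string (a passing record has an empty flag set). `af`, `dp`, `alt_depth`
#' are per-sample support fields; records where both `af` and the depth pair
#' are missing are "unsupported" and fail support thresholds.
#'
#' @param chrom,pos,ref,alt vectors; `pos` is the 1-based VCF position.
#' @param filter character; ";"-joined filter tokens, "" when passing.
#' @param af,dp,alt_depth numeric support fields (NA allowed).
#' @param caller provenance label.
#' @param sample sample label.
#' @return data frame of class `c("variant_records", "data.frame")`.
#' @export
variant_records <- function(chrom, pos, ref, alt, filter = "",
                            af = NA_real_, dp = NA_real_,
                            alt_depth = NA_real_, caller = NA_character_,
                            sample = NA_character_) {
  n <- length(pos)
  af <- as.numeric(af)
  dp <- as.numeric(dp)
  alt_depth <- as.numeric(alt_depth)
  # missing AF falls back to alt_depth / DP when both depths are present
  need <- is.na(af) & !is.na(dp) & !is.na(alt_depth) & dp > 0
  af[need] <- alt_depth[need] / dp[need]
  bad_af <- !is.na(af) & (af < 0 | af > 1)
  if (any(bad_af)) stop("allelic fraction outside [0,1]")
  bad_ad <- !is.na(dp) & !is.na(alt_depth) & alt_depth > dp
  if (any(bad_ad)) stop("alt depth exceeds total depth")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   filter = rep_len(as.character(filter), n),
                   af = rep_len(af, n), dp = rep_len(dp, n),
                   alt_depth = rep_len(alt_depth, n),
                   caller = rep_len(as.character(caller), n),
                   sample = rep_len(as.character(sample), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("variant_records", "data.frame")
  df
}

#' Position-only site keys
#'
#' Two calls are the "same site" when chromosome and position agree,
#' regardless of alleles — the matching rule used throughout the
#' panel-of-normals and consensus steps.
#'
#' @param x `variant_records` (or any data frame with chrom, pos).
#' @return character vector `"chrom:pos"`.
#' @export
site_key <- function(x) paste(x$chrom, x$pos, sep = ":")

#' Filter flag tokens of each record
#'
#' @param x `variant_records`.
#' @return list of character vectors (empty vector = passing).
#' @export
filter_tokens <- function(x) {
  lapply(strsplit(x$filter, ";", fixed = TRUE),
         function(t) t[nzchar(t) & t != "PASS" & t != "."])
}

.normalize_filter <- function(f) {
  f[is.na(f) | f == "." | f == "PASS"] <- ""
  f
}

.format_field <- function(format, sample, key) {
  keys <- strsplit(format, ":", fixed = TRUE)
  vals <- strsplit(sample, ":", fixed = TRUE)
  vapply(seq_along(keys), function(i) {
    j <- match(key, keys[[i]])
    if (is.na(j) || j > length(vals[[i]])) NA_character_ else vals[[i]][j]
  }, character(1))
}

.num <- function(x) {
  x[!is.na(x) & x == "."] <- NA_character_
  suppressWarnings(as.numeric(x))
}

.nth_csv <- function(x, n) {
  vapply(seq_along(x), function(i) {
    if (is.na(x[i])) return(NA_character_)
    parts <- strsplit(x[i], ",", fixed = TRUE)[[1]]
    if (n[i] > length(parts)) NA_character_ else parts[n[i]]
  }, character(1))
}

#' Read an SNV/indel VCF into variant records
#'
#' Multiallelic rows are split into one record per alternate allele on
#' ingest; per-alt FORMAT fields (AD / AF / NV / NR) are split accordingly.
#' FILTER `"."` and `"PASS"` become the empty flag set.
#'
#' @param path VCF 4.x file.
#' @param dialect `"mutect2"` or `"platypus"` — identifies which FORMAT keys
#'   carry AF, DP and alt depth.
#' @param sample sample label to attach; defaults to the first genotype
#'   column name.
#' @return `variant_records`.
#' @export
read_vcf <- function(path, dialect = c("mutect2", "platypus"), sample = NULL) {
  dialect <- match.arg(dialect)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) return(variant_records(character(0), integer(0), character(0), character(0)))
  has_gt <- ncol(v@gt) >= 2
  if (is.null(sample)) sample <- if (has_gt) colnames(v@gt)[2] else NA_character_
  fmt <- if (has_gt) v@gt[, 1] else rep(NA_character_, n)
  smp <- if (has_gt) v@gt[, 2] else rep(NA_character_, n)

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_i <- rep(seq_len(n), n_alt)     # source row per split record
  alt_i <- sequence(n_alt)            # which alt within the row

  filt <- .normalize_filter(fix[row_i, "FILTER"])
  if (dialect == "mutect2") {
    dp <- .num(.format_field(fmt, smp, "DP"))[row_i]
    ad <- .format_field(fmt, smp, "AD")[row_i]
    alt_depth <- .num(.nth_csv(ad, alt_i + 1L))   # AD = ref,alt1,alt2,...
    af <- .num(.nth_csv(.format_field(fmt, smp, "AF")[row_i], alt_i))
  } else {
    nr <- .num(.nth_csv(.format_field(fmt, smp, "NR")[row_i], alt_i))
    nv <- .num(.nth_csv(.format_field(fmt, smp, "NV")[row_i], alt_i))
    dp <- nr
    alt_depth <- nv
    af <- ifelse(!is.na(nr) & !is.na(nv) & nr > 0, nv / nr, NA_real_)
  }
  variant_records(chrom = fix[row_i, "CHROM"], pos = as.integer(fix[row_i, "POS"]),
                  ref = fix[row_i, "REF"], alt = unlist(alts),
                  filter = filt, af = af, dp = dp, alt_depth = alt_depth,
                  caller = dialect, sample = sample)
}

#' Write variant records as a VCF file
#'
#' Emits one row per record (previously split multiallelics stay split) with
#' support fields in Mutect2-style FORMAT keys. Filter tokens are written
#' verbatim; an empty flag set becomes `PASS`.
#'
#' @param records `variant_records`.
#' @param path output path.
#' @param sample genotype column name; defaults to the records' sample label.
#' @param contigs optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample = NULL, contigs = NULL) {
  if (is.null(sample)) {
    sample <- if (nrow(records) && !is.na(records$sample[1])) records$sample[1] else "SAMPLE"
  }
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)))
  }
  flt <- sort(unique(unlist(filter_tokens(records))))
  if (length(flt)) hdr <- c(hdr, sprintf('##FILTER=<ID=%s,Description="%s">', flt, flt))
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  if (nrow(records)) {
    o <- order(records$chrom, records$pos, records$alt)
    r <- records[o, , drop = FALSE]
    filt <- ifelse(nzchar(r$filter), r$filter, "PASS")
    fmt <- sprintf("0/1:%s:%s:%s",
                   ifelse(is.na(r$af), ".", format(r$af, trim = TRUE, digits = 6)),
                   ifelse(is.na(r$dp), ".", format(r$dp, trim = TRUE)),
                   ifelse(is.na(r$dp) | is.na(r$alt_depth), ".",
                          paste0(format(r$dp - r$alt_depth, trim = TRUE), ",",
                                 format(r$alt_depth, trim = TRUE))))
    body <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", filt, ".",
                  "GT:AF:DP:AD", fmt, sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gene model from GTF/GFF3
#'
#' Only `gene` and `CDS` features are used. Intervals are converted to the
#' internal 0-based half-open convention. CDS intervals may be stored
#' unmerged; queries behave as if merged.
#'
#' @param path GTF or GFF3 file.
#' @return list of class `gene_model` with elements `genes` and `cds`, both
#'   `genomic_intervals` with a `gene_id` column.
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  gid <- as.character(gr$gene_id)
  take <- function(what) {
    keep <- type == what
    genomic_intervals(as.character(GenomicRanges::seqnames(gr[keep])),
                      GenomicRanges::start(gr[keep]) - 1L,
                      GenomicRanges::end(gr[keep]),
                      gene_id = gid[keep])
  }
  gm <- list(genes = take("gene"), cds = take("CDS"))
  # CDS must lie within its gene body
  if (nrow(gm$cds)) {
    gb <- gm$genes
    for (i in seq_len(nrow(gm$cds))) {
      j <- which(gb$gene_id == gm$cds$gene_id[i] & gb$chrom == gm$cds$chrom[i])
      if (length(j) && !(any(gm$cds$start[i] >= gb$start[j] & gm$cds$end[i] <= gb$end[j]))) {
        stop("CDS interval outside gene body for ", gm$cds$gene_id[i])
      }
    }
  }
  class(gm) <- "gene_model"
  gm
}

#' Read a copy-ratio segment table
#'
#' Tab-separated with columns contig, start, end, log2 copy ratio (1-based
#' closed coordinates, as written by common segmentation tools).
#'
#' @param path TSV path.
#' @return `genomic_intervals` with a `log2_ratio` column.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  cn <- function(...) intersect(c(...), names(df))[1]
  genomic_intervals(df[[cn("contig", "chrom", "chromosome")]],
                    df[[cn("start")]] - 1L, df[[cn("end")]],
                    log2_ratio = df[[cn("log2_ratio", "mean_log2_copy_ratio", "log2")]])
}

#' Read a regenotyping evidence table
#'
#' Tab-separated: chrom, pos, sample, support (0/1). One row per queried
#' site per normal sample; `support` says whether that normal shows any
#' read or genotype support at the site.
#'
#' @param path TSV path.
#' @return data frame of class `normal_evidence`.
#' @export
read_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "sample", "support") %in% names(df)))
  df$support <- as.logical(df$support)
  class(df) <- c("normal_evidence", "data.frame")
  df
}
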