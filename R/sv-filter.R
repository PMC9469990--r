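#' Build a structural-variant record table
#'
#' One row per VCF record. Non-breakend types (DEL/INS/INV/DUP) live on one
#' chromosome with `pos1 <= pos2`; translocation breakends (BND) occur in
#' mate pairs linked by `mate_id`, with the partner breakpoint in
#' `chrom2/pos2`. `pr`/`sr` are paired-read and split-read alt support
#' counts.
#'
#' @param sv_id unique identifier.
#' @param sv_type one of DEL, INS, INV, DUP, BND.
#' @param chrom1,pos1 first (or only) breakpoint, 1-based.
#' @param chrom2,pos2 second breakpoint (end position for non-BND).
#' @param svlen length in bp (NA for BND).
#' @param pr,sr paired-read / split-read support counts.
#' @param imprecise logical; breakpoints not base-pair resolved.
#' @param filter ";"-joined filter tokens, "" when passing.
#' @param mate_id partner record id (BND only, else NA).
#' @param sample sample label.
#' @return data frame of class `c("sv_records", "data.frame")` with an
#'   additional `centromeric` flag column (initialized FALSE).
#' @export
sv_records <- function(sv_id, sv_type, chrom1, pos1, chrom2 = chrom1,
                       pos2 = pos1, svlen = NA_real_, pr = 0L, sr = 0L,
                       imprecise = FALSE, filter = "", mate_id = NA_character_,
                       sample = NA_character_) {
  n <- length(sv_id)
  df <- data.frame(sv_id = as.character(sv_id),
                   sv_type = as.character(sv_type),
                   chrom1 = as.character(chrom1), pos1 = as.integer(pos1),
                   chrom2 = rep_len(as.character(chrom2), n),
                   pos2 = rep_len(as.integer(pos2), n),
                   svlen = rep_len(as.numeric(svlen), n),
                   pr = rep_len(as.integer(pr), n),
                   sr = rep_len(as.integer(sr), n),
                   imprecise = rep_len(as.logical(imprecise), n),
                   filter = rep_len(.normalize_filter(as.character(filter)), n),
                   mate_id = rep_len(as.character(mate_id), n),
                   sample = rep_len(as.character(sample), n),
                   centromeric = rep_len(FALSE, n),
                   stringsAsFactors = FALSE)
  bad_type <- !df$sv_type %in% c("DEL", "INS", "INV", "DUP", "BND")
  if (any(bad_type)) stop("unknown sv_type: ", df$sv_type[bad_type][1])
  nb <- df$sv_type != "BND"
  if (any(nb & (df$chrom1 != df$chrom2 | df$pos1 > df$pos2))) {
    stop("non-BND records must have pos1 <= pos2 on a single chromosome")
  }
  if (any(df$pr < 0 | df$sr < 0, na.rm = TRUE)) stop("negative support counts")
  if (anyDuplicated(df$sv_id)) stop("duplicate sv_id")
  class(df) <- c("sv_records", "data.frame")
  df
}

# Canonical breakpoint pair: ((chromA,posA),(chromB,posB)) sorted so the
# lexicographically smaller (chrom,pos) comes first; makes the merge
# predicate symmetric in breakend orientation.
.canonical_bp <- function(svs) {
  swap <- svs$chrom2 < svs$chrom1 |
    (svs$chrom2 == svs$chrom1 & svs$pos2 < svs$pos1)
  data.frame(chromA = ifelse(swap, svs$chrom2, svs$chrom1),
             posA = ifelse(swap, svs$pos2, svs$pos1),
             chromB = ifelse(swap, svs$chrom1, svs$chrom2),
             posB = ifelse(swap, svs$pos1, svs$pos2))
}

#' Cluster structural variants with a nonlinear merge distance
#'
#' Two SVs are mergeable iff they share `sv_type` and chromosome pair and
#' both breakpoints lie within `d` of each other, where
#' `d = min(max_dist, length of either variant)` for length-bearing types
#' (a 300 bp deletion only merges within 300 bp) and `d = max_dist` for
#' BND and INS. Clusters are single-linkage components of the mergeable
#' relation; the result is invariant to input order.
#'
#' @param callsets an `sv_records` table or list of them (e.g. one per
#'   sample).
#' @param max_dist maximum merge distance in bp.
#' @return `sv_records` of all inputs with an added `cluster` column
#'   (integer id, numbered by first sorted member).
#' @export
merge_svs <- function(callsets, max_dist = 1000) {
  if (is.data.frame(callsets)) callsets <- list(callsets)
  svs <- do.call(rbind, lapply(callsets, as.data.frame))
  class(svs) <- c("sv_records", "data.frame")
  n <- nrow(svs)
  if (n == 0) { svs$cluster <- integer(0); return(svs) }
  # deterministic processing order regardless of input order
  bp <- .canonical_bp(svs)
  o <- order(svs$sv_type, bp$chromA, bp$posA, bp$chromB, bp$posB,
             svs$sv_id, svs$sample)
  svs <- svs[o, , drop = FALSE]
  bp <- bp[o, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  len_d <- ifelse(svs$sv_type %in% c("BND", "INS") | is.na(svs$svlen),
                  max_dist, pmin(max_dist, abs(svs$svlen)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (svs$sv_type[j] != svs$sv_type[i]) break # sorted by type first
      if (bp$chromA[i] != bp$chromA[j] || bp$chromB[i] != bp$chromB[j]) next
      d <- min(len_d[i], len_d[j])
      if (abs(bp$posA[i] - bp$posA[j]) <= d && abs(bp$posB[i] - bp$posB[j]) <= d) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  svs$cluster <- as.integer(factor(roots, levels = unique(roots)))
  rownames(svs) <- NULL
  svs
}

#' Remove SVs present in the panel of normals
#'
#' Merges the tumor call set with all normal call sets; a tumor SV survives
#' iff its cluster contains no member from a normal sample.
#'
#' @param cell_line_svs `sv_records` for the tumor sample.
#' @param normal_callsets list of `sv_records`, one per normal.
#' @param max_dist merge distance passed to [merge_svs()].
#' @param step audit label.
#' @return list with `records` (surviving tumor SVs) and `audit`.
#' @export
pon_screen <- function(cell_line_svs, normal_callsets, max_dist = 1000,
                       step = "sv_pon_screen") {
  tumor_sample <- unique(cell_line_svs$sample)
  merged <- merge_svs(c(list(cell_line_svs), normal_callsets), max_dist)
  is_normal <- !(merged$sample %in% tumor_sample)
  bad_clusters <- unique(merged$cluster[is_normal])
  surv_ids <- merged$sv_id[!is_normal & !(merged$cluster %in% bad_clusters)]
  keep <- cell_line_svs$sv_id %in% surv_ids
  list(records = cell_line_svs[keep, , drop = FALSE],
       audit = .audit_row(step, nrow(cell_line_svs), removed = sum(!keep)))
}

#' Apply SV quality filters
#'
#' Keeps records whose filter field is passing, that are not flagged
#' IMPRECISE, and where paired-read or split-read support reaches
#' `min_support`.
#'
#' @param svs `sv_records`.
#' @param min_support minimum PR or SR alt support (inclusive).
#' @param step audit label.
#' @return list with `records` and `audit`.
#' @export
apply_sv_quality_filters <- function(svs, min_support = 15,
                                     step = "sv_quality") {
  keep <- !nzchar(svs$filter) & !svs$imprecise &
    (svs$pr >= min_support | svs$sr >= min_support)
  list(records = svs[keep, , drop = FALSE],
       audit = .audit_row(step, nrow(svs), removed = sum(!keep)))
}

#' Flag SVs overlapping centromeric windows
#'
#' Sets `centromeric` when either breakpoint (BND) or the spanned interval
#' (other types) overlaps a window of the centromere BED. Flagged records
#' are retained; downstream recurrence counting excludes them by default.
#'
#' @param svs `sv_records`.
#' @param centromere_bed path to a BED file or a `genomic_intervals`.
#' @return `sv_records` with the `centromeric` column set.
#' @export
flag_centromeric <- function(svs, centromere_bed) {
  windows <- if (is.character(centromere_bed)) read_bed(centromere_bed) else centromere_bed
  if (nrow(svs) == 0) return(svs)
  is_bnd <- svs$sv_type == "BND"
  iv <- genomic_intervals(
    chrom = svs$chrom1,
    start = svs$pos1 - 1L,
    end = ifelse(is_bnd, svs$pos1, svs$pos2))
  flag <- rep(FALSE, nrow(svs))
  h <- overlap_hits(iv, windows)
  flag[unique(h$query)] <- TRUE
  # second breakend of translocations
  if (any(is_bnd)) {
    iv2 <- genomic_intervals(svs$chrom2[is_bnd], svs$pos2[is_bnd] - 1L,
                             svs$pos2[is_bnd])
    h2 <- overlap_hits(iv2, windows)
    flag[which(is_bnd)[unique(h2$query)]] <- TRUE
  }
  svs$centromeric <- flag
  svs
}

#' Screen SVs against regenotyping evidence in normals
#'
#' Removes any SV with support in at least one normal sample. Evidence is
#' keyed by `sv_id` and must cover every queried id.
#'
#' @param svs `sv_records`.
#' @param evidence data frame with columns `sv_id`, `sample`, `support`.
#' @param step audit label.
#' @return list with `records` and `audit`.
#' @export
regenotype_screen_sv <- function(svs, evidence, step = "sv_regenotype") {
  if (nrow(svs) == 0) return(list(records = svs, audit = .audit_row(step, 0L)))
  missing <- setdiff(svs$sv_id, evidence$sv_id)
  if (length(missing)) {
    stop("no SV regenotyping evidence for ", length(missing),
         " record(s), e.g. ", missing[1])
  }
  supported <- unique(evidence$sv_id[as.logical(evidence$support)])
  hit <- svs$sv_id %in% supported
  list(records = svs[!hit, , drop = FALSE],
       audit = .audit_row(step, nrow(svs), removed = sum(hit)))
}

#' Remove breakends whose mate was filtered out
#'
#' Translocations are represented as mate-linked BND pairs; when one end
#' has been removed by an earlier step the orphaned end is removed too, so
#' the surviving BND set is closed under mate linkage. Non-BND records are
#' unaffected.
#'
#' @param svs `sv_records` after filtering.
#' @param original_ids sv_ids of the unfiltered input, used to distinguish
#'   "mate filtered out" from "mate never existed" (the latter is a
#'   malformed-input error). Defaults to the ids in `svs`.
#' @param step audit label.
#' @return list with `records` and `audit`.
#' @export
drop_orphan_breakends <- function(svs, original_ids = svs$sv_id,
                                  step = "sv_orphan_bnd") {
  is_bnd <- svs$sv_type == "BND"
  mates <- svs$mate_id[is_bnd]
  never_seen <- !is.na(mates) & !(mates %in% original_ids)
  if (any(never_seen) || any(is.na(mates))) {
    stop("malformed input: BND without a mate in the original call set")
  }
  orphan <- is_bnd & !(svs$mate_id %in% svs$sv_id)
  list(records = svs[!orphan, , drop = FALSE],
       audit = .audit_row(step, nrow(svs), removed = sum(orphan)))
}

#' Run the five-step structural-variant filter
#'
#' Steps: merge tumor + normal call sets with the nonlinear distance and
#' remove tumor SVs clustering with any normal (panel-of-normals screen,
#' steps 1-2 of the procedure); drop non-PASS, IMPRECISE and low-support
#' records and flag centromeric overlaps (step 3); remove SVs with
#' regenotyping support in any normal (step 4); remove orphaned
#' translocation breakends (step 5).
#'
#' @param config list with entries `tumor` (path or `sv_records`),
#'   `normals` (list of paths or `sv_records`), `centromeres` (BED path or
#'   `genomic_intervals`, optional), `evidence` (data frame or TSV path
#'   with sv_id/sample/support), `min_support` (default 15), `max_dist`
#'   (default 1000), `exclude_centromeric` (default FALSE — flagged records
#'   are retained but marked).
#' @return object of class `sv_pipeline_result`: list with `records` and
#'   `audit`.
#' @export
run_sv_pipeline <- function(config) {
  tumor <- if (is.character(config$tumor)) read_sv_vcf(config$tumor) else config$tumor
  normals <- lapply(config$normals, function(x) {
    if (is.character(x)) read_sv_vcf(x) else x
  })
  min_support <- config$min_support %||% 15
  max_dist <- config$max_dist %||% 1000
  original_ids <- tumor$sv_id

  s12 <- pon_screen(tumor, normals, max_dist, step = "step1_pon_screen")
  rec <- s12$records
  s3 <- apply_sv_quality_filters(rec, min_support, step = "step3_quality")
  rec <- s3$records
  if (!is.null(config$centromeres)) {
    rec <- flag_centromeric(rec, config$centromeres)
    if (isTRUE(config$exclude_centromeric)) {
      a_c <- .audit_row("step3_centromeric", nrow(rec), removed = sum(rec$centromeric))
      rec <- rec[!rec$centromeric, , drop = FALSE]
    } else a_c <- NULL
  } else a_c <- NULL
  ev <- config$evidence
  if (is.character(ev)) ev <- utils::read.delim(ev, stringsAsFactors = FALSE)
  s4 <- regenotype_screen_sv(rec, ev, step = "step4_regenotype")
  rec <- s4$records
  s5 <- drop_orphan_breakends(rec, original_ids, step = "step5_orphan_bnd")
  rec <- s5$records

  aud <- do.call(rbind, c(list(s12$audit, s3$audit), list(a_c),
                          list(s4$audit, s5$audit)))
  class(aud) <- c("filter_audit", "data.frame")
  validate_audit(aud)
  structure(list(records = rec, audit = aud), class = "sv_pipeline_result")
}

#' @export
print.sv_pipeline_result <- function(x, ...) {
  cat("Tumor-only structural-variant filter\n")
  cat("  final call set:", nrow(x$records), "records (",
      sum(x$records$sv_type == "BND"), "breakends )\n")
  print(x$audit)
  invisible(x)
}
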