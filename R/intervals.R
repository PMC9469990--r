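#' Genomic intervals, 0-based half-open
#'
#' The package-internal coordinate convention is 0-based half-open
#' (`[start, end)`), the BED convention. VCF positions convert at the I/O
#' boundary via `pos_internal = pos_vcf - 1`. A `genomic_intervals` object is
#' a plain data frame with columns `chrom`, `start`, `end` (and any extra
#' columns the caller attaches), validated on construction.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors; `start < end` required, half-open.
#' @param ... further equal-length columns carried along.
#' @return A data frame of class `c("genomic_intervals", "data.frame")`.
#' @examples
#' genomic_intervals("chr1", 0, 10)
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1L && length(start) > 1L) chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start) || length(start) != length(end)) {
    stop("chrom, start, end must have equal length")
  }
  if (any(is.na(chrom) | !nzchar(chrom))) stop("chrom must be non-empty")
  if (any(!is.finite(start) | !is.finite(end))) stop("non-finite coordinates")
  if (any(start >= end)) stop("intervals must satisfy start < end (0-based half-open)")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   ..., stringsAsFactors = FALSE)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

# IRanges is 1-based closed; [start, end) maps to [start + 1, end].
.as_iranges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

#' Find subject intervals overlapping a query
#'
#' Half-open semantics: intervals that merely touch (`[0,10)` vs `[10,20)`)
#' do not overlap. Chromosomes are compared as exact strings.
#'
#' @param query a single-row `genomic_intervals` (or list with chrom/start/end).
#' @param subjects a `genomic_intervals` data frame.
#' @return Integer indices into `subjects` with nonzero intersection length,
#'   in subject order.
#' @export
overlap_query <- function(query, subjects) {
  stopifnot(nrow(subjects) >= 0)
  if (is.data.frame(query)) stopifnot(nrow(query) == 1)
  same <- which(subjects$chrom == query$chrom[1] | subjects$chrom == query$chrom)
  if (length(same) == 0) return(integer(0))
  q <- IRanges::IRanges(start = query$start[1] + 1L, end = query$end[1])
  hits <- IRanges::findOverlaps(q, .as_iranges(subjects[same, , drop = FALSE]))
  sort(same[S4Vectors::subjectHits(hits)])
}

#' Pairwise overlap hits between two interval sets
#'
#' @param queries,subjects `genomic_intervals` data frames.
#' @return data frame with columns `query`, `subject` (row indices).
#' @export
overlap_hits <- function(queries, subjects) {
  out <- list()
  for (ch in unique(queries$chrom)) {
    qi <- which(queries$chrom == ch)
    si <- which(subjects$chrom == ch)
    if (length(si) == 0) next
    h <- IRanges::findOverlaps(.as_iranges(queries[qi, , drop = FALSE]),
                               .as_iranges(subjects[si, , drop = FALSE]))
    if (length(h)) {
      out[[ch]] <- data.frame(query = qi[S4Vectors::queryHits(h)],
                              subject = si[S4Vectors::subjectHits(h)])
    }
  }
  if (length(out) == 0) return(data.frame(query = integer(0), subject = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$query, res$subject), , drop = FALSE]
}

#' Merge intervals into a disjoint sorted union
#'
#' Book-ended intervals (`[0,5)` + `[5,8)`) merge, matching the default of
#' bedtools merge. Output covers exactly the union of input bases.
#'
#' @param intervals `genomic_intervals` data frame.
#' @return `genomic_intervals` of disjoint intervals sorted by chrom, start.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals[, c("chrom", "start", "end")])
  parts <- lapply(split(seq_len(nrow(intervals)), intervals$chrom), function(idx) {
    r <- IRanges::reduce(.as_iranges(intervals[idx, , drop = FALSE]))
    data.frame(chrom = intervals$chrom[idx[1]],
               start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  out <- do.call(rbind, parts[order(names(parts))])
  rownames(out) <- NULL
  genomic_intervals(out$chrom, out$start, out$end)
}

#' Total intersection length between one interval and a set
#'
#' Overlapping subjects are merged first so double-covered bases count once.
#' @keywords internal
intersect_length <- function(query, subjects) {
  idx <- overlap_query(query, subjects)
  if (length(idx) == 0) return(0)
  m <- merge_intervals(subjects[idx, c("chrom", "start", "end")])
  sum(pmin(m$end, query$end[1]) - pmax(m$start, query$start[1]))
}

#' Read a BED file as genomic intervals
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#'
#' @param path BED file path (3+ columns, no header).
#' @return `genomic_intervals`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L,
                    GenomicRanges::end(gr))
}

#' Write genomic intervals as a BED file
#'
#' @param intervals `genomic_intervals`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(chrom = intervals$chrom,
                   start = format(intervals$start, scientific = FALSE, trim = TRUE),
                   end = format(intervals$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
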