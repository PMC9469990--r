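#' Classify copy-ratio segments by log2 thresholds
#'
#' A segment with log2 ratio at or above `gain_thresh` is a one-copy gain;
#' at or below `deep_loss_thresh` a two-copy loss. The band in between is
#' neutral unless a shallow-loss cutoff is supplied, in which case ratios
#' at or below it (but above the deep-loss cutoff) are one-copy losses.
#'
#' @param log2_ratio numeric vector of segment log2 copy ratios.
#' @param gain_thresh gain cutoff (default 0.4, inclusive).
#' @param deep_loss_thresh two-copy-loss cutoff (default -0.9, inclusive).
#' @param shallow_loss_thresh optional one-copy-loss cutoff (inclusive);
#'   `NULL` (default) disables the class.
#' @return character vector: `gain`, `neutral`, `loss_one_copy`,
#'   `loss_two_copy`.
#' @export
classify_segment <- function(log2_ratio, gain_thresh = 0.4,
                             deep_loss_thresh = -0.9,
                             shallow_loss_thresh = NULL) {
  stopifnot(gain_thresh > 0, deep_loss_thresh < 0)
  if (any(!is.finite(log2_ratio))) stop("non-finite log2 ratio")
  call <- rep("neutral", length(log2_ratio))
  call[log2_ratio >= gain_thresh] <- "gain"
  if (!is.null(shallow_loss_thresh)) {
    stopifnot(shallow_loss_thresh > deep_loss_thresh, shallow_loss_thresh < 0)
    call[log2_ratio <= shallow_loss_thresh] <- "loss_one_copy"
  }
  call[log2_ratio <= deep_loss_thresh] <- "loss_two_copy"
  call
}

#' Annotate gene overlap of classified segments
#'
#' Emits one call per (gene, sample, class) for every non-neutral segment
#' overlapping the gene body, with the fraction of the (merged) gene body
#' covered by same-class segments. The annotation is invariant to splitting
#' a segment into adjacent pieces with the same ratio. The gene body is the
#' overlap target; set `exonic_only = TRUE` to restrict to CDS intervals.
#'
#' @param segments `genomic_intervals` with `log2_ratio` (from
#'   [read_segments()]) and optionally a precomputed `call` column.
#' @param gene_model a `gene_model` from [read_gene_model()].
#' @param sample sample label attached to the calls.
#' @param gain_thresh,deep_loss_thresh,shallow_loss_thresh see
#'   [classify_segment()].
#' @param exonic_only overlap CDS intervals instead of gene bodies.
#' @return data frame with gene_id, sample, call, overlap_fraction.
#' @export
annotate_genes <- function(segments, gene_model, sample = NA_character_,
                           gain_thresh = 0.4, deep_loss_thresh = -0.9,
                           shallow_loss_thresh = NULL, exonic_only = FALSE) {
  if (!("call" %in% names(segments))) {
    segments$call <- classify_segment(segments$log2_ratio, gain_thresh,
                                      deep_loss_thresh, shallow_loss_thresh)
  }
  target <- if (exonic_only) gene_model$cds else gene_model$genes
  out <- list()
  for (gid in unique(target$gene_id)) {
    body <- merge_intervals(target[target$gene_id == gid, c("chrom", "start", "end")])
    body_len <- sum(body$end - body$start)
    for (cls in c("gain", "loss_one_copy", "loss_two_copy")) {
      seg <- segments[segments$call == cls, , drop = FALSE]
      if (nrow(seg) == 0) next
      cov <- 0
      for (b in seq_len(nrow(body))) {
        cov <- cov + intersect_length(body[b, , drop = FALSE],
                                      seg[, c("chrom", "start", "end")])
      }
      if (cov > 0) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gid, sample = sample, call = cls,
          overlap_fraction = cov / body_len, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(0), sample = character(0),
                      call = character(0), overlap_fraction = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene recurrence of copy-number calls across a cohort
#'
#' Fraction of samples carrying each call class per gene; a sample counts
#' once per gene per class however many same-class segments overlap it.
#'
#' @param gene_calls data frame from [annotate_genes()] pooled over samples.
#' @param n_samples cohort size (denominator).
#' @return data frame with gene_id, call, n_samples_altered, fraction.
#' @export
recurrence <- function(gene_calls, n_samples) {
  stopifnot(n_samples >= 1)
  u <- unique(gene_calls[, c("gene_id", "call", "sample")])
  agg <- stats::aggregate(sample ~ gene_id + call, data = u, FUN = length)
  names(agg)[names(agg) == "sample"] <- "n_samples_altered"
  agg$fraction <- agg$n_samples_altered / n_samples
  agg[order(agg$gene_id, agg$call), , drop = FALSE]
}
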