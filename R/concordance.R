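#' Restrict variant records to coding (CDS) regions
#'
#' SNVs are kept iff their position lies inside any CDS interval; interval
#' variants (indels with multi-base footprints, or rows carrying
#' `start`/`end` columns) are kept iff they intersect any CDS. The
#' operation is idempotent.
#'
#' @param records `variant_records` (chrom/pos/ref) or interval records.
#' @param gene_model a `gene_model` from [read_gene_model()].
#' @return the subset of `records` inside CDS.
#' @export
restrict_to_cds <- function(records, gene_model) {
  cds <- merge_intervals(gene_model$cds[, c("chrom", "start", "end")])
  if (nrow(records) == 0) return(records)
  if (all(c("start", "end") %in% names(records))) {
    iv <- genomic_intervals(records$chrom, records$start, records$end)
  } else {
    width <- if ("ref" %in% names(records)) pmax(nchar(records$ref), 1L) else 1L
    iv <- genomic_intervals(records$chrom, records$pos - 1L,
                            records$pos - 1L + width)
  }
  hit <- rep(FALSE, nrow(records))
  h <- overlap_hits(iv, cds)
  hit[unique(h$query)] <- TRUE
  records[hit, , drop = FALSE]
}

#' Exclude low-impact variants
#'
#' Removes records whose functional impact class is "low" (case
#' insensitive, e.g. from an upstream annotator). Records with no impact
#' annotation are retained and counted in an `unannotated` attribute.
#'
#' @param records data frame with an optional `impact` column.
#' @return filtered records with attribute `unannotated`.
#' @export
exclude_low_impact <- function(records) {
  if (!("impact" %in% names(records))) {
    attr(records, "unannotated") <- nrow(records)
    return(records)
  }
  imp <- toupper(records$impact)
  keep <- is.na(imp) | imp != "LOW"
  out <- records[keep, , drop = FALSE]
  attr(out, "unannotated") <- sum(is.na(imp[keep]))
  out
}

#' Per-gene recurrence within and across studies
#'
#' Counts, per gene, the fraction of samples affected in each study (a
#' sample counts once per gene however many hits it carries) and a pooled
#' fraction over all non-reference studies ("prior literature").
#'
#' @param harmonized named list of data frames, each with columns `gene_id`
#'   and `sample` (one per study).
#' @param n_samples named integer vector of per-study cohort sizes
#'   (defaults to the number of distinct samples seen per study).
#' @param reference_study study name excluded from the pooled literature
#'   fraction (e.g. this cohort); NULL pools everything.
#' @return data frame: gene_id, study, n_samples_affected, fraction, plus
#'   rows with study = "pooled_literature".
#' @export
gene_recurrence_across_studies <- function(harmonized, n_samples = NULL,
                                           reference_study = NULL) {
  stopifnot(length(harmonized) > 0, !is.null(names(harmonized)))
  if (is.null(n_samples)) {
    n_samples <- vapply(harmonized, function(d) length(unique(d$sample)), integer(1))
  }
  per_study <- do.call(rbind, lapply(names(harmonized), function(st) {
    u <- unique(harmonized[[st]][, c("gene_id", "sample")])
    agg <- stats::aggregate(sample ~ gene_id, data = u, FUN = length)
    data.frame(gene_id = agg$gene_id, study = st,
               n_samples_affected = agg$sample,
               fraction = agg$sample / n_samples[[st]],
               stringsAsFactors = FALSE)
  }))
  lit <- setdiff(names(harmonized), reference_study)
  if (length(lit)) {
    pooled <- do.call(rbind, lapply(lit, function(st) {
      cbind(unique(harmonized[[st]][, c("gene_id", "sample")]), study = st)
    }))
    u <- unique(pooled[, c("gene_id", "study", "sample")])
    agg <- stats::aggregate(sample ~ gene_id, data = u, FUN = length)
    per_study <- rbind(per_study, data.frame(
      gene_id = agg$gene_id, study = "pooled_literature",
      n_samples_affected = agg$sample,
      fraction = agg$sample / sum(n_samples[lit]),
      stringsAsFactors = FALSE))
  }
  rownames(per_study) <- NULL
  per_study[order(per_study$gene_id, per_study$study), , drop = FALSE]
}

#' Fraction of one call set confirmed in another
#'
#' Confirmation is by chromosome+position by default (the matching rule
#' used throughout the pipeline); `allele_exact = TRUE` additionally
#' requires ref and alt to agree. An empty `set_a` makes the fraction
#' undefined (NA).
#'
#' @param set_a,set_b `variant_records` harmonized to the same sample.
#' @param allele_exact require allele agreement (default FALSE).
#' @return list of class `concordance`: `fraction`, `n_confirmed`,
#'   `n_total`, `confirmed` (the confirmed subset of `set_a`).
#' @export
callset_concordance <- function(set_a, set_b, allele_exact = FALSE) {
  key <- function(x) {
    if (allele_exact) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":") else site_key(x)
  }
  if (nrow(set_a) == 0) {
    return(structure(list(fraction = NA_real_, n_confirmed = 0L, n_total = 0L,
                          confirmed = set_a), class = "concordance"))
  }
  hit <- key(set_a) %in% key(set_b)
  structure(list(fraction = mean(hit), n_confirmed = sum(hit),
                 n_total = nrow(set_a),
                 confirmed = set_a[hit, , drop = FALSE]),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance: %d / %d confirmed (%.1f%%)\n",
              x$n_confirmed, x$n_total, 100 * x$fraction))
  invisible(x)
}
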