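#' Infer sample sex from X/autosome coverage
#'
#' The ratio of mean chromosome X depth to the unweighted mean of
#' per-autosome mean depths classifies the sample: ratios in [0.3, 0.7]
#' are male, [0.8, 1.2] female (endpoints inclusive), anything else
#' indeterminate.
#'
#' @param coverage named numeric vector of per-chromosome mean depths, or a
#'   data frame with columns `chrom` and `mean_depth`.
#' @param x_chrom name of the X chromosome (default `"chrX"`).
#' @param male_range,female_range inclusive classification bins.
#' @return list of class `sex_call` with `sex` (male / female /
#'   indeterminate) and `ratio`.
#' @export
infer_sex <- function(coverage, x_chrom = "chrX",
                      male_range = c(0.3, 0.7), female_range = c(0.8, 1.2)) {
  if (is.data.frame(coverage)) {
    coverage <- stats::setNames(coverage$mean_depth, coverage$chrom)
  }
  if (!(x_chrom %in% names(coverage))) stop("X chromosome not in coverage table")
  auto <- coverage[setdiff(names(coverage), x_chrom)]
  if (length(auto) == 0) stop("no autosomes in coverage table")
  if (any(coverage < 0)) stop("negative depth")
  if (mean(auto) == 0) stop("zero autosomal depth")
  ratio <- unname(coverage[x_chrom] / mean(auto))
  sex <- if (ratio >= male_range[1] && ratio <= male_range[2]) "male"
         else if (ratio >= female_range[1] && ratio <= female_range[2]) "female"
         else "indeterminate"
  structure(list(sex = sex, ratio = ratio), class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("sex: %s (X/autosome coverage ratio %.3f)\n", x$sex, x$ratio))
  invisible(x)
}

#' Mutational burden in mutations per megabase
#'
#' Total mutation count divided by the combined size of the counted
#' chromosomes in Mb. The chromosomes counted should be the same contig
#' allow-list used during variant filtering.
#'
#' @param n_mutations non-negative mutation count.
#' @param chromosome_sizes named numeric vector of chromosome lengths in bp.
#' @return mutations per Mb.
#' @export
mutational_burden <- function(n_mutations, chromosome_sizes) {
  if (length(chromosome_sizes) == 0) stop("empty chromosome size table")
  if (any(chromosome_sizes <= 0)) stop("chromosome sizes must be positive")
  if (n_mutations < 0) stop("negative mutation count")
  n_mutations / (sum(chromosome_sizes) / 1e6)
}

#' Inter-mutation distance series for rainfall analysis
#'
#' Per chromosome, positions are sorted, duplicates collapsed, and the
#' distances between consecutive mutations computed (n-1 per chromosome).
#'
#' @param records `variant_records` (or data frame with chrom, pos).
#' @return list of class `rainfall_series`: per chromosome, a list with
#'   `positions` and `distances`.
#' @export
rainfall <- function(records) {
  out <- lapply(split(records$pos, records$chrom), function(p) {
    p <- sort(unique(p))
    list(positions = p,
         distances = if (length(p) > 1) diff(p) else numeric(0))
  })
  structure(out, class = "rainfall_series")
}

#' Detect kataegis-like hypermutation clusters
#'
#' Reports maximal runs of at least `min_run` consecutive mutations whose
#' mean inter-mutation distance does not exceed `max_mean_dist`.
#' Overlapping qualifying windows are unioned, so reported regions are
#' disjoint and maximal; each spans first to last mutation of its run
#' (half-open interval, so the span in bp is `end - start`).
#'
#' @param series a `rainfall_series` from [rainfall()].
#' @param min_run minimum number of mutations in a run (default 6).
#' @param max_mean_dist maximum mean spacing in bp (default 1000).
#' @return `genomic_intervals` of hypermutated regions with an
#'   `n_mutations` column; zero rows when none found.
#' @export
detect_kataegis <- function(series, min_run = 6, max_mean_dist = 1000) {
  regions <- list()
  for (ch in names(series)) {
    p <- series[[ch]]$positions
    n <- length(p)
    if (n < min_run) next
    # mark inter-mutation gaps covered by a qualifying window; overlapping
    # windows share a gap, merely index-adjacent runs do not, so maximal
    # gap runs give disjoint maximal regions
    covered <- rep(FALSE, n - 1)
    cum <- c(0, cumsum(diff(p)))  # cum[j] - cum[i] = p[j] - p[i]
    for (i in seq_len(n - min_run + 1)) {
      for (j in (i + min_run - 1):n) {
        # mean gap over window [i, j] = (p[j] - p[i]) / (j - i)
        if ((cum[j] - cum[i]) / (j - i) <= max_mean_dist) {
          covered[i:(j - 1)] <- TRUE
        }
      }
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_run - 1)) {
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = p[starts[k]], end = p[ends[k] + 1],
        n_mutations = r$lengths[k] + 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(regions) == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_mutations = integer(0))
    class(out) <- c("genomic_intervals", "data.frame")
    return(out)
  }
  df <- do.call(rbind, regions)
  genomic_intervals(df$chrom, df$start, df$end, n_mutations = df$n_mutations)
}

#' Per-sample genome summary
#'
#' Convenience wrapper combining sex inference, mutational burden and
#' kataegis detection for one sample.
#'
#' @param records filtered `variant_records` for the sample.
#' @param coverage per-chromosome mean depths (see [infer_sex()]).
#' @param chromosome_sizes named vector of contig lengths in bp.
#' @param x_chrom X chromosome name.
#' @param ... passed to [detect_kataegis()].
#' @return list of class `genome_summary` with `sex`, `burden_per_mb`,
#'   `n_mutations`, `kataegis`.
#' @export
summarize_genome <- function(records, coverage, chromosome_sizes,
                             x_chrom = "chrX", ...) {
  structure(list(
    sex = infer_sex(coverage, x_chrom = x_chrom),
    n_mutations = nrow(records),
    burden_per_mb = mutational_burden(nrow(records), chromosome_sizes),
    kataegis = detect_kataegis(rainfall(records), ...)),
    class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("genome summary: %d mutations, %.2f mut/Mb, sex %s (ratio %.2f), %d kataegis region(s)\n",
              x$n_mutations, x$burden_per_mb, x$sex$sex, x$sex$ratio,
              nrow(x$kataegis)))
  invisible(x)
}
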