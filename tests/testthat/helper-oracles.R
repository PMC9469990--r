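# Independent naive oracles and tiny fixture builders shared by the tests.
# These deliberately use brute-force algorithms distinct from the package's
# implementations.

rec <- function(chrom, pos, ref = "A", alt = "T", filter = "", af = 0.5,
                dp = 30, alt_depth = 15, caller = "mutect2",
                sample = "tumorT") {
  variant_records(chrom, pos, ref, alt, filter = filter, af = af, dp = dp,
                  alt_depth = alt_depth, caller = caller, sample = sample)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000) {
  s <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(50, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), s, s + w)
}

# O(n^2) overlap oracle for 0-based half-open intervals
naive_overlap_pairs <- function(queries, subjects) {
  out <- list()
  for (i in seq_len(nrow(queries))) {
    for (j in seq_len(nrow(subjects))) {
      if (queries$chrom[i] == subjects$chrom[j] &&
          max(queries$start[i], subjects$start[j]) <
          min(queries$end[i], subjects$end[j])) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

# per-base bitmap union size
naive_union_bases <- function(intervals) {
  total <- 0
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    bases <- logical(max(iv$end))
    for (i in seq_len(nrow(iv))) bases[(iv$start[i] + 1):iv$end[i]] <- TRUE
    total <- total + sum(bases)
  }
  total
}

# literal window-scan kataegis oracle: every window of >= min_run mutations
# with mean gap <= max_mean_dist marks the gaps it spans; maximal runs of
# marked gaps become regions (overlapping windows share a gap)
naive_kataegis <- function(positions, min_run = 6, max_mean_dist = 1000) {
  p <- sort(unique(positions))
  n <- length(p)
  if (n < min_run) return(data.frame(start = numeric(0), end = numeric(0)))
  marked <- rep(FALSE, n - 1)
  for (i in 1:n) for (j in i:n) {
    if (j - i + 1 >= min_run && mean(diff(p[i:j])) <= max_mean_dist) {
      marked[i:(j - 1)] <- TRUE
    }
  }
  regions <- list()
  i <- 1
  while (i <= n - 1) {
    if (marked[i]) {
      j <- i
      while (j < n - 1 && marked[j + 1]) j <- j + 1
      if (j - i + 2 >= min_run) {
        regions[[length(regions) + 1L]] <- c(p[i], p[j + 1], j - i + 2)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(regions)) return(data.frame(start = numeric(0), end = numeric(0),
                                          n = integer(0)))
  m <- do.call(rbind, regions)
  data.frame(start = m[, 1], end = m[, 2], n = m[, 3])
}

# small randomized SV fixture with mate-paired BNDs for closure properties
random_sv_fixture <- function(n_pairs = 8, n_del = 5, sample = "tumorT") {
  ids1 <- sprintf("bnd_%02d_1", seq_len(n_pairs))
  ids2 <- sprintf("bnd_%02d_2", seq_len(n_pairs))
  posa <- sample.int(9e5, n_pairs)
  posb <- sample.int(9e5, n_pairs)
  bnd <- rbind(
    sv_records(ids1, "BND", "chr1", posa, "chr2", posb,
               pr = sample(c(10L, 20L), n_pairs, TRUE),
               imprecise = sample(c(TRUE, FALSE), n_pairs, TRUE, prob = c(.2, .8)),
               filter = sample(c("", "MinQual"), n_pairs, TRUE, prob = c(.8, .2)),
               mate_id = ids2, sample = sample),
    sv_records(ids2, "BND", "chr2", posb, "chr1", posa,
               pr = sample(c(10L, 20L), n_pairs, TRUE),
               imprecise = sample(c(TRUE, FALSE), n_pairs, TRUE, prob = c(.2, .8)),
               filter = sample(c("", "MinQual"), n_pairs, TRUE, prob = c(.8, .2)),
               mate_id = ids1, sample = sample))
  del <- sv_records(sprintf("del_%02d", seq_len(n_del)), "DEL", "chr3",
                    pos1 = 20000 * seq_len(n_del),
                    pos2 = 20000 * seq_len(n_del) + 5000, svlen = 5000,
                    pr = sample(c(10L, 20L), n_del, TRUE), sample = sample)
  out <- rbind(bnd, del)
  class(out) <- c("sv_records", "data.frame")
  out
}

# partition signature for comparing clusterings up to relabeling
cluster_signature <- function(merged) {
  parts <- split(sort(merged$sv_id), merged$cluster)
  sort(vapply(parts, paste, "", collapse = "|"))
}
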