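#' Default synthetic-cohort configuration
#'
#' The defaults define the study conditions every stage is exercised
#' under: 2 tumor cell lines against 23 unmatched normal germline samples,
#' 250 planted SNV/indel truth entries per tumor distributed over classes
#' that straddle every filtering rule (support grids around AF 0.05 /
#' DP 10 / 3 alt reads, caller-private calls, same-position
#' different-allele representations, rescue-eligible flagged records,
#' panel-of-normals and germline-resource overlaps, regenotyping leaks,
#' off-allow-list contigs), plus structural variants with support around
#' the PR/SR 15 rule and mate-paired breakends, copy-ratio segments at the
#' classification boundaries, coverage ratios inside and outside the sex
#' bins, and a drifted three-breed genotype panel.
#'
#' @param n_tumors,n_normals cohort sizes.
#' @param snv_counts named integer vector of per-tumor planted SNV class
#'   sizes (must keep its names; the default sums to 250).
#' @param contig_length length of each toy chromosome in bp.
#' @param n_autosomes autosomes `chr1..chrN`; `chrX`, `chrM` and
#'   `chrUn_1` are always added, the latter two off the allow-list.
#' @param breed_panel list with `n_breeds`, `n_per_breed`, `n_markers`,
#'   `missing_rate`, `drift`.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumors = 2, n_normals = 23,
                          snv_counts = c(somatic_eligible = 50,
                                         somatic_rescued_mutect2 = 10,
                                         somatic_rescued_platypus = 10,
                                         somatic_lowsupport = 30,
                                         private_mutect2 = 20,
                                         private_platypus = 20,
                                         germline_resource = 40,
                                         germline_pon = 30,
                                         artifact_flag = 20,
                                         germline_leak = 15,
                                         excluded_contig = 5),
                          contig_length = 1e6, n_autosomes = 5,
                          breed_panel = list(n_breeds = 3, n_per_breed = 15,
                                             n_markers = 400,
                                             missing_rate = 0.02,
                                             drift = 0.15)) {
  stopifnot(n_tumors >= 1, n_normals >= 1, all(snv_counts >= 0))
  autosomes <- paste0("chr", seq_len(n_autosomes))
  structure(list(n_tumors = n_tumors, n_normals = n_normals,
                 snv_counts = snv_counts, contig_length = contig_length,
                 autosomes = autosomes,
                 allow_contigs = c(autosomes, "chrX"),
                 breed_panel = breed_panel),
            class = "cohort_config")
}

# Random toy reference: one DNAString per contig, seeded by the caller.
.simulate_reference <- function(contigs) {
  seqs <- vapply(contigs, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

.ref_base <- function(reference, chrom, pos, len = 1L) {
  as.character(Biostrings::subseq(reference[[chrom]], pos, pos + len - 1L))
}

.other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
}

# Support-value grids straddling the AF/DP/alt thresholds.
.good_support <- function(n) {
  combos <- list(c(60, 3), c(10, 3), c(20, 3), c(40, 6), c(80, 40), c(10, 5))
  picks <- combos[((seq_len(n) - 1) %% length(combos)) + 1]
  dp <- vapply(picks, `[`, numeric(1), 1)
  alt <- vapply(picks, `[`, numeric(1), 2)
  data.frame(dp = dp, alt = alt, af = alt / dp)
}

.low_support <- function(n) {
  combos <- list(c(9, 4), c(40, 2), c(100, 4), c(9, 2), c(50, 2))
  picks <- combos[((seq_len(n) - 1) %% length(combos)) + 1]
  dp <- vapply(picks, `[`, numeric(1), 1)
  alt <- vapply(picks, `[`, numeric(1), 2)
  data.frame(dp = dp, alt = alt, af = alt / dp)
}

#' Simulate a full desk-scale cohort with known truth
#'
#' Generates, deterministically from one seed, everything the pipeline
#' stages consume: two tumor SNV call sets per tumor in distinct caller
#' dialects, normal call sets, germline resources, a withdrawn-sites list,
#' regenotyping evidence, Manta-style SV call sets with mate-paired
#' breakends, a centromere window set, copy-ratio segments at the
#' classification boundaries, per-chromosome coverage, a toy reference
#' sequence and gene annotation, and a drifted breed genotype panel with
#' admixed query samples. Every emitted record traces to one truth entry.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the same config + seed reproduce the bundle
#'   exactly.
#' @return list of class `synthetic_cohort`; see elements `tumors`,
#'   `normals`, `germline_resources`, `removed_sites`, `evidence`, `sv`,
#'   `segments`, `coverage`, `reference`, `gene_model`, `ancestry`,
#'   `truth`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  contigs <- stats::setNames(
    rep(config$contig_length, length(config$allow_contigs) + 2),
    c(config$allow_contigs, "chrM", "chrUn_1"))
  reference <- .simulate_reference(contigs)

  ## ---- position pool: 10 bp grid per contig keeps footprints disjoint
  n_pool <- 40 * sum(config$snv_counts) # generous
  pool_chrom <- sample(config$allow_contigs, n_pool, replace = TRUE)
  pool <- do.call(rbind, lapply(split(seq_len(n_pool), pool_chrom), function(i) {
    data.frame(chrom = pool_chrom[i[1]],
               pos = 10L * sample.int(config$contig_length %/% 10L - 2L,
                                      length(i)),
               stringsAsFactors = FALSE)
  }))
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  rownames(pool) <- NULL
  pool_next <- 0L
  take_sites <- function(n, contig = NULL) {
    if (is.null(contig)) {
      out <- pool[pool_next + seq_len(n), , drop = FALSE]
      pool_next <<- pool_next + n
    } else {
      out <- data.frame(chrom = contig,
                        pos = 10L * sample.int(config$contig_length %/% 10L - 2L, n))
    }
    rownames(out) <- NULL
    out
  }

  counts <- config$snv_counts
  tumor_names <- paste0("tumor", seq_len(config$n_tumors))
  normal_names <- paste0("normal", sprintf("%02d", seq_len(config$n_normals)))

  tumors <- list()
  truth_all <- list()
  resource_rows <- list()
  removed_rows <- list()
  pon_rows <- list()
  evidence_rows <- list()

  for (tn in tumor_names) {
    cls <- rep(names(counts), counts)
    n_rec <- length(cls)
    sites <- take_sites(n_rec)
    # off-allow-list records live on chrM / chrUn_1
    excl <- cls == "excluded_contig"
    if (any(excl)) {
      sites$chrom[excl] <- rep(c("chrM", "chrUn_1"), length.out = sum(excl))
    }
    # alleles from the reference; a slice of eligible somatics are indels
    ref <- vapply(seq_len(n_rec), function(i) .ref_base(reference, sites$chrom[i], sites$pos[i]), "")
    alt <- .other_base(ref)
    is_indel <- rep(FALSE, n_rec)
    el <- which(cls == "somatic_eligible")
    ind <- el[seq_len(min(5, length(el)))]
    for (i in ind) {
      ref[i] <- .ref_base(reference, sites$chrom[i], sites$pos[i], 3L)
      alt[i] <- substr(ref[i], 1, 1)       # 2 bp deletion
      is_indel[i] <- TRUE
    }
    gr <- which(cls == "germline_resource")
    gr_ind <- gr[seq_len(min(5, length(gr)))]
    for (i in gr_ind) {
      ref[i] <- .ref_base(reference, sites$chrom[i], sites$pos[i], 3L)
      alt[i] <- substr(ref[i], 1, 1)
      is_indel[i] <- TRUE
    }

    good <- .good_support(n_rec)
    low_idx <- cls == "somatic_lowsupport"
    good[low_idx, ] <- .low_support(sum(low_idx))

    m2_filter <- rep("", n_rec)
    pl_filter <- rep("", n_rec)
    m2_filter[cls == "somatic_rescued_mutect2"] <- "germline"
    pl_filter[cls == "somatic_rescued_platypus"] <- "alleleBias"
    art <- which(cls == "artifact_flag")
    half <- art[seq_len(length(art) %/% 2)]
    m2_filter[half] <- sample(c("weak_evidence", "germline;weak_evidence"),
                              length(half), replace = TRUE)
    pl_filter[setdiff(art, half)] <- "alleleBias"

    in_m2 <- cls != "private_platypus"
    in_pl <- cls != "private_mutect2"
    # same-position different-allele caller discordance for some somatics
    pl_alt <- alt
    disc <- el[setdiff(seq_len(min(15, length(el))), seq_len(5))]
    pl_alt[disc] <- .other_base(ref[disc])

    m2 <- variant_records(sites$chrom[in_m2], sites$pos[in_m2], ref[in_m2],
                          alt[in_m2], filter = m2_filter[in_m2],
                          af = good$af[in_m2], dp = good$dp[in_m2],
                          alt_depth = good$alt[in_m2],
                          caller = "mutect2", sample = tn)
    pl <- variant_records(sites$chrom[in_pl], sites$pos[in_pl], ref[in_pl],
                          pl_alt[in_pl], filter = pl_filter[in_pl],
                          af = good$af[in_pl], dp = good$dp[in_pl],
                          alt_depth = good$alt[in_pl],
                          caller = "platypus", sample = tn)

    eligible <- cls %in% c("somatic_eligible", "somatic_rescued_mutect2",
                           "somatic_rescued_platypus")
    truth <- data.frame(sample = tn, chrom = sites$chrom, pos = sites$pos,
                        ref = ref, alt = alt, class = cls,
                        eligible = eligible, stringsAsFactors = FALSE)
    truth_all[[tn]] <- truth
    tumors[[tn]] <- list(mutect2 = m2, platypus = pl, truth = truth)

    # resources: round-robin over the three germline resources, with the
    # indel representations shifted by 1 bp (footprint overlap still holds)
    if (length(gr)) {
      r_pos <- sites$pos[gr]
      r_ref <- ref[gr]
      shift <- gr %in% gr_ind
      r_pos[shift] <- r_pos[shift] + 1L
      for (k in which(shift)) {
        r_ref[k] <- .ref_base(reference, sites$chrom[gr[k]], r_pos[k], 3L)
      }
      res_name <- c("germline_reference", "broad_snps", "axelsson_snps")[
        ((seq_along(gr) - 1) %% 3) + 1]
      resource_rows[[tn]] <- data.frame(
        resource = res_name, chrom = sites$chrom[gr], pos = r_pos,
        ref = r_ref, alt = .other_base(substr(r_ref, 1, 1)),
        stringsAsFactors = FALSE)
    }
    resc <- cls %in% c("somatic_rescued_mutect2", "somatic_rescued_platypus")
    removed_rows[[tn]] <- data.frame(chrom = sites$chrom[resc],
                                     pos = sites$pos[resc],
                                     ref = ref[resc], alt = alt[resc],
                                     stringsAsFactors = FALSE)
    pon_cls <- cls == "germline_pon"
    pon_rows[[tn]] <- data.frame(chrom = sites$chrom[pon_cls],
                                 pos = sites$pos[pon_cls],
                                 ref = ref[pon_cls], alt = alt[pon_cls],
                                 stringsAsFactors = FALSE)

    # regenotyping evidence: every planted site x every normal; leaks get
    # support in 1-3 normals
    leak <- cls == "germline_leak"
    sup <- matrix(FALSE, n_rec, config$n_normals)
    for (i in which(leak)) {
      sup[i, sample.int(config$n_normals, sample(1:3, 1))] <- TRUE
    }
    evidence_rows[[tn]] <- data.frame(
      chrom = rep(sites$chrom, config$n_normals),
      pos = rep(sites$pos, config$n_normals),
      sample = rep(normal_names, each = n_rec),
      support = as.vector(sup), stringsAsFactors = FALSE)
  }

  ## ---- normals: assigned PON sites plus private sites
  pon_sites_df <- unique(do.call(rbind, pon_rows))
  normals <- list()
  assign_n <- lapply(seq_len(nrow(pon_sites_df)),
                     function(i) sample.int(config$n_normals, sample(1:3, 1)))
  for (j in seq_len(config$n_normals)) {
    mine <- which(vapply(assign_n, function(a) j %in% a, logical(1)))
    priv <- take_sites(5)
    priv_ref <- vapply(seq_len(nrow(priv)), function(i)
      .ref_base(reference, priv$chrom[i], priv$pos[i]), "")
    chrom <- c(pon_sites_df$chrom[mine], priv$chrom)
    pos <- c(pon_sites_df$pos[mine], priv$pos)
    ref <- c(pon_sites_df$ref[mine], priv_ref)
    alt <- .other_base(substr(ref, 1, 1))
    normals[[normal_names[j]]] <- variant_records(
      chrom, pos, ref, alt, filter = "", af = 0.5, dp = 30, alt_depth = 15,
      caller = "platypus", sample = normal_names[j])
  }
  # guarantee every PON site is carried by at least one normal (assignment
  # above already does; keep the invariant explicit)
  stopifnot(all(vapply(assign_n, length, integer(1)) >= 1))

  resources_df <- do.call(rbind, resource_rows)
  germline_resources <- lapply(split(resources_df, resources_df$resource),
                               function(d) {
    variant_records(d$chrom, d$pos, d$ref, d$alt, filter = "",
                    af = 0.5, dp = 30, alt_depth = 15,
                    caller = "mutect2", sample = "resource")
  })
  removed_df <- do.call(rbind, removed_rows)
  removed_sites <- variant_records(removed_df$chrom, removed_df$pos,
                                   removed_df$ref, removed_df$alt,
                                   caller = "mutect2", sample = "withdrawn")
  evidence <- do.call(rbind, evidence_rows)
  class(evidence) <- c("normal_evidence", "data.frame")

  sv <- .simulate_sv_cohort(config, tumor_names, normal_names)
  segments <- .simulate_segments(config, tumor_names)
  coverage <- .simulate_coverage(config, tumor_names)
  gene_model <- .toy_gene_model(segments)
  ancestry <- .simulate_ancestry_bundle(config$breed_panel)

  structure(list(config = config, seed = seed, contigs = contigs,
                 reference = reference, tumors = tumors, normals = normals,
                 germline_resources = germline_resources,
                 removed_sites = removed_sites, evidence = evidence,
                 sv = sv, segments = segments, coverage = coverage,
                 gene_model = gene_model, ancestry = ancestry,
                 truth = do.call(rbind, truth_all)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$tumors), "tumors,", length(x$normals),
      "normals,", nrow(x$truth), "planted SNV/indel truth entries\n")
  invisible(x)
}

# SV cohort: breakpoint blocks on a 20 kb grid keep unrelated SVs apart.
.simulate_sv_cohort <- function(config, tumor_names, normal_names) {
  block <- 20000L
  # breakpoint blocks stay below 820 kb; centromere windows sit at 900 kb so
  # only deliberately placed records can touch them
  n_blocks <- 40L
  used <- 0L
  take_block <- function(n) {
    out <- used + seq_len(n)
    used <<- used + n
    stopifnot(max(out) <= n_blocks * length(config$autosomes))
    data.frame(chrom = config$autosomes[(out - 1) %% length(config$autosomes) + 1],
               pos = block * ((out - 1) %/% length(config$autosomes) + 1L) +
                 sample.int(2000L, n))
  }
  cen_start <- 900000
  centromeres <- genomic_intervals(chrom = config$autosomes,
                                   start = rep(cen_start, length(config$autosomes)),
                                   end = rep(cen_start + 5000, length(config$autosomes)))
  tumors <- list(); normals_sv <- list(); truth <- list(); evid <- list()
  normal_priv <- take_block(length(normal_names))
  germ_source <- list()
  for (tn in tumor_names) {
    mk <- function(n, type, prefix, len = 5000L, pr = 30L, sr = 0L,
                   imprecise = FALSE, filter = "", at = NULL) {
      b <- if (is.null(at)) take_block(n) else at
      sv_records(sv_id = sprintf("%s_%s_%02d", tn, prefix, seq_len(n)),
                 sv_type = type, chrom1 = b$chrom, pos1 = b$pos,
                 chrom2 = b$chrom, pos2 = b$pos + len, svlen = len,
                 pr = pr, sr = sr, imprecise = imprecise, filter = filter,
                 sample = tn)
    }
    som <- rbind(mk(4, "DEL", "som_del"),
                 mk(4, "DUP", "som_dup", sr = 20L, pr = 0L),
                 mk(4, "INV", "som_inv", pr = 15L))
    # mate-paired translocation breakends
    bnd_pair <- function(n, prefix, pr = 25L) {
      a <- take_block(n); b <- take_block(n)
      ids1 <- sprintf("%s_%s_%02d_1", tn, prefix, seq_len(n))
      ids2 <- sprintf("%s_%s_%02d_2", tn, prefix, seq_len(n))
      rbind(sv_records(ids1, "BND", a$chrom, a$pos, b$chrom, b$pos,
                       pr = pr, mate_id = ids2, sample = tn),
            sv_records(ids2, "BND", b$chrom, b$pos, a$chrom, a$pos,
                       pr = pr, mate_id = ids1, sample = tn))
    }
    bnd_ok <- bnd_pair(3, "som_bnd")
    bnd_orphan <- bnd_pair(3, "orph_bnd")
    # one mate of each orphan pair fails the support filter
    fail_ids <- sprintf("%s_orph_bnd_%02d_2", tn, 1:3)
    bnd_orphan$pr[bnd_orphan$sv_id %in% fail_ids] <- 14L
    low <- mk(6, "DEL", "low", pr = 14L, sr = 14L)
    impr <- mk(4, "DEL", "impr", pr = 40L, imprecise = TRUE)
    nonp <- mk(3, "DUP", "nonpass", filter = "MaxDepth")
    leak <- mk(4, "DEL", "leak")
    cen_at <- data.frame(chrom = config$autosomes[1:2],
                         pos = cen_start - 1000L)
    cen <- mk(2, "DEL", "cen", len = 4000L, at = cen_at)
    # germline SVs sit 150 bp from a normal-sample counterpart
    gblocks <- take_block(8)
    germ <- sv_records(sprintf("%s_germ_%02d", tn, 1:8), "DEL",
                       gblocks$chrom, gblocks$pos, gblocks$chrom,
                       gblocks$pos + 5000L, svlen = 5000L, pr = 30L,
                       sample = tn)
    germ_source[[tn]] <- gblocks
    tum <- rbind(som, bnd_ok, bnd_orphan, low, impr, nonp, leak, cen, germ)
    class(tum) <- c("sv_records", "data.frame")
    tumors[[tn]] <- tum
    surviving_bnd <- bnd_ok$sv_id
    truth[[tn]] <- data.frame(
      sv_id = tum$sv_id, sample = tn,
      class = c(rep("somatic_pass", nrow(som)),
                rep("somatic_bnd", nrow(bnd_ok)),
                rep("orphan_bnd", nrow(bnd_orphan)),
                rep("low_support", nrow(low)),
                rep("imprecise", nrow(impr)),
                rep("non_pass", nrow(nonp)),
                rep("regenotype_leak", nrow(leak)),
                rep("centromeric", nrow(cen)),
                rep("germline_sv", nrow(germ))),
      stringsAsFactors = FALSE)
    truth[[tn]]$eligible <- truth[[tn]]$class %in%
      c("somatic_pass", "somatic_bnd", "centromeric")
    evid[[tn]] <- data.frame(
      sv_id = rep(tum$sv_id, each = 3),
      sample = rep(normal_names[1:3], nrow(tum)),
      support = rep(grepl("_leak_", tum$sv_id), each = 3) &
        rep(c(TRUE, FALSE, FALSE), nrow(tum)),
      stringsAsFactors = FALSE)
  }
  for (j in seq_along(normal_names)) {
    rows <- do.call(rbind, lapply(germ_source, function(g) {
      g[sample.int(nrow(g), 3), , drop = FALSE]   # each normal sees 3 per tumor
    }))
    priv <- normal_priv[j, , drop = FALSE]
    normals_sv[[normal_names[j]]] <- sv_records(
      sv_id = sprintf("%s_sv_%02d", normal_names[j], seq_len(nrow(rows) + 1)),
      sv_type = "DEL",
      chrom1 = c(rows$chrom, priv$chrom),
      pos1 = c(rows$pos + 150L, priv$pos),
      chrom2 = c(rows$chrom, priv$chrom),
      pos2 = c(rows$pos + 150L + 5000L, priv$pos + 5000L),
      svlen = 5000L, pr = 20L, sample = normal_names[j])
  }
  # every planted germline SV must appear in at least one normal
  for (tn in tumor_names) {
    g <- germ_source[[tn]]
    covered <- vapply(seq_len(nrow(g)), function(i) {
      any(vapply(normals_sv, function(nsv) {
        any(nsv$chrom1 == g$chrom[i] & abs(nsv$pos1 - (g$pos[i] + 150L)) < 1)
      }, logical(1)))
    }, logical(1))
    if (!all(covered)) {
      j <- which(!covered)
      first <- normals_sv[[1]]
      add <- sv_records(sprintf("normal01_fix_%s_%02d", tn, j), "DEL",
                        g$chrom[j], g$pos[j] + 150L, g$chrom[j],
                        g$pos[j] + 150L + 5000L, svlen = 5000L, pr = 20L,
                        sample = normal_names[1])
      normals_sv[[1]] <- {x <- rbind(first, add); class(x) <- class(first); x}
    }
  }
  list(tumors = tumors, normals = normals_sv, centromeres = centromeres,
       evidence = do.call(rbind, evid), truth = do.call(rbind, truth))
}

# Copy-ratio segments covering both classification boundaries.
.simulate_segments <- function(config, tumor_names) {
  ratios <- c(-1.2, -0.9, -0.3, 0.0, 0.4, 0.9)
  out <- list()
  for (tn in tumor_names) {
    r <- sample(rep(ratios, 2))   # 12 segments of 80 kb on chr1
    seg <- genomic_intervals(chrom = "chr1",
                             start = (seq_along(r) - 1) * 80000,
                             end = seq_along(r) * 80000,
                             log2_ratio = r)
    seg$truth_call <- classify_segment(seg$log2_ratio)
    out[[tn]] <- seg
  }
  out
}

# Per-chromosome mean depths: tumor1 male (ratio 0.5), tumor2 female (1.0),
# further tumors alternate, with one indeterminate ratio available via truth.
.simulate_coverage <- function(config, tumor_names) {
  out <- list()
  sexes <- rep(c("male", "female"), length.out = length(tumor_names))
  for (i in seq_along(tumor_names)) {
    base <- stats::runif(1, 25, 60)
    auto <- stats::setNames(base + stats::rnorm(length(config$autosomes), 0, 0.3),
                            config$autosomes)
    ratio <- if (sexes[i] == "male") 0.5 else 1.0
    depths <- c(auto, chrX = unname(mean(auto) * ratio))
    out[[tumor_names[i]]] <- list(depths = depths, sex_truth = sexes[i])
  }
  out
}

# Six genes of 10 kb placed inside successive chr1 segments, two 2 kb CDS
# chunks each.
.toy_gene_model <- function(segments) {
  starts <- (seq_len(6) - 1) * 80000 + 30000
  genes <- genomic_intervals("chr1", starts, starts + 10000,
                             gene_id = paste0("GENE", 1:6))
  cds <- genomic_intervals("chr1",
                           c(starts + 1000, starts + 6000),
                           c(starts + 3000, starts + 8000),
                           gene_id = rep(paste0("GENE", 1:6), 2))
  structure(list(genes = genes, cds = cds), class = "gene_model")
}

#' Simulate a drifted breed allele-frequency panel
#'
#' Breed frequencies drift from a common ancestral frequency by a
#' beta-distributed perturbation whose spread is set by `drift`
#' (larger = more differentiation between breeds).
#'
#' @param n_breeds,n_markers panel dimensions.
#' @param drift drift intensity in (0, 1).
#' @return matrix breeds x markers of allele frequencies in [0.02, 0.98].
#' @export
simulate_breed_freqs <- function(n_breeds = 3, n_markers = 400, drift = 0.15) {
  anc <- stats::runif(n_markers, 0.05, 0.95)
  shape <- (1 - drift) / drift
  f <- t(vapply(seq_len(n_breeds), function(k) {
    stats::rbeta(n_markers, anc * shape, (1 - anc) * shape)
  }, numeric(n_markers)))
  f <- pmin(pmax(f, 0.02), 0.98)
  rownames(f) <- paste0("breed", LETTERS[seq_len(n_breeds)])
  f
}

#' Simulate admixed genotypes from panel frequencies
#'
#' Each marker's dosage is drawn as Binomial(2, sum_k q_k f_kj); a
#' missingness rate masks genotypes at random.
#'
#' @param panel_freqs breeds x markers frequency matrix.
#' @param q ancestry simplex (one sample) or samples x breeds matrix.
#' @param missing_rate per-genotype missingness probability.
#' @param seed optional integer seed.
#' @return a `genotype_matrix` (markers placed 2.5 kb apart on chr1).
#' @export
simulate_admixed_genotypes <- function(panel_freqs, q, missing_rate = 0,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  stopifnot(ncol(q) == nrow(panel_freqs),
            all(abs(rowSums(q) - 1) < 1e-8), all(q >= 0))
  J <- ncol(panel_freqs)
  geno <- t(apply(q, 1, function(qi) {
    p <- as.vector(qi %*% panel_freqs)
    g <- stats::rbinom(J, 2, p)
    if (missing_rate > 0) g[stats::runif(J) < missing_rate] <- NA
    g
  }))
  genotype_matrix(geno, chrom = rep("chr1", J), pos = 2500 * seq_len(J))
}

# Reference panel genotypes + admixed queries with known q.
.simulate_ancestry_bundle <- function(bp) {
  freqs <- simulate_breed_freqs(bp$n_breeds, bp$n_markers, bp$drift)
  labels <- rep(rownames(freqs), each = bp$n_per_breed)
  ref_q <- diag(bp$n_breeds)[rep(seq_len(bp$n_breeds), each = bp$n_per_breed), ]
  ref <- simulate_admixed_genotypes(freqs, ref_q, bp$missing_rate)
  ref$labels <- labels
  q_truth <- rbind(purebred = c(1, rep(0, bp$n_breeds - 1)),
                   admixed = c(0.7, 0.3, rep(0, bp$n_breeds - 2)))
  query <- simulate_admixed_genotypes(freqs, q_truth, bp$missing_rate)
  rownames(query$geno) <- rownames(q_truth)
  list(freqs = freqs, reference = ref, query = query, q_truth = q_truth)
}

#' Simulate a mutation catalog from known signature exposures
#'
#' Counts are a multinomial draw of `n_mutations` from the mixture
#' `sum_k e_k s_k`.
#'
#' @param exposures simplex vector over signatures, or samples x K matrix.
#' @param signatures K x 96 signature matrix (rows sum to 1).
#' @param n_mutations mutations per sample.
#' @param seed optional integer seed.
#' @return 96 x samples `mutation_catalog`.
#' @export
simulate_signature_catalog <- function(exposures, signatures, n_mutations,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  signatures <- .check_signatures(signatures)
  if (is.null(dim(exposures))) exposures <- matrix(exposures, nrow = 1)
  stopifnot(ncol(exposures) == nrow(signatures), all(exposures >= 0),
            all(abs(rowSums(exposures) - 1) < 1e-8))
  n_mutations <- rep_len(n_mutations, nrow(exposures))
  counts <- vapply(seq_len(nrow(exposures)), function(s) {
    p <- as.vector(exposures[s, ] %*% signatures)
    if (n_mutations[s] == 0) integer(96) else
      as.integer(stats::rmultinom(1, n_mutations[s], p))
  }, integer(96))
  dimnames(counts) <- list(sbs_channels(),
                           rownames(exposures) %||% paste0("sample", seq_len(nrow(exposures))))
  structure(counts, class = c("mutation_catalog", "matrix"),
            skipped = c(non_snv = 0L, no_context = 0L, ref_mismatch = 0L))
}

#' Simulate a synthetic signature catalog in the COSMIC SBS layout
#'
#' K signatures over the 96 channels, each concentrating most of its mass
#' on its own random subset of channels so mixtures are identifiable.
#'
#' @param k number of signatures.
#' @param seed optional integer seed.
#' @param n_active channels carrying most of each signature's mass.
#' @return K x 96 matrix, rows summing to 1, named `SBSsim1..K`.
#' @export
simulate_signature_bank <- function(k = 3, seed = NULL, n_active = 12) {
  if (!is.null(seed)) set.seed(seed)
  sig <- t(vapply(seq_len(k), function(i) {
    w <- stats::rgamma(96, 0.05)        # sparse background
    act <- sample.int(96, n_active)
    w[act] <- w[act] + stats::rgamma(n_active, 5)
    w / sum(w)
  }, numeric(96)))
  dimnames(sig) <- list(paste0("SBSsim", seq_len(k)), sbs_channels())
  sig
}
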