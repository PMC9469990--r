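#' Filtering audit tables
#'
#' Every filtering operation reports an audit row `(step, n_in, removed,
#' rescued, n_out)` with `n_out = n_in - removed + rescued` (rescues never
#' add records — they flip flagged records back to passing — so `rescued`
#' is bookkept but contributes 0 to the count change). Chained rows must
#' satisfy `n_in[k+1] == n_out[k]`.
#' @keywords internal
.audit_row <- function(step, n_in, removed = 0L, rescued = 0L) {
  df <- data.frame(step = step, n_in = as.integer(n_in),
                   removed = as.integer(removed), rescued = as.integer(rescued),
                   n_out = as.integer(n_in - removed), stringsAsFactors = FALSE)
  class(df) <- c("filter_audit", "data.frame")
  df
}

#' Check internal consistency of a filter audit chain
#'
#' @param audit a `filter_audit` data frame.
#' @return TRUE invisibly; stops when counts do not chain.
#' @export
validate_audit <- function(audit) {
  if (nrow(audit) > 1 &&
      any(audit$n_in[-1] != audit$n_out[-nrow(audit)])) {
    stop("audit chain broken: n_in of a step does not equal n_out of the previous step")
  }
  if (any(audit$n_out != audit$n_in - audit$removed)) stop("audit row not conserved")
  invisible(TRUE)
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Filtering audit (", nrow(x), " steps)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Position-overlap matching against a site resource.
# `resource` is either a character vector of "chrom:pos" keys (position-only
# matching for every record) or a data frame with chrom/pos/ref, in which
# case SNVs match on identical chrom+pos while indels match when reference
# footprints [pos-1, pos-1+nchar(ref)) intersect. Alternate alleles are
# never compared.
.site_match <- function(records, resource) {
  if (nrow(records) == 0) return(logical(0))
  if (is.character(resource)) return(site_key(records) %in% resource)
  stopifnot(is.data.frame(resource), all(c("chrom", "pos") %in% names(resource)))
  hit <- site_key(records) %in% site_key(resource)
  if (!("ref" %in% names(resource)) || !("ref" %in% names(records))) return(hit)
  is_indel <- nchar(records$ref) != 1L | nchar(records$alt) != 1L
  res_indel <- nchar(resource$ref) != 1L
  if (any(is_indel) && any(res_indel)) {
    ri <- which(is_indel & !hit)
    if (length(ri)) {
      rec_iv <- genomic_intervals(records$chrom[ri], records$pos[ri] - 1L,
                                  records$pos[ri] - 1L + nchar(records$ref[ri]))
      res_iv <- genomic_intervals(resource$chrom[res_indel],
                                  resource$pos[res_indel] - 1L,
                                  resource$pos[res_indel] - 1L + nchar(resource$ref[res_indel]))
      h <- overlap_hits(rec_iv, res_iv)
      hit[ri[unique(h$query)]] <- TRUE
    }
  }
  hit
}

#' Rescue records flagged solely by a withdrawn-resource filter
#'
#' Resets the filter field to passing (empty set) for records whose site
#' overlaps a variant withdrawn from the germline resource *and* whose
#' filter set is exactly `{flag_name}`. Records carrying any additional flag
#' are left untouched.
#'
#' @param records `variant_records`.
#' @param removed_sites sites withdrawn from the germline resource: a
#'   character vector of `"chrom:pos"` keys or a data frame with chrom/pos.
#' @param flag_name the single filter token eligible for rescue
#'   (e.g. `"germline"` for Mutect2 output, `"alleleBias"` for Platypus).
#' @param step audit label.
#' @return list with `records` and one-row `audit`.
#' @export
rescue_flag <- function(records, removed_sites, flag_name,
                        step = paste0("rescue_", flag_name)) {
  stopifnot(length(flag_name) == 1L, nzchar(flag_name))
  toks <- filter_tokens(records)
  only_flag <- vapply(toks, function(t) length(t) == 1L && t == flag_name, logical(1))
  hit <- .site_match(records, removed_sites) & only_flag
  records$filter[hit] <- ""
  list(records = records,
       audit = .audit_row(step, nrow(records), removed = 0L, rescued = sum(hit)))
}

#' Build a position-only panel of normals
#'
#' The union of variant sites over all normal call sets. Membership is by
#' chromosome and position only; alternate alleles are ignored, so two
#' normals carrying different alleles at one position yield a single panel
#' site.
#'
#' @param normal_callsets list of `variant_records`, one per normal sample.
#' @return object of class `pon_sites`: list with `records` (deduplicated
#'   chrom/pos/ref table used for matching) and `provenance` (sample labels).
#' @export
build_site_pon <- function(normal_callsets) {
  if (length(normal_callsets) == 0) {
    stop("panel of normals requires at least one normal call set")
  }
  all <- do.call(rbind, lapply(normal_callsets, function(x) {
    x[, c("chrom", "pos", "ref", "sample")]
  }))
  dedup <- all[!duplicated(site_key(all)), c("chrom", "pos", "ref")]
  rownames(dedup) <- NULL
  structure(list(records = dedup,
                 provenance = unique(stats::na.omit(all$sample))),
            class = "pon_sites")
}

#' @export
print.pon_sites <- function(x, ...) {
  cat("Panel of normals:", nrow(x$records), "sites from",
      length(x$provenance), "normal samples\n")
  invisible(x)
}

#' Remove records overlapping a site resource
#'
#' Position-only matching (footprint overlap for indels when the resource
#' carries reference alleles): a tumor A>G call at a site listed as A>T in
#' the resource is removed.
#'
#' @param records `variant_records`.
#' @param sites a `pon_sites` object, character `"chrom:pos"` keys, or a
#'   data frame with chrom/pos(/ref).
#' @param step audit label.
#' @return list with `records` and `audit`.
#' @export
remove_sites <- function(records, sites, step = "remove_sites") {
  if (inherits(sites, "pon_sites")) sites <- sites$records
  hit <- .site_match(records, sites)
  list(records = records[!hit, , drop = FALSE],
       audit = .audit_row(step, nrow(records), removed = sum(hit)))
}

#' Remove records with a non-passing filter flag
#'
#' @param records `variant_records`.
#' @param step audit label.
#' @return list with `records` and `audit`.
#' @export
drop_non_pass <- function(records, step = "drop_non_pass") {
  keep <- !nzchar(records$filter)
  list(records = records[keep, , drop = FALSE],
       audit = .audit_row(step, nrow(records), removed = sum(!keep)))
}

#' Keep variants called by both callers
#'
#' Output is drawn from `callset_a` (the designated primary caller, whose
#' allele representation is reported) restricted to sites also present in
#' `callset_b`. Matching is by chromosome and position only.
#'
#' @param callset_a,callset_b `variant_records` from the same tumor sample.
#' @param step audit label.
#' @return list with `records` and `audit`.
#' @export
consensus_intersect <- function(callset_a, callset_b, step = "consensus") {
  sa <- unique(stats::na.omit(callset_a$sample))
  sb <- unique(stats::na.omit(callset_b$sample))
  if (length(sa) == 1 && length(sb) == 1 && sa != sb) {
    stop("consensus across different samples: ", sa, " vs ", sb)
  }
  keep <- site_key(callset_a) %in% site_key(callset_b)
  list(records = callset_a[keep, , drop = FALSE],
       audit = .audit_row(step, nrow(callset_a), removed = sum(!keep)))
}

#' Apply allelic-fraction / depth / alt-read support thresholds
#'
#' A record is kept iff `AF >= min_af` and `DP >= min_dp` and
#' `alt_depth >= min_alt` — the logical complement of the removal rule
#' "AF < 0.05, DP < 10, or fewer than 3 alt reads", so boundary values are
#' kept. Records with unresolvable support fields are removed.
#'
#' @param records `variant_records`.
#' @param min_af,min_dp,min_alt keep thresholds (inclusive).
#' @param step audit label.
#' @return list with `records` and `audit`.
#' @export
apply_support_thresholds <- function(records, min_af = 0.05, min_dp = 10,
                                     min_alt = 3, step = "support_thresholds") {
  keep <- !is.na(records$af) & !is.na(records$dp) & !is.na(records$alt_depth) &
    records$af >= min_af & records$dp >= min_dp & records$alt_depth >= min_alt
  list(records = records[keep, , drop = FALSE],
       audit = .audit_row(step, nrow(records), removed = sum(!keep)))
}

#' Screen candidates against regenotyping evidence in normals
#'
#' A candidate is removed when any normal sample shows support at its site.
#' Evidence must cover every queried site; a missing site is an error, never
#' a silent keep.
#'
#' @param records `variant_records`.
#' @param evidence `normal_evidence` data frame (chrom, pos, sample, support).
#' @param step audit label.
#' @return list with `records` and `audit`.
#' @export
regenotype_screen <- function(records, evidence, step = "regenotype_screen") {
  if (nrow(records) == 0) {
    return(list(records = records, audit = .audit_row(step, 0L)))
  }
  keys <- site_key(records)
  ekeys <- paste(evidence$chrom, evidence$pos, sep = ":")
  missing <- setdiff(unique(keys), ekeys)
  if (length(missing)) {
    stop("no regenotyping evidence for ", length(missing), " site(s), e.g. ",
         missing[1])
  }
  supported <- unique(ekeys[evidence$support])
  hit <- keys %in% supported
  list(records = records[!hit, , drop = FALSE],
       audit = .audit_row(step, nrow(records), removed = sum(hit)))
}

.as_records <- function(x, dialect, sample = NULL) {
  if (is.character(x)) read_vcf(x, dialect = dialect, sample = sample) else x
}

.as_evidence <- function(x) if (is.character(x)) read_evidence(x) else x

#' Run the eight-step tumor-only simple-somatic-mutation filter
#'
#' Executes, in order: contig allow-listing; rescue of Mutect2 records
#' flagged `germline` only at withdrawn-resource sites (step 1); the same
#' rescue for Platypus `alleleBias` flags (step 2); Platypus panel-of-normals
#' site removal (step 3); removal of non-passing records in both call sets
#' (step 4); position-only consensus intersection, reported in the Mutect2
#' allele representation (step 5); subtraction of each germline resource,
#' audited per resource (step 6); AF/DP/alt-read support thresholds
#' (step 7); and the regenotyping screen against normal samples (step 8).
#'
#' @param config list with entries:
#'   \describe{
#'     \item{mutect2, platypus}{tumor call sets — paths or `variant_records`.}
#'     \item{normals}{list of Platypus normal call sets (paths or records)
#'       used to build the panel of normals; alternatively `pon`, a
#'       prebuilt `pon_sites`.}
#'     \item{germline_resources}{named list of resources (paths or records).}
#'     \item{removed_sites}{sites withdrawn from the germline reference
#'       (path, records, or `"chrom:pos"` keys).}
#'     \item{evidence}{regenotyping evidence (path or `normal_evidence`).}
#'     \item{contigs}{optional character allow-list; records on other
#'       contigs (unanchored, mitochondrial) are dropped first.}
#'     \item{min_af, min_dp, min_alt}{support thresholds (defaults 0.05,
#'       10, 3).}
#'   }
#' @return object of class `snv_pipeline_result`: list with `records` (the
#'   final call set, Mutect2 representation), `audit`, and `pon`.
#' @export
run_snv_pipeline <- function(config) {
  m2 <- .as_records(config$mutect2, "mutect2")
  pl <- .as_records(config$platypus, "platypus")
  min_af <- config$min_af %||% 0.05
  min_dp <- config$min_dp %||% 10
  min_alt <- config$min_alt %||% 3
  audit <- list()

  if (!is.null(config$contigs)) {
    keep2 <- m2$chrom %in% config$contigs
    keepp <- pl$chrom %in% config$contigs
    audit$allow_m2 <- .audit_row("contig_allowlist_mutect2", nrow(m2), sum(!keep2))
    audit$allow_pl <- .audit_row("contig_allowlist_platypus", nrow(pl), sum(!keepp))
    m2 <- m2[keep2, , drop = FALSE]
    pl <- pl[keepp, , drop = FALSE]
  }

  removed_sites <- config$removed_sites
  if (is.character(removed_sites) && length(removed_sites) == 1 &&
      file.exists(removed_sites)) {
    removed_sites <- read_vcf(removed_sites, "mutect2")
  }
  s1 <- rescue_flag(m2, removed_sites, "germline", step = "step1_rescue_germline")
  m2 <- s1$records
  s2 <- rescue_flag(pl, removed_sites, "alleleBias", step = "step2_rescue_alleleBias")
  pl <- s2$records

  pon <- config$pon
  if (is.null(pon)) {
    normals <- lapply(config$normals, .as_records, dialect = "platypus")
    pon <- build_site_pon(normals)
  }
  s3 <- remove_sites(pl, pon, step = "step3_platypus_pon")
  pl <- s3$records

  s4a <- drop_non_pass(m2, step = "step4_nonpass_mutect2")
  m2 <- s4a$records
  s4b <- drop_non_pass(pl, step = "step4_nonpass_platypus")
  pl <- s4b$records

  s5 <- consensus_intersect(m2, pl, step = "step5_consensus")
  rec <- s5$records

  s6 <- list()
  resources <- config$germline_resources %||% list()
  if (length(resources) && is.null(names(resources))) {
    names(resources) <- paste0("resource", seq_along(resources))
  }
  for (nm in names(resources)) {
    res <- resources[[nm]]
    if (is.character(res) && length(res) == 1 && file.exists(res)) {
      res <- read_vcf(res, "mutect2")
    }
    st <- remove_sites(rec, res, step = paste0("step6_germline_", nm))
    rec <- st$records
    s6[[nm]] <- st$audit
  }

  s7 <- apply_support_thresholds(rec, min_af, min_dp, min_alt,
                                 step = "step7_support")
  rec <- s7$records
  s8 <- regenotype_screen(rec, .as_evidence(config$evidence),
                          step = "step8_regenotype")
  rec <- s8$records

  aud <- do.call(rbind, c(unname(audit),
                          list(s1$audit, s2$audit, s3$audit, s4a$audit,
                               s4b$audit, s5$audit), unname(s6),
                          list(s7$audit, s8$audit)))
  class(aud) <- c("filter_audit", "data.frame")
  # parallel Mutect2/Platypus branches join at step 5, so chain checks apply
  # per branch; row-level conservation applies everywhere
  stopifnot(all(aud$n_out == aud$n_in - aud$removed))
  structure(list(records = rec, audit = aud, pon = pon),
            class = "snv_pipeline_result")
}

#' @export
print.snv_pipeline_result <- function(x, ...) {
  cat("Tumor-only SNV/indel consensus filter\n")
  cat("  final call set:", nrow(x$records), "records\n")
  print(x$audit)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
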