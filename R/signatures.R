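#' The 96 canonical single-base-substitution channels
#'
#' Six pyrimidine-centered substitution classes (C>A, C>G, C>T, T>A, T>C,
#' T>G) crossed with 16 flanking contexts, ordered by substitution class,
#' then 5' base, then 3' base — the fixed channel order used by the COSMIC
#' signature files this package consumes.
#'
#' @return character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(f) paste0(f, "[", s, "]", bases)))
  }), use.names = FALSE)
}

.revcomp <- function(x) chartr("ACGT", "TGCA",
                               vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""), ""))

#' Build a 96-channel trinucleotide-context mutation catalog
#'
#' Single-base substitutions are assigned to pyrimidine-centered channels;
#' mutations reported on a purine reference base are reverse-complemented.
#' Records whose +/-1 bp context cannot be retrieved (contig edge, unknown
#' base, reference mismatch) are skipped and tallied.
#'
#' @param snvs `variant_records`; non-SNV rows are ignored with a tally.
#' @param reference a [Biostrings::DNAStringSet] or FASTA path supplying
#'   the genome sequence.
#' @param samples column order of the catalog; defaults to the samples
#'   present.
#' @return integer matrix 96 x samples of class `mutation_catalog`, with
#'   channel rownames and an attribute `skipped` (named count vector).
#' @export
build_catalog <- function(snvs, reference, samples = NULL) {
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*", "", names(reference))
  channels <- sbs_channels()
  if (is.null(samples)) samples <- unique(snvs$sample)
  cat_m <- matrix(0L, 96, length(samples), dimnames = list(channels, samples))
  skipped <- c(non_snv = 0L, no_context = 0L, ref_mismatch = 0L)
  is_snv <- nchar(snvs$ref) == 1L & nchar(snvs$alt) == 1L &
    snvs$ref %in% c("A", "C", "G", "T") & snvs$alt %in% c("A", "C", "G", "T")
  skipped["non_snv"] <- sum(!is_snv)
  snvs <- snvs[is_snv, , drop = FALSE]
  for (i in seq_len(nrow(snvs))) {
    ch <- snvs$chrom[i]; pos <- snvs$pos[i]
    if (!(ch %in% names(reference)) || pos < 2 ||
        pos > length(reference[[ch]]) - 1) {
      skipped["no_context"] <- skipped["no_context"] + 1L
      next
    }
    tri <- as.character(Biostrings::subseq(reference[[ch]], pos - 1L, pos + 1L))
    if (grepl("[^ACGT]", tri)) { skipped["no_context"] <- skipped["no_context"] + 1L; next }
    if (substr(tri, 2, 2) != snvs$ref[i]) {
      skipped["ref_mismatch"] <- skipped["ref_mismatch"] + 1L
      next
    }
    ref <- snvs$ref[i]; alt <- snvs$alt[i]
    if (ref %in% c("A", "G")) {           # collapse onto pyrimidine strand
      tri <- .revcomp(tri)
      ref <- chartr("AG", "TC", ref)
      alt <- chartr("ACGT", "TGCA", alt)
    }
    key <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3))
    cat_m[key, snvs$sample[i]] <- cat_m[key, snvs$sample[i]] + 1L
  }
  structure(cat_m, class = c("mutation_catalog", "matrix"), skipped = skipped)
}

.check_signatures <- function(signatures) {
  signatures <- as.matrix(signatures)
  if (ncol(signatures) != 96) stop("signature matrix must be K x 96")
  if (any(signatures < 0)) stop("negative signature probability")
  if (any(abs(rowSums(signatures) - 1) > 1e-8)) {
    stop("signature rows must sum to 1 (tolerance 1e-8)")
  }
  signatures
}

#' Adjust signatures for genome-specific mutational opportunities
#'
#' Reweights each signature's channel probabilities by the target genome's
#' trinucleotide abundances and renormalizes per signature:
#' `s'_kj = s_kj * o_j / sum_j(s_kj * o_j)`. Uniform opportunities leave
#' signatures unchanged; the transform is invariant to rescaling `o`.
#'
#' @param signatures K x 96 matrix, rows summing to 1.
#' @param opportunities non-negative 96-vector (not all zero).
#' @return adjusted K x 96 matrix, rows summing to 1.
#' @export
adjust_for_opportunities <- function(signatures, opportunities) {
  signatures <- .check_signatures(signatures)
  opportunities <- as.numeric(opportunities)
  if (length(opportunities) != 96) stop("opportunities must have length 96")
  if (any(opportunities < 0) || all(opportunities == 0)) {
    stop("opportunities must be non-negative and not all zero")
  }
  adj <- sweep(signatures, 2, opportunities, `*`)
  rs <- rowSums(adj)
  if (any(rs == 0)) stop("signature has zero mass under these opportunities")
  sweep(adj, 1, rs, `/`)
}

# EM for multinomial mixture exposures, vectorized over columns of `counts`
# (each column an independent 96-channel catalog fitted against the same
# signature matrix). Returns list(exposures = K x B, loglik = B,
# trace = list of loglik vectors when requested).
.em_exposures <- function(counts, signatures, tol = 1e-8, max_iter = 5000,
                          trace = FALSE) {
  S <- t(signatures)                      # 96 x K
  K <- ncol(S); B <- ncol(counts)
  E <- matrix(1 / K, K, B)
  N <- colSums(counts)
  ll_old <- rep(-Inf, B)
  tr <- if (trace) vector("list", B) else NULL
  for (it in seq_len(max_iter)) {
    P <- S %*% E                          # 96 x B mixture probabilities
    P[P < 1e-300] <- 1e-300
    ll <- colSums(counts * log(P))
    if (trace) for (b in seq_len(B)) tr[[b]] <- c(tr[[b]], ll[b])
    E <- E * (t(S) %*% (counts / P))
    E <- sweep(E, 2, ifelse(N > 0, N, 1), `/`)
    if (all(ll - ll_old < tol * (abs(ll_old) + 1))) {
      return(list(exposures = E, loglik = ll, iterations = it, trace = tr))
    }
    ll_old <- ll
  }
  stop("exposure EM did not converge within ", max_iter,
       " iterations (final loglik change ", signif(max(ll - ll_old), 3), ")")
}

#' Fit signature exposures under a multinomial model
#'
#' Maximum-likelihood exposures for each sample's catalog given a fixed
#' signature matrix, solved by expectation-maximization (log-likelihood is
#' non-decreasing across iterations). Uncertainty is quantified by
#' bootstrap percentile intervals: catalogs are resampled as multinomial
#' draws of the observed size and refit, and the central `interval_mass`
#' of the bootstrap exposures reported. The intervals play the role of the
#' posterior credible intervals used by Bayesian refitting tools; the
#' downstream selection rule consumes only the point estimate and the
#' interval lower bound.
#'
#' @param catalog 96 x samples count matrix (see [build_catalog()]).
#' @param signatures K x 96 matrix with rows summing to 1 (apply
#'   [adjust_for_opportunities()] first when refitting onto a different
#'   genome).
#' @param n_boot bootstrap replicates (default 200).
#' @param interval_mass central interval mass (default 0.95).
#' @param seed integer seed for the bootstrap resampling.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap; exceeding it is an error.
#' @return object of class `exposure_estimates`: list with `exposures`,
#'   `lower`, `upper` (K x samples matrices), `loglik`, `n_mutations`,
#'   `loglik_trace` (per-sample EM trace of the point fit).
#' @export
fit_exposures <- function(catalog, signatures, n_boot = 200,
                          interval_mass = 0.95, seed = NULL, tol = 1e-8,
                          max_iter = 5000) {
  signatures <- .check_signatures(signatures)
  counts <- as.matrix(unclass(catalog))
  if (nrow(counts) != 96) stop("catalog must have 96 channel rows")
  if (any(colSums(counts) == 0)) stop("every fitted sample needs >= 1 mutation")
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(signatures); S <- ncol(counts)
  fit <- .em_exposures(counts, signatures, tol, max_iter, trace = TRUE)
  lower <- upper <- matrix(NA_real_, K, S,
                           dimnames = list(rownames(signatures), colnames(counts)))
  alpha <- (1 - interval_mass) / 2
  for (s in seq_len(S)) {
    n <- sum(counts[, s])
    boot <- stats::rmultinom(n_boot, n, counts[, s] / n)
    bfit <- .em_exposures(boot, signatures, tol, max_iter)
    qs <- apply(bfit$exposures, 1, stats::quantile, probs = c(alpha, 1 - alpha))
    lower[, s] <- pmin(qs[1, ], fit$exposures[, s])
    upper[, s] <- pmax(qs[2, ], fit$exposures[, s])
  }
  dimnames(fit$exposures) <- list(rownames(signatures), colnames(counts))
  structure(list(exposures = fit$exposures, lower = lower, upper = upper,
                 loglik = fit$loglik, n_mutations = colSums(counts),
                 loglik_trace = fit$trace),
            class = "exposure_estimates")
}

#' @export
print.exposure_estimates <- function(x, ...) {
  cat("Signature exposures (", nrow(x$exposures), " signatures x ",
      ncol(x$exposures), " samples )\n", sep = "")
  print(round(x$exposures, 3))
  invisible(x)
}

#' Select well-supported signatures and refit
#'
#' A signature is retained iff the lower bound of its exposure interval
#' exceeds `floor` in at least one sample; fitting is then rerun on the
#' retained set only, so refit exposures renormalize over it.
#'
#' @param estimates first-pass `exposure_estimates`.
#' @param catalog the catalog that produced them.
#' @param signatures the full K x 96 signature matrix.
#' @param floor selection lower bound (default 0.025, strict `>`).
#' @param ... passed to [fit_exposures()] for the refit.
#' @return `exposure_estimates` over the retained signatures, with a
#'   `selected` attribute naming them.
#' @export
select_and_refit <- function(estimates, catalog, signatures, floor = 0.025, ...) {
  signatures <- .check_signatures(signatures)
  keep <- apply(estimates$lower > floor, 1, any)
  if (!any(keep)) stop("no signature passed the selection floor of ", floor)
  refit <- fit_exposures(catalog, signatures[keep, , drop = FALSE], ...)
  attr(refit, "selected") <- rownames(signatures)[keep]
  refit
}
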