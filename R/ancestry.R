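#' Build a genotype matrix object
#'
#' Dosage-coded biallelic genotypes (0/1/2 alternate-allele copies, NA for
#' missing) for samples x SNPs, with SNP coordinates and optional per-sample
#' breed labels (reference samples labeled, query samples NA).
#'
#' @param geno samples x SNPs numeric matrix with entries in {0,1,2,NA}.
#' @param chrom,pos SNP coordinates (length = ncol(geno)).
#' @param labels per-sample breed label or NA (length = nrow(geno)).
#' @return list of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, chrom, pos, labels = NULL) {
  geno <- as.matrix(geno)
  if (!all(geno %in% c(0, 1, 2) | is.na(geno))) {
    stop("genotypes must be dosages in {0,1,2} or NA")
  }
  stopifnot(length(chrom) == ncol(geno), length(pos) == ncol(geno))
  if (is.null(labels)) labels <- rep(NA_character_, nrow(geno))
  stopifnot(length(labels) == nrow(geno))
  structure(list(geno = geno, chrom = as.character(chrom),
                 pos = as.numeric(pos), labels = as.character(labels)),
            class = "genotype_matrix")
}

#' Hudson's two-population FST estimator
#'
#' Per-SNP estimate with sample-size correction:
#' numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`. Estimates may be negative in finite samples.
#' Sites where the denominator is zero (both populations fixed for the
#' same allele) are undefined (NA) and excluded from aggregation.
#'
#' @param p1,p2 allele frequencies in each population (vectors).
#' @param n1,n2 allele sample sizes (>= 2).
#' @param aggregate if TRUE return the multi-SNP ratio-of-averages
#'   (sum of numerators / sum of denominators over defined sites) instead
#'   of per-SNP values.
#' @return per-SNP FST vector, or a single aggregated value.
#' @export
hudson_fst <- function(p1, n1, p2, n2, aggregate = FALSE) {
  if (any(c(n1, n2) < 2)) stop("sample sizes must be >= 2")
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) stop("frequencies must lie in [0,1]")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (aggregate) {
    ok <- den > 0
    if (!any(ok)) stop("FST undefined: all sites monomorphic for the same allele")
    return(sum(num[ok]) / sum(den[ok]))
  }
  ifelse(den > 0, num / den, NA_real_)
}

.breed_freqs <- function(geno, labels, breed) {
  g <- geno[labels %in% breed, , drop = FALSE]
  n_obs <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_obs)
  list(p = p, n = 2 * n_obs)   # n = sampled allele count
}

#' Select ancestry-informative markers by FST
#'
#' Drops SNPs whose missingness reaches `max_missing`, computes per-breed
#' FST against the configured comparison scheme, and selects SNPs whose
#' FST exceeds `fst_thresh`. `scheme = "ovr"` compares each breed against
#' all remaining samples pooled; `"pairwise"` compares every breed pair.
#' `mode = "any"` selects a SNP when any comparison exceeds the threshold,
#' `"all"` when every defined comparison does.
#'
#' @param genotypes a `genotype_matrix` with labeled reference samples.
#' @param fst_thresh selection threshold (strict `>`, default 0.15).
#' @param max_missing maximum tolerated per-SNP missingness (strict `<`,
#'   default 0.10).
#' @param scheme `"ovr"` (one-vs-rest, default) or `"pairwise"`.
#' @param mode `"any"` (default) or `"all"`.
#' @return sorted integer indices of selected SNPs.
#' @export
select_markers <- function(genotypes, fst_thresh = 0.15, max_missing = 0.10,
                           scheme = c("ovr", "pairwise"), mode = c("any", "all")) {
  scheme <- match.arg(scheme); mode <- match.arg(mode)
  geno <- genotypes$geno
  labels <- genotypes$labels
  breeds <- sort(unique(stats::na.omit(labels)))
  if (length(breeds) < 2) stop("marker selection needs >= 2 labeled breeds")
  missingness <- colMeans(is.na(geno[!is.na(labels), , drop = FALSE]))
  eligible <- missingness < max_missing
  comps <- if (scheme == "ovr") {
    lapply(breeds, function(b) list(a = b, b = setdiff(breeds, b)))
  } else {
    cb <- utils::combn(breeds, 2)
    lapply(seq_len(ncol(cb)), function(i) list(a = cb[1, i], b = cb[2, i]))
  }
  fst <- vapply(comps, function(cp) {
    f1 <- .breed_freqs(geno, labels, cp$a)
    f2 <- .breed_freqs(geno, labels, cp$b)
    n1 <- pmax(f1$n, 2); n2 <- pmax(f2$n, 2)
    hudson_fst(f1$p, n1, f2$p, n2)
  }, numeric(ncol(geno)))
  if (is.null(dim(fst))) fst <- matrix(fst, nrow = 1)
  over <- fst > fst_thresh
  hit <- if (mode == "any") apply(over, 1, any, na.rm = TRUE)
         else apply(over, 1, function(x) all(x[!is.na(x)]) && any(!is.na(x)))
  sort(which(eligible & hit))
}

#' LD-based marker pruning
#'
#' Within each chromosome, while any retained pair of SNPs closer than
#' `window_bp` has squared genotype correlation above `r2_thresh`, the
#' member of the (positionally first) violating pair with the higher
#' missingness is removed (ties broken toward the higher column index), so
#' the output is deterministic. The pruned set contains no within-window
#' pair exceeding the threshold.
#'
#' @param genotypes a `genotype_matrix` (positions must be available).
#' @param window_bp window size in bp (pairs closer than this are tested).
#' @param r2_thresh removal threshold (strict `>`, default 0.5).
#' @return sorted integer indices of retained SNPs.
#' @export
ld_prune <- function(genotypes, window_bp = 50000, r2_thresh = 0.5) {
  geno <- genotypes$geno
  keep <- rep(TRUE, ncol(geno))
  missingness <- colMeans(is.na(geno))
  for (ch in unique(genotypes$chrom)) {
    idx <- which(genotypes$chrom == ch)
    idx <- idx[order(genotypes$pos[idx])]
    repeat {
      ret <- idx[keep[idx]]
      if (length(ret) < 2) break
      violated <- FALSE
      for (a in seq_len(length(ret) - 1)) {
        i <- ret[a]
        for (b in (a + 1):length(ret)) {
          j <- ret[b]
          if (abs(genotypes$pos[j] - genotypes$pos[i]) >= window_bp) break
          r <- suppressWarnings(stats::cor(geno[, i], geno[, j],
                                           use = "pairwise.complete.obs"))
          if (!is.na(r) && r^2 > r2_thresh) {
            drop <- if (missingness[i] > missingness[j]) i
                    else if (missingness[j] > missingness[i]) j
                    else max(i, j)
            keep[drop] <- FALSE
            violated <- TRUE
            break
          }
        }
        if (violated) break
      }
      if (!violated) break
    }
  }
  sort(which(keep))
}

#' Build a breed allele-frequency panel
#'
#' Per-breed alternate-allele frequencies from labeled reference samples;
#' breeds below the minimum panel size are dropped.
#'
#' @param genotypes a `genotype_matrix` with labeled reference samples.
#' @param min_panel_size minimum purebred dogs per breed (default 12).
#' @return list of class `allele_frequency_panel` with `freqs`
#'   (breeds x SNPs), `counts` (samples per breed).
#' @export
allele_frequency_panel <- function(genotypes, min_panel_size = 12) {
  labels <- genotypes$labels
  tab <- table(stats::na.omit(labels))
  breeds <- sort(names(tab)[tab >= min_panel_size])
  if (length(breeds) == 0) stop("no breed reaches the minimum panel size")
  freqs <- t(vapply(breeds, function(b) .breed_freqs(genotypes$geno, labels, b)$p,
                    numeric(ncol(genotypes$geno))))
  structure(list(freqs = freqs, counts = as.integer(tab[breeds])),
            class = "allele_frequency_panel")
}

# EM for one query sample's ancestry fractions against fixed panel
# frequencies; returns list(q, loglik, trace).
.admixture_em <- function(g, freqs, tol = 1e-7, max_iter = 10000) {
  obs <- !is.na(g)
  if (!any(obs)) stop("all genotypes missing for a query sample")
  g <- g[obs]
  f <- pmin(pmax(freqs[, obs, drop = FALSE], 1e-6), 1 - 1e-6)  # K x J
  K <- nrow(f); J <- ncol(f)
  q <- rep(1 / K, K)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    A <- colSums(q * f)            # P(alt allele) per marker
    B <- colSums(q * (1 - f))
    ll <- sum(g * log(A) + (2 - g) * log(B))
    trace <- c(trace, ll)
    # responsibility-weighted allele counts per ancestry component
    q_new <- (f %*% (g / A) + (1 - f) %*% ((2 - g) / B)) * q / (2 * J)
    q <- as.vector(q_new) / sum(q_new)
    if (ll - ll_old < tol * (abs(ll_old) + 1)) {
      return(list(q = q, loglik = ll, trace = trace))
    }
    ll_old <- ll
  }
  stop("ancestry EM did not converge within ", max_iter, " iterations")
}

#' Supervised global ancestry inference
#'
#' For each query sample, maximizes the binomial likelihood of its dosages
#' given fixed breed allele frequencies,
#' `prod_j Binom(g_j; 2, sum_k q_k f_kj)`, over the ancestry simplex `q`
#' by expectation-maximization (boundary-stable frequency clamping,
#' log-likelihood non-decreasing). Missing genotypes are skipped. Panel
#' frequencies are never updated — with fully labeled references,
#' supervised mode reduces to per-sample `q` estimation.
#'
#' @param query_genotypes a `genotype_matrix` of query samples (markers
#'   aligned with the panel columns).
#' @param panel an `allele_frequency_panel`.
#' @param seed optional integer; set for reproducibility of any downstream
#'   stochastic consumer (the EM itself is deterministic from its uniform
#'   initialization).
#' @param tol log-likelihood convergence tolerance (default 1e-7).
#' @return object of class `ancestry_result`: list with `q`
#'   (samples x breeds matrix, rows on the simplex) and `loglik`.
#' @export
supervised_ancestry <- function(query_genotypes, panel, seed = NULL,
                                tol = 1e-7) {
  if (!is.null(seed)) set.seed(seed)
  geno <- query_genotypes$geno
  if (ncol(geno) != ncol(panel$freqs)) {
    stop("query markers not aligned with panel frequencies")
  }
  fits <- lapply(seq_len(nrow(geno)), function(i) {
    .admixture_em(geno[i, ], panel$freqs, tol = tol)
  })
  q <- do.call(rbind, lapply(fits, `[[`, "q"))
  dimnames(q) <- list(rownames(geno), rownames(panel$freqs))
  structure(list(q = q, loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                 trace = lapply(fits, `[[`, "trace")),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat("Supervised ancestry for", nrow(x$q), "sample(s) over", ncol(x$q), "breeds\n")
  print(round(x$q, 3))
  invisible(x)
}

#' Consensus breed call from ancestry fractions
#'
#' Reports the top breed when its fraction reaches `dominance_thresh`
#' (inclusive); otherwise `"mixed/village"` — the expected behavior for
#' village dogs, whose ancestry spreads thinly over many breeds.
#'
#' @param result an `ancestry_result` (or a samples x breeds matrix).
#' @param dominance_thresh minimum dominant fraction (default 0.5).
#' @return data frame with sample, call, top_breed, top_fraction.
#' @export
consensus_breed <- function(result, dominance_thresh = 0.5) {
  q <- if (inherits(result, "ancestry_result")) result$q else as.matrix(result)
  top <- apply(q, 1, which.max)
  frac <- q[cbind(seq_len(nrow(q)), top)]
  breed <- colnames(q)[top]
  data.frame(sample = rownames(q) %||% as.character(seq_len(nrow(q))),
             call = ifelse(frac >= dominance_thresh, breed, "mixed/village"),
             top_breed = breed, top_fraction = frac,
             stringsAsFactors = FALSE, row.names = NULL)
}
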