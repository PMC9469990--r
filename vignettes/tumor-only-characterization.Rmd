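---
title: "Tumor-only whole-genome characterization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only whole-genome characterization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumoronly)
```

# The problem

Cancer cell lines and archival tumors frequently lack a germline sample
from the same individual. Somatic variant calling then cannot subtract the
individual's own inherited variation; it must lean on *external* evidence:
unmatched normal samples (a panel of normals), population germline
resources, and regenotyping of candidate sites in those normals. Because
each of these resources is incomplete, the subtraction must be stringent —
accepting that some true somatic variants will be lost — and every removal
must be auditable. This package implements such a workflow for canine
genomes: consensus filtering of simple somatic mutations from two callers,
structural-variant filtering, copy-number classification, per-sample genome
summaries, mutational-signature refitting, and breed-ancestry calling, plus
a synthetic-cohort generator that makes all of it testable with planted
truth.

# Coordinate and matching conventions

Internally every interval is **0-based half-open** (`[start, end)`, the BED
convention); VCF positions convert at the I/O boundary via
`pos_internal = pos_vcf − 1`. One internal convention eliminates the
off-by-one class of bugs that arises when BED, GTF and VCF coordinates mix.
Book-ended intervals merge (as `bedtools merge` does by default).

Variant identity throughout the filtering steps is **position-only**
(`chrom:pos`), never allele-aware: different callers record the same event
with different alternate alleles often enough that requiring allele
agreement would leak germline variants through the filters. For indels the
position-only rule is relaxed to *reference-footprint overlap*
(`[pos−1, pos−1+nchar(ref))` intersecting the resource variant's
footprint), because tools also place indel start positions differently.
Multiallelic records are split into one record per alternate allele on
ingest; the raw filter field is preserved verbatim, with `.` and `PASS`
normalized to the empty flag set.

# The SNV consensus filter

Steps, in order: (1) reset the filter to passing for records flagged
`germline` *only* at sites withdrawn from the germline reference; (2) the
same rescue for `alleleBias` flags in the second caller's output; (3)
subtract the position-only panel of normals from the second caller's
calls; (4) remove non-passing records; (5) keep only sites called by both
callers, reporting the first caller's allele representation; (6) subtract
each germline resource in turn (audited per resource; union and sequential
application give identical results, only audit granularity differs); (7)
keep records with `AF ≥ 0.05`, `DP ≥ 10` and `alt reads ≥ 3`; (8) remove
candidates with regenotyping support in any normal.

Decisions worth making explicit:

* **Ordering matters for the rescues.** Step 4 removes every flagged
  record, so rescues (steps 1–2) must precede it; a regression test
  asserts the two orders differ. Steps 6 and 7 commute and a property test
  asserts that too.
* **Threshold boundaries are keep-inclusive.** The removal rule is stated
  with strict inequalities (`AF < 0.05`, `DP < 10`, fewer than 3 reads),
  so `AF = 0.05`, `DP = 10`, `alt = 3` are kept.
* **Missing support fields.** When a dialect lacks an AF tag, AF is
  recomputed as `alt_depth / DP`; when neither is recoverable the record is
  "unsupported" and fails step 7 rather than passing silently.
* **The regenotyping engine is a contract, not a tool.** Step 8 consumes a
  boolean support-per-normal-per-site table; the decision rule ("any
  support → remove") is what the workflow defines, and any regenotyper can
  stand behind the table. A missing site in the evidence table is an
  error, never a silent keep.
* **Contig allow-list.** Unanchored and mitochondrial contigs are excluded
  up front.
* The audit rows satisfy `n_out = n_in − removed` everywhere, with rescues
  bookkept separately (they flip flags, not counts); the two caller
  branches chain independently and join at the consensus step.

# The SV filter

Call sets merge by single-linkage clustering under a **nonlinear merge
distance**: two SVs are mergeable iff they share type and chromosome pair
and both breakpoints lie within `d = min(max_dist, length of either
variant)` (so a 300 bp deletion only merges within 300 bp), with
`d = max_dist = 1000` bp for breakends and insertions. Clustering is made
order-invariant by processing records in canonical breakpoint order. A
tumor SV survives the panel-of-normals screen iff its cluster contains no
normal-sample member. Quality filtering keeps passing, precise records
with `PR ≥ 15` or `SR ≥ 15`. Centromere-window overlaps are *flagged*, not
removed — whether flagged variants were dropped downstream is not
determinable, so the flag is carried and an `exclude_centromeric` switch
exposed; flagged records are excluded from recurrence counting by default.
After the regenotyping screen, breakends whose mate was removed at any
earlier step are removed too, so the surviving breakend set is closed
under mate linkage (a malformed input whose mate never existed is an
error instead). The source procedure numbers its steps 1, 3, 4, 5 with the
ID-extraction sentence as the implicit step 2; the audit labels here keep
the published numbering for steps 3–5.

# Copy number and genome summaries

Segments classify by log2 copy ratio: `≥ 0.4` one-copy gain, `≤ −0.9`
two-copy loss, the band between neutral. The stated rule conflates
"losses" with the gain threshold in its prose; the parenthetical meanings
are unambiguous and are what is implemented. No one-copy-loss cutoff is
ever printed, so the shallow-loss band is off by default and configurable
(`shallow_loss_thresh`). Gene annotation targets the gene body (an
`exonic_only` mode restricts to CDS); overlap fractions are computed on
merged gene intervals so the annotation is invariant to segment splitting.

Sex is the ratio of mean X depth to the *unweighted* mean of per-autosome
mean depths (configurable; base-weighted averaging differs negligibly at
WGS depth uniformity): `[0.3, 0.7]` male, `[0.8, 1.2]` female, endpoints
inclusive — "between" is ambiguous and inclusivity is the documented
choice — anything else indeterminate. Burden is mutations divided by the
combined allow-list contig size in Mb; whether X belongs in the
denominator is unstated, so the default counts every allow-listed contig.

Kataegis was identified visually from rainfall plots in the source
workflow; the numeric rule here — maximal runs of **≥ 6 mutations with
mean inter-mutation spacing ≤ 1 kb** — is this package's own, matching the
literature-standard convention, and both parameters are exposed.
Qualifying windows mark the inter-mutation *gaps* they span; maximal runs
of marked gaps become regions. Marking gaps rather than mutation indices
keeps two dense runs separated by one long gap from fusing into a single
region, while windows that genuinely share a gap merge. Regions span first
to last mutation (half-open, so span in bp is `end − start`).

# Signature refitting

Catalogs are 96-channel pyrimidine-centered trinucleotide counts in the
fixed COSMIC channel order (validated on load); purine-reference records
are reverse-complemented, and records whose ±1 bp context is unavailable
are skipped and tallied. Signatures transfer between genomes through the
opportunity adjustment `s'_kj ∝ s_kj o_j` (scale-invariant, invertible).

Exposures maximize the multinomial likelihood
`c ~ Mult(N, Σ_k e_k s'_k)` by EM — the update is the standard
responsibility-weighted count share, log-likelihood provably
non-decreasing, convergence declared at relative improvement `< 1e-8`
(cap 5000 iterations; exceeding the cap is an error with diagnostics).
Uncertainty comes from **bootstrap percentile intervals** (200 multinomial
resamples of the catalog, refit jointly as one vectorized EM): this
replaces the Bayesian MCMC fit of the original tooling. The deviation is
deliberate: the downstream selection rule consumes only a point estimate
and an interval lower bound, and the frequentist surrogate is
deterministic under a seed and directly testable. The selection rule is
unchanged — retain a signature iff its interval lower bound exceeds 0.025
in at least one sample, then refit on the retained set (exposures
renormalize over it). Mean exposures are reported but never used as a
selection criterion.

# Breed ancestry

Hudson's FST estimator with sample-size correction is computed per SNP;
multi-SNP aggregation is the ratio of summed numerators to summed
denominators, with undefined sites (both populations fixed for the same
allele) excluded. Marker selection drops SNPs with ≥ 10% missingness and
keeps those whose FST exceeds 0.15. The published phrase "across all
comparisons" does not determine the comparison scheme; strictly requiring
*all pairwise* comparisons to exceed 0.15 would select almost nothing, so
the default is **one-vs-rest with selection when any comparison exceeds
the threshold** (an informative-marker reading), with `scheme =
"pairwise"` and `mode = "all"` available. Neither scheme is asserted to be
the original one. LD pruning removes, within 50 kb, the higher-missingness
member of any pair with `r² > 0.5` (ties toward the higher index), giving
a deterministic output that provably contains no violating pair.

Supervised ancestry fixes the panel allele frequencies and estimates only
the per-sample simplex `q` by EM on the binomial likelihood
`Π_j Binom(g_j; 2, Σ_k q_k f_kj)` — with fully labeled references,
supervised admixture reduces exactly to this per-sample problem.
Frequencies are clamped to `[1e-6, 1−1e-6]` for boundary stability;
missing genotypes are skipped; convergence at relative improvement
`< 1e-7`. The consensus call reports the top breed at a dominant fraction
`≥ 0.5` (inclusive) and `"mixed/village"` otherwise — village dogs have no
modern-breed ancestry and surface as many small fractions.

# The synthetic cohort

The generator's defaults are the study conditions: **2 tumors against 23
normal germline samples**, 250 planted SNV/indel truth entries per tumor
split into classes that exercise every rule — well-supported somatics
(support grids that include the exact boundary values `AF = 0.05`,
`DP = 10`, `alt = 3`), low-support somatics straddling each threshold from
below, rescue-eligible records flagged `germline`-only or `alleleBias` at
withdrawn sites, caller-private calls, same-position/different-allele
caller discordances, germline variants planted in the panel of normals or
in one of three germline resources (five of them as indels whose resource
representation is shifted 1 bp to exercise footprint matching),
regenotyping leaks supported in 1–3 normals, and records on off-allow-list
contigs. SVs plant passing somatics, mate-paired breakends, pairs with one
failing mate, low-support/imprecise/non-passing records, centromeric
spans, and germline SVs 150 bp from a normal counterpart. Segments tile
chr1 at ratios `{−1.2, −0.9, −0.3, 0, 0.4, 0.9}`; coverage ratios are
planted at 0.5 and 1.0; the breed panel drifts three breeds from a common
ancestral frequency with admixed queries at `q = (1,0,0)` and
`(0.7,0.3,0)`.

All randomness flows from one `set.seed(seed)` call, so a config + seed
pair reproduces the bundle byte-for-byte (asserted on the written files).
What the generator does *not* emulate: read-level data (no FASTQ/BAM),
realistic canine sequence content, mapping artifacts, contamination, or
caller-internal behavior — caller dialects are emulated at the VCF-field
level because the filtering contracts consume VCF fields only. Passing
tests therefore demonstrate that the decision rules are implemented
exactly, not that the rules themselves are optimal on real data.

```{r cohort, eval = FALSE}
co  <- simulate_cohort(cohort_config(), seed = 7)
res <- run_snv_pipeline(snv_pipeline_config(co, "tumor1"))
res$audit
```

# Problem sizes and verification

The test suite verifies each operation against an independent oracle:
interval overlap and merging against O(n²) pairwise and per-base bitmap
checks (1,000 and 500 random intervals), consensus intersection against
brute-force set intersection at 1,000 records, kataegis against a literal
window scan on 100 random catalogs, the exposure EM against a 1-D direct
maximizer on two-signature instances (agreement within 1e-4), the
ancestry EM against a 0.001-step grid search (within 1e-3), and Hudson FST
against closed-form hand values. End-to-end recovery uses the default
cohort; signature recovery uses 3 signatures at 20,000 mutations/sample
with the selection rule checked over 100 replicates; ancestry recovery
uses 5,000 markers. Breakend closure is checked on 1,000 randomized
fixtures. These sizes are the package's chosen verification conditions and
run in well under two minutes apiece.

# Known limitations

* The filters are faithful to a deliberately stringent design: any tumor
  variant coinciding by position with any resource entry is removed, so
  true somatic variants at polymorphic sites are lost by construction.
* Bootstrap percentile intervals approximate, but are not, posterior HPD
  intervals; very sparse catalogs (tens of mutations) make the lower
  bounds conservative.
* The LD pruner is quadratic per window and intended for the post-FST
  marker scale, not for millions of SNPs.
* `read_vcf` handles the two supported dialects' FORMAT conventions; it is
  not a general-purpose VCF feature-complete reader (no BCF, no tabix).
* Supervised ancestry assumes the query's true ancestry lies in the span
  of the panel breeds; out-of-panel ancestry (village dogs) surfaces as
  diffuse fractions, which is the intended signal, not an estimate of the
  true mixture.
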