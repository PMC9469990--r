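# tumoronly

Whole-genome characterization of tumor samples **without a matched germline
control**, built for canine osteosarcoma cell lines and applicable to any
unmatched canine WES/WGS dataset. When no normal from the same individual is
available, germline variation must be subtracted using external resources —
panels of unmatched normals, population germline VCFs, and regenotyping
evidence — applied stringently and with full bookkeeping. This package
implements that workflow as tested, reusable R functions, together with a
synthetic-cohort generator that plants known truth so every stage can be
verified at desk scale.

## What it implements

**Simple somatic mutations** — an eight-step consensus filter over two
caller dialects (Mutect2-style and Platypus-style VCFs):

1. reset `germline`-only filter flags at sites withdrawn from the germline
   reference; 2. the same rescue for Platypus `alleleBias` flags;
3. subtract a position-only panel of normals built from the normal call
   sets; 4. drop non-passing records; 5. keep only variants called by both
   callers (matching by chromosome and position, never by allele — tools
   disagree on allele representation); 6. subtract up to three germline
   resources (indels match by reference-footprint overlap); 7. keep records
   with AF ≥ 0.05, DP ≥ 10 and ≥ 3 alt reads (the complement of the removal
   rule `AF < 0.05, DP < 10, alt < 3`); 8. remove candidates with
   regenotyping support in any normal sample. Every step emits an audit row
   `(step, n_in, removed, rescued, n_out)` and the chain is validated.

**Structural variants** — a five-step filter of Manta-style call sets:
panel-of-normals screening via single-linkage clustering with the nonlinear
merge distance `d = min(1000, SV length)`; removal of non-PASS, IMPRECISE
and low-support records (kept iff PR ≥ 15 or SR ≥ 15); centromere-window
flagging; a regenotyping screen; and removal of orphaned translocation
breakends so the surviving BND set is mate-closed.

**Copy number** — segments classified by log2 copy ratio (≥ 0.4 one-copy
gain, ≤ −0.9 two-copy loss), gene-body overlap annotation with per-gene
overlap fractions, and cohort recurrence counting.

**Genome summaries** — sex from the X/autosome coverage ratio
([0.3, 0.7] male, [0.8, 1.2] female), mutational burden in mutations/Mb,
rainfall inter-mutation distances, and kataegis detection (maximal runs of
≥ 6 mutations with mean spacing ≤ 1 kb).

**Mutational signatures** — 96-channel trinucleotide catalogs
(pyrimidine-centered, COSMIC channel order), genome-opportunity adjustment
`s'_kj ∝ s_kj o_j`, maximum-likelihood exposure refitting under a
multinomial model `c ~ Multinomial(N, Σ_k e_k s'_k)` solved by EM, bootstrap
percentile intervals, and the select-and-refit rule (keep signatures whose
interval lower bound exceeds 0.025 in any sample, then refit).

**Breed ancestry** — Hudson's FST estimator
`[(p1−p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1)] / [p1(1−p2) + p2(1−p1)]`,
FST > 0.15 marker selection, LD pruning (50 kb windows, r² > 0.5), and
supervised admixture: per query sample, maximize
`Π_j Binom(g_j; 2, Σ_k q_k f_kj)` over the ancestry simplex by EM with the
panel frequencies held fixed.

**Concordance** — CDS restriction, low-impact exclusion, per-gene
per-study recurrence fractions, and call-set confirmation rates
(position-level by default, allele-exact optional).

## Worked example

```r
library(tumoronly)

co  <- simulate_cohort(cohort_config(), seed = 7)   # 2 tumors, 23 normals
res <- run_snv_pipeline(snv_pipeline_config(co, "tumor1"))
res
#> Tumor-only SNV/indel consensus filter
#>   final call set: 70 records
#> Filtering audit (13 steps)
#>                               step n_in removed rescued n_out
#>           contig_allowlist_mutect2  230       5       0   225
#>          contig_allowlist_platypus  230       5       0   225
#>              step1_rescue_germline  225       0      10   225
#>            step2_rescue_alleleBias  225       0      10   225
#>                 step3_platypus_pon  225      30       0   195
#>              step4_nonpass_mutect2  225      10       0   215
#>             step4_nonpass_platypus  195      10       0   185
#>                    step5_consensus  215      60       0   155
#>       step6_germline_axelsson_snps  155      13       0   142
#>          step6_germline_broad_snps  142      13       0   129
#>  step6_germline_germline_reference  129      14       0   115
#>                      step7_support  115      30       0    85
#>                   step8_regenotype   85      15       0    70
```

The 70 survivors are exactly the 70 planted eligible somatic variants
(50 well-supported somatics, 10 rescued from `germline`-only flags, 10 from
`alleleBias` flags); all 180 planted germline, artifact, low-support and
caller-private records are removed. Signature refitting on a simulated
catalog recovers its generating mixture:

```r
sig  <- simulate_signature_bank(3, seed = 11)
catm <- simulate_signature_catalog(rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3)),
                                   sig, 20000, seed = 2)
fit_exposures(catm, sig, n_boot = 200, seed = 3)
#> Signature exposures (3 signatures x 2 samples)
#>         sample1 sample2
#> SBSsim1   0.599   0.200
#> SBSsim2   0.296   0.502
#> SBSsim3   0.105   0.298
```

and supervised ancestry recovers a 70/30 two-breed admixture over 5,000
markers (`breedA 0.719, breedB 0.275, breedC 0.006` → consensus call
`breedA`). `hudson_fst(0.8, 10, 0.2, 10)` returns `0.4771242`, the
closed-form value, and a fixed difference returns exactly 1.

A thin shell interface wraps the same functions:

```sh
exec/tumoronly simulate --out fixtures --seed 4
exec/tumoronly snv-filter --mutect2 fixtures/tumor1.mutect2.vcf \
  --platypus fixtures/tumor1.platypus.vcf --pon-dir pon \
  --germline-resources fixtures/resource.germline_reference.vcf,... \
  --removed-sites fixtures/removed_sites.vcf --evidence fixtures/evidence.tsv \
  --contigs chr1,chr2,chr3,chr4,chr5,chrX --out filtered.vcf
```

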