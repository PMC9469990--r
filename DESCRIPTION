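Package: tumoronly
Title: Tumor-Only Whole-Genome Somatic Characterization for Canine Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Characterizes whole-genome sequence of tumor samples that lack a
    matched germline control, as used for canine osteosarcoma cell lines.
    Implements an eight-step consensus filter for simple somatic mutations
    combining two caller dialects with panel-of-normal and germline-resource
    subtraction, a five-step structural-variant filter with nonlinear-distance
    merging and breakend mate closure, copy-ratio segment classification and
    gene-level annotation, sex inference from X/autosome coverage, mutational
    burden and kataegis detection, mutational-signature refitting under a
    multinomial model with genome-opportunity adjustment and a lower-bound
    select-and-refit rule, and supervised breed-ancestry inference with Hudson
    FST marker selection and LD pruning. A synthetic-cohort generator with
    planted truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
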