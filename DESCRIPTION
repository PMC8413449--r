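Package: mitodyn
Title: Mitochondrial DNA Heteroplasmy Dynamics During Cell Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of mitochondrial DNA (mtDNA) heteroplasmy dynamics in
    fibroblast-to-iPSC reprogramming and directed differentiation: variant and
    sample quality control for bulk WGS, bulk RNA-seq and single-cell RNA-seq
    calls; classification of variants across fibroblast/iPSC pairs (shared,
    lost, iPSC-specific) with heteroplasmic-shift statistics and exact binomial
    direction tests; iPSC-specific mutation-rate estimation with exact Poisson
    intervals; strand-resolved 6- and 96-class trinucleotide mutational
    signatures on the circular mitochondrial genome; single-cell pseudo-bulk
    heteroplasmy, stage assignment and mtDNA-based lineage clustering;
    heteroplasmy-expression variance partitioning and differential expression;
    and a synthetic cohort generator (age-dependent mutation burden, binomial
    reprogramming bottleneck, signature-driven de novo mutations, read-sampling
    noise, clonal single cells) so the full pipeline is testable without
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    lme4,
    limma,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    uwot
Config/testthat/edition: 3
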