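---
title: "Modelling mtDNA heteroplasmy dynamics through reprogramming and differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mtDNA heteroplasmy dynamics through reprogramming and differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodyn)
```

## The problem

Most human cells carry hundreds to thousands of copies of the 16,569-bp
mitochondrial genome, and somatic mutations create mixed populations of
mtDNA molecules within a cell or tissue (heteroplasmy). When dermal
fibroblasts are reprogrammed into induced pluripotent stem cells (iPSCs),
the heteroplasmic variant spectrum changes abruptly: most age-acquired
fibroblast variants disappear from the derived line, while other variants —
including ones undetectable in the founder — rise to high heteroplasmy
fractions. `mitodyn` implements the statistical machinery to quantify these
dynamics from deep-sequencing variant calls: quality control, variant
classification across fibroblast/iPSC pairs, heteroplasmic-shift and
mutation-rate estimation, strand-resolved mutational signatures, single-cell
lineage tracing, and heteroplasmy–expression association — together with a
synthetic cohort generator so that every stage is testable without access to
restricted donor data.

## Quantities and models

**Heteroplasmy fraction (HF)** is the fraction of reads carrying the
alternate allele at a site. Operationally a site is *absent* below 2%,
*heteroplasmic* between 2% and 98% (95% in single-cell RNA-seq, where depth
is lower), and *homoplasmic* above. The 2% detection floor reflects the
reproducibility limit of variant detection at roughly 1000–2000-fold
coverage.

**Variant classification.** For each fibroblast→iPSC pair, a variant is
*shared* (detected ≥2% in both, heteroplasmic in at least one), *lost*
(heteroplasmic in the fibroblast, undetected in the iPSC) or
*iPSC-specific* (detected in the iPSC, undetected in the fibroblast).
Variants homoplasmic in both members are inherited haplogroup markers and
are not classified. When two iPSC lines derive from one fibroblast, the
unique fibroblast heteroplasmies partition into shared-both / shared-one /
lost-both, and the unique iPSC variants into specific-both / specific-one.

**Heteroplasmic shift.** For shared variants the shift is
`HS = log2(HF_iPSC / HF_fibroblast)` — a fold change rather than an absolute
difference, because doubling from 2% to 4% and from 50% to 52% are very
different events on the natural (logistic) scale of heteroplasmy drift.
Shifts above 6 are flagged extreme. Direction (increase vs decrease) is
tested with a two-sided exact binomial test against 0.5 and a
Clopper–Pearson interval.

**Mutation rate.** The iPSC-specific rate is
`events / (16,569 × n_lines)` per base pair per genome per reprogramming,
with an exact Poisson 95% interval. Apparent iPSC-specific variants whose
founder fibroblast shows *any* non-zero allele fraction in the unfiltered
calls are rescued as pre-existing before counting. The per-molecule rate
divides by a copies-per-cell normaliser that must be supplied explicitly:
the published per-genome and per-molecule figures imply two different
normalisers (≈46 and ≈31), so the package refuses to guess one.

**Signatures.** Substitutions are expressed with a pyrimidine reference base
(C>A, C>G, C>T, T>A, T>C, T>G) and the strand that carried the pyrimidine.
The 96-class spectrum adds the 5′ and 3′ neighbours (circular at the
origin) and normalises counts by the trinucleotide frequency of each strand
of the reference, giving context-normalised rates; the 6-class regional
display reports relative frequencies. Cohort spectra are compared class by
class with two-sided Fisher tests combined by Stouffer's method. Because a
two-sided p of 1 must map to no evidence (Z = 0), two-sided inputs are
transformed as `z = qnorm(1 - p/2)`; one-sided inputs use
`z = qnorm(1 - p)`. Identical spectra therefore combine to p = 0.5, and two
one-sided p = 0.05 give Z = 2.326.

**Age models.** Per-line heteroplasmy burden and logit mean HF are
regressed on donor age, sex and macro-haplogroup by ordinary least squares
(four models: burden and HF in fibroblasts and iPSCs). Shift direction is
modelled by logistic regression on logit founder HF, region class (D-loop
reference level), haplogroup and age; complete separation is flagged rather
than silently reported.

**Single cells.** Cells are staged from collection day and pseudotime
(iPSC: day 0; mesendoderm: day 1–2 with pseudotime in [0.15, 0.5);
definitive endoderm: day 2–3 above 0.7; boundary values 0.5 and 0.7 fall to
*undefined*, following the interval wording of the stage definitions).
Pseudo-bulk HF is the zero-inclusive mean across cells and equals carrier
proportion × mean carrier HF whenever non-carriers are exactly zero.
Lineages are recovered by average-linkage hierarchical clustering of the
cells × variants HF matrix cut at an absolute Euclidean height.

**Expression.** Variable genes are ranked by deviation above a robust
loess mean–variance trend on log-normalised expression. Variance components
for stage, batch and line are random effects in a linear mixed model
(`lme4`), with the per-cell mean nonsynonymous HF entering as a fixed
effect whose share is the variance of its fitted component; within a single
line the model reduces to least squares and the HF share to R².
Differential expression between mtDNA-genotype groups uses a per-gene
linear model on log-normalised expression with stage covariates and limma's
moderated statistics, Benjamini–Hochberg adjusted. These are deliberately
simple, explicitly documented replacements for the heavier hurdle-model
machinery sometimes used on single-cell data: the behaviour that matters —
null calibration and recovery of injected effects — is what the test suite
pins down.

## The reference model

Coordinates are 1-based and circular; the control region (D-loop) wraps the
origin, spanning 16024–576 (1122 bp). The bundled annotation uses the
canonical human mtDNA gene coordinates; protein-coding positions are
translated with the vertebrate mitochondrial genetic code in the annotated
frame and orientation, with terminal partial codons padded with `A`
(completion of the stop codon by polyadenylation). Where protein genes
overlap (ATP8/ATP6, ND4L/ND4) the gene first in genomic order decides the
reported class and the alternative consequence is kept as a diagnostic.
Low-complexity tracts (66–71, 300–316, 513–525, 3106–3107, 12418–12425,
16182–16194) are excluded from calling.

The package does not distribute the rCRS sequence itself; it ships a
**synthetic** 16,569-bp sequence with rCRS-like base composition,
homopolymer tracts at the low-complexity intervals, and fixed reference
alleles at the hotspot and pathogenic anchor sites, so the bundled site
lists are consistent. Any single-record FASTA of the correct length can be
supplied instead, and all coordinate-dependent behaviour is identical. The
D-loop subregion table (MT-OHR, MT-LSP, MT-CSB1…) is user-editable; lookup
returns the smallest containing interval, so m.414 resolves to the L-strand
promoter. The bundled pathogenic-site list contains well-known confirmed
pathogenic point mutations and is intended to be replaced by the user's
curated list.

Which physical strand the reference FASTA represents is a convention, not a
fact recoverable from the file; `mitodyn` treats it as the L strand by
default and every signature function takes a `fasta_strand` argument to
flip it.

## What the synthetic cohort emulates

`sim_params()` fixes the study conditions: 146 donors aged 27–77; burden
Poisson with mean `2.8 + 0.10 × age` (slope matching the fibroblast
age-accumulation estimate); heteroplasmy fractions from Beta(1.3, 12.8)
truncated at 2% (mean ≈ 9%, an implicit model of clonal expansion — no
cell-division process is simulated because only HF distributions are
consumed downstream); region-weighted placement with D-loop (2.2×) and rRNA
(1.6×) enrichment; recurrent hotspots m.414 (19.2% of lines), m.2623 and
m.13369 (12.3%); three inherited homoplasmies per donor.

Reprogramming passes each heteroplasmy through a binomial bottleneck
`p′ = B/N`, `B ~ Binomial(N, p)` with `N = 5` segregating units by default —
the bottleneck size is not identifiable from published summaries, so a
single small value producing rapid segregation of the right order was fixed
and is not tuned. De novo mutations arrive as Poisson(8.62 × 10⁻⁵ × 16,569)
events per line; classes are drawn from configurable 6-class signature
weights (then a site uniformly within the class), and founding HFs come
from Beta(1, 30) truncated at 2% — the real founding spectrum is unknown,
so the generator only models the detection-capable tail. A consequence
worth knowing: because simulated founding HFs never fall below the
detection floor, lowering the iPSC detection threshold in
`threshold_sensitivity()` barely increases the synthetic rate, whereas on
real data sub-threshold variants produce a severalfold rise.

Read-level noise is Binomial(depth, HF) with gamma-distributed depth
(mean 1824, sd 2249) split binomially between strands. Single cells get
latent clones; a sub-homoplasmic variant belongs to one clone at HF
`min(1, HF_bulk / clone frequency)` so pseudo-bulk recovers the bulk truth;
near-homoplasmic variants are ancestral in all clones. Expression is
negative binomial with a log-linear HF effect on a configurable set of
genes, plus optional stage/batch random effects.

What the generator does *not* emulate: NUMT contamination, alignment and
caller artefacts beyond a flat error-site rate, depth heterogeneity along
the genome, transcriptome-driven cell typing, and real linkage between
variant age and HF. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
artefact of real sequencing data.

## Numerical choices and degenerate inputs

* Filters run in a fixed order (SNV → AF → depth → strand → low-complexity
  → RNA artefacts) so per-rule removal counts are reproducible; the report
  always reconciles to the input row count, and filtering is idempotent.
* Contamination screening calls two samples similar when they share more
  than 10 heteroplasmies with |ΔHF| ≤ 0.05; the tolerance is configurable
  because the underlying criterion is not standardised.
* `heteroplasmic_shift()` refuses zero HFs rather than flooring them:
  shifts are defined for shared variants only, and lost/specific variants
  are reported by category, not by pseudo-counted shifts.
* Logit transforms clamp HFs to [10⁻⁶, 1 − 10⁻⁶].
* Single-level covariates are dropped from regressions with a warning;
  an all-increase shift table returns an empty coefficient table with a
  separation flag.
* The lineage dendrogram is cut at an absolute Euclidean height
  (default 0.5): below the separation produced by one homoplasmic marker,
  a clone-free line stays a single cluster. The embedding defaults to
  deterministic principal components; UMAP (via `uwot`) is available with a
  recorded seed when stochastic neighbourhood embedding is preferred.
* Stouffer combination skips classes with all-zero margins and reports
  them.

## Problem sizes used in the test suite

The shipped tests exercise the cohort at its natural scale where that is
cheap (146 donors, 141 derived lines, 10⁵-row call tables, 10⁴ bottleneck
replicates, 50-replicate rate-recovery and 20-replicate slope-recovery
calibrations) and at a few hundred cells / genes for the single-cell and
expression modules, which keeps the full suite at roughly a minute while
leaving the calibration properties statistically sharp.

## Known limitations

* The NS/SS ratio of simulated de novo variants reflects the mutational
  opportunity of the genetic code under the chosen signature weights; the
  generator does not model selection, so the elevated NS/SS ratios seen in
  real iPSC data are not reproduced by simulation — only the formula is.
* Cohort descriptive means (burden, mean HF, the published headline rate)
  depend on the real donor cohort and are not targets of the synthetic
  build; the formulas that produce them are exported and tested.
* Haplogroup assignment, pseudotime inference, alignment and base-level
  calling are out of scope: haplogroups, pseudotime and variant calls are
  inputs.
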