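# mitodyn

Mitochondrial DNA heteroplasmy dynamics through cell reprogramming and
differentiation.

Human cells carry many copies of the 16,569-bp mitochondrial genome, and
somatic mutation creates mixed allele populations (heteroplasmy) whose
fractions drift when fibroblasts are reprogrammed into induced pluripotent
stem cells (iPSCs). `mitodyn` is an R package for analysts working with
deep-sequencing mtDNA variant calls from such experiments. It implements:

* **Quality control** — the variant filters (SNV-only, allele fraction ≥ 2%,
  depth ≥ 200×, ≥ 2 minor-allele reads per strand, low-complexity masks,
  RNA artefact sites), sample-level depth/contamination rules, and the
  five single-cell filters.
* **Pair dynamics** — classification of variants across fibroblast→iPSC
  pairs and duos (shared / lost / iPSC-specific), the heteroplasmic shift
  `HS = log2(HF_iPSC / HF_fibroblast)`, exact binomial direction tests with
  Clopper–Pearson intervals, the iPSC-specific mutation rate
  `events / (16,569 × n_lines)` with exact Poisson intervals and
  sub-threshold rescue, NS/SS ratios, region mutation frequencies with
  Fisher enrichment, relative copy number `CN = 2 × DP_mt / DP_autosome`,
  and the burden/HF-on-age and shift-direction regression models.
* **Mutational signatures** — strand-resolved 6- and 96-class spectra with
  trinucleotide-context normalisation on the circular genome, cohort
  comparison by per-class Fisher tests combined with Stouffer's method, and
  correlation against external signature matrices.
* **Single cells** — stage assignment from collection day and pseudotime,
  pseudo-bulk heteroplasmy, carrier statistics, binned mutation
  frequencies, cross-stage concordance, and mtDNA-based lineage clustering.
* **Expression association** — variable-gene selection, variance
  partitioning (stage / batch / line / mean nonsynonymous heteroplasmy),
  and differential expression between mtDNA-genotype-defined sub-clones.
* **A synthetic cohort generator** — age-dependent fibroblast burden,
  beta-distributed heteroplasmy fractions, region-weighted placement with
  recurrent hotspots, a binomial reprogramming bottleneck with
  signature-driven de novo mutations, binomial read noise, and single cells
  with clone structure and variant-linked expression effects — so the full
  pipeline runs and is tested without restricted cohort data.

The package ships a synthetic 16,569-bp reference sequence (the rCRS itself
is not redistributed) with the canonical gene annotation; any single-record
FASTA of the right length can be substituted via `load_reference()`.

## Worked example

```r
library(mitodyn)

ref    <- mito_reference()
params <- sim_params()            # 146 donors, slope 0.10/yr, N = 5, ...

fib <- simulate_fibroblast_cohort(ref, params, seed = 1)
ips <- simulate_reprogramming(fib$truth, fib$samples, ref, params,
                              n_ipsc_per_donor = 1, seed = 2)

fib_calls <- simulate_read_counts(fib$truth, ref, params, seed = 3)
ips_calls <- simulate_read_counts(ips$truth, ref, params, seed = 4)
samples   <- rbind(cbind(fib$samples, fibroblast_line = NA), ips$samples)

res <- run_pipeline(run_config(fibro_calls = fib_calls,
                               ipsc_calls = ips_calls,
                               samples = samples,
                               fibro_calls_unfiltered = fib_calls), ref)

round(100 * res$summary$lost_fraction, 1)
#> [1] 67
res$rate
#> RateEstimate: 143 events / 146 lines -> 5.91e-05 per bp per genome
#>   (95% CI 4.98e-05-6.96e-05)
direction_binomial(sum(res$shifts$hs > 0), nrow(res$shifts))$ci_low
#> [1] 0.8775221
```

Here two-thirds of the fibroblast heteroplasmies are lost through the
simulated five-unit bottleneck, the synthetic de novo events are recovered
at a rate close to the configured 8.62 × 10⁻⁵ per bp per genome (the
shortfall is the sub-threshold rescue removing events that collide with
low-level founder calls), and shared variants predominantly increase in
heteroplasmy — the hallmark of a reprogramming bottleneck.

On real data, replace the simulated tables with calls read by
`read_variant_table()` (TSV or VCF with `AF`/`DP`/`ADF`/`ADR` fields) and a
sample sheet with `line_id`, `donor_id`, `tissue`, `age`, `sex`,
`macro_haplogroup` and, for iPSC lines, `fibroblast_line`.

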