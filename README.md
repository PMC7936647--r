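# exposig

Mutational-signature analysis of chemical-exposure experiments and tumor
cohorts, built around the comparison of solvent-control and treated
samples. `exposig` takes somatic variant calls (VCF), builds mutation
catalogs over the three canonical category schemes — SBS96 (single base
substitutions in trinucleotide context, pyrimidine-strand collapsed),
DBS78 (doublet base substitutions) and ID83 (small insertions/deletions
stratified by homopolymer, tandem-repeat and microhomology context) —
refits them against reference signature matrices, removes baseline
(culture/solvent) signatures measured in a control sample, and projects
tumor-cohort spectra onto the resulting exposure signature.

It is aimed at analysts studying environmental or experimental mutagens
(e.g. plasticizer-derived compounds such as bisphenol A or styrene
oxide) who have caller output in hand and want a tested, reproducible
path from VCFs to signature weights and cohort-level statistics, plus a
deterministic simulator to validate every stage without sequencing data.

## The model

A sample's catalog is a count vector `m` over a scheme's categories.
Given a column-stochastic reference matrix `P` (one signature per
column), refitting estimates non-negative weights `w` minimizing

```
|| P w − m / Σm ||²   subject to  w ≥ 0,  Σw ≤ 1
```

by iterative forward selection: the signature whose optimal single
weight most reduces the squared error is added, all selected weights are
re-optimized jointly, selection stops when the improvement falls below
`1e-3`, and weights under `0.06` are zeroed (then re-optimized).

Baseline removal follows the maximum-a-posteriori attribution rule: with
fitted weights `w`, each category `c` is attributed to the signature

```
argmax_s  w_s P(c | s) / Σ_s' w_s' P(c | s')
```

and categories attributed to baseline signatures — those fitted in the
solvent-only control — are zeroed (a posterior-weighted soft mode is
available). Cohort analytics use cosine similarity between spectra,
centered PCA of the 96-dimensional frequency vectors, ordinary least
squares of similarity on patient age, and exact (enumerated) or
tie-corrected normal Mann–Whitney tests between cohorts. Context-wise
mutation rates are counts normalized by the merged length of each
genomic compartment, reported on a log10 scale.

## Worked example

Simulate a solvent-control plus treated replicates (the default
conditions: 200 kb reference, control of 300 mutations from two baseline
signatures, treated replicates of 600 mutations drawing half from an
exposure signature), then recover and isolate the exposure signature:

```r
library(exposig)

cfg  <- simulation_config(seed = 7)
pair <- simulate_pair(cfg)
g    <- pair$genref$genome

ctl <- build_catalog(pair$control$records,    g, "SBS96")
trt <- build_catalog(pair$treated[[1]]$records, g, "SBS96")

refit(ctl, cfg$signature_set)
#> <refit_result> 2 active signatures; residual SSE 0.002549; unattributed 0
#>   SYN1   SYN2
#> 0.6577 0.3423
refit(trt, cfg$signature_set)
#> <refit_result> 3 active signatures; residual SSE 0.001423; unattributed 0
#>   SYN3   SYN1   SYN2
#> 0.4867 0.2708 0.2425

base_fit <- refit(ctl, cfg$signature_set)
baseline <- names(base_fit$weights)[base_fit$weights > 0.06]
att  <- attribute_and_subtract(trt, cfg$signature_set, baseline)
expo <- cfg$signature_set$profiles[, "SYN3"]
cosine_similarity(catalog_frequency(trt), expo)                   # 0.775
cosine_similarity(catalog_frequency(att$adjusted_catalog), expo)  # 0.969
```

The control fit recovers the baseline mixture (true weights 0.6/0.4);
the treated fit recovers the planted 0.5 exposure admixture (0.487); and
MAP baseline subtraction moves the treated spectrum from cosine 0.775 to
0.969 against the pure exposure signature.

A command-line wrapper (`exec/exposig`) exposes the stages as
subcommands (`simulate`, `filter`, `catalog`, `refit`, `attribute`,
`context`, `cohort`) driven by a YAML config, writing a run manifest
whose hash is identical across reruns of the same config and seed.

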