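---
title: "Exposure mutational signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure mutational signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposig)
```

# Overview

`exposig` implements the analysis path from somatic variant calls to
exposure-signature estimates: a filtering cascade, catalog construction
over the SBS96/DBS78/ID83 schemes, non-negative signature refitting,
maximum-a-posteriori (MAP) baseline subtraction, genomic-context
mutation-rate normalization, and cohort analytics. This vignette records
the scientific model behind each stage, the tunable parameters and their
defaults, what the bundled simulator does and does not emulate, and the
design decisions taken where more than one reading was defensible.

# Variant filtering

Caller output is filtered by a fixed cascade: caller quality, read depth
in both treated and control samples, alt-supporting reads, a doublet
allele-balance window, blacklist overlap, and removal of variants shared
between samples. Defaults are `min_qual = 40`, `min_depth = 20`,
`min_alt_support = 4` — stringent somatic-calling practice for ~35x
whole genomes. Two readings were genuinely open and are resolved as
follows:

* **Quality threshold direction.** "Filter at quality 40" is read as
  *remove* calls with quality `< 40` (keep `>= 40`): keeping sub-40
  calls would be the opposite of a stringent filter. The boundary call
  at exactly 40 survives, as the toy fixture exercises.
* **Doublet allele-balance predicate.** The allele-balance rule for
  doublet calls has ambiguous operator precedence when written as a
  one-line expression. It is implemented as a removal predicate with
  explicit parenthesization — remove if `depth < 20`, or
  `0.01 < AB < 0.25`, or `AB > 0.75` — i.e. keep confident heterozygous
  (`0.25 <= AB <= 0.75`) and reference-like (`AB <= 0.01`) calls. All
  four constants sit in `filter_policy()` and can be overridden; the
  chosen parenthesization is a package decision, not an external given.
* **One policy for all classes.** The same quality/depth/support policy
  applies to SNVs and indels; nothing in the upstream contract
  distinguishes them.

Removals are attributed to the *first* failing criterion in cascade
order, so per-criterion counts are reproducible; since the kept set is a
conjunction, order affects attribution only, never the survivors —
which is also why filtering is idempotent. Records missing a field the
policy tests raise an error rather than passing silently.

Coordinates follow the Bioconductor convention internally (1-based
inclusive `GRanges`); BED input is 0-based half-open and the shift
happens once, inside the `rtracklayer` importer. Shared-variant removal
keys on exact `(chrom, pos, ref, alt)` identity.

# Catalog construction

**SBS96.** Every substitution is reported on the pyrimidine strand:
purine-reference calls are reverse-complemented, flanks swapping roles.
Adjacent SNV pairs in the same sample are first merged into doublets and
excluded from the SBS96 catalog, so a doublet is never double-counted as
two substitutions; runs of three or more adjacent SNVs are set aside as
neither. Merge-first is a package decision — the alternative (cataloging
doublets and their component SBS both) inflates SBS counts at doublet
sites.

**DBS78.** Both-base-changed doublets are collapsed by reverse
complement onto ten canonical reference doublets; for the four
palindromic references the lexicographically smaller of the alternate
and its reverse complement is reported. The mapping is a lookup table
built by exhaustive enumeration of all 144 both-base-changed doublet
substitutions at load time; the test suite confirms exactly 78
equivalence classes.

**ID83.** Indels are reduced to their pure inserted/deleted unit
(shared VCF anchor bases stripped) and left-normalized against the
reference before classification, so caller alignment dialect cannot
change the label. One-base events are pyrimidine-collapsed and binned by
the homopolymer run length of the affected base, *including* the deleted
base itself — deleting one T from a run of six lands in the 6+ bin
(`1:Del:T:5`). Longer events are binned by tandem copy number of the
unit; single-copy deletions fall back to junction-microhomology bins
(longest overlap between the deleted unit's ends and the flanking
sequence, capped below the unit length). Labels follow the COSMIC ID83
naming so published matrices can be used directly.

Records whose context contains `N` are excluded from counts and reported
separately; catalogs expose a mutations-per-Mb burden when a callable
length is supplied.

# Signature refitting

Refitting minimizes the squared error between the catalog frequency
vector and a non-negative combination of signature columns, subject to
the weights summing to at most 1. The reference algorithm is iterative
forward selection — add the signature whose optimally chosen single
weight most reduces the error, then re-optimize all selected weights
jointly — because greedy selection with re-optimization reproduces the
behavior analysts expect from the widely used refitting tools and yields
sparse, interpretable weight sets. The joint re-optimization is a cyclic
coordinate descent whose per-coordinate update is the exact constrained
1-D minimizer, so the objective is non-increasing on the convex feasible
set.

Tunables: selection stops when the error improvement falls below
`tol = 1e-3`; weights below `cutoff = 0.06` are zeroed. Whether to
re-optimize the surviving weights after the cutoff is not externally
fixed, so both behaviors are exposed
(`reoptimize_after_cutoff`, default `TRUE`). The test suite checks the
forward-selection result against an independent constrained
least-squares solve (`pracma::lsqnonneg`) on the same active set, to
`1e-4` in error — the dual-route check that guards the implementation.

# Baseline attribution subtraction

With fitted weights `w`, the posterior of signature `s` at category `c`
is `w_s P(c|s) / Σ_s' w_s' P(c|s')` over the actively fitted signatures.
Each category is attributed to its MAP signature; categories attributed
to baseline signatures — those refitted with weight above the cutoff in
the solvent-only control catalog — are zeroed. Hard zeroing is the
default because the attribution semantics assign each context to exactly
one signature; a soft mode subtracting the posterior-weighted expected
baseline count per category is available behind a flag. Categories with
zero probability under every active signature have no posterior; they
pass through unadjusted and are flagged, as are posterior ties, which
are broken by signature name order (with a `1e-9` tolerance so
floating-point noise cannot hide an exact tie).

# Context rates

Per compartment, the rate is the mutation count divided by the merged
interval length, reported as `log10`. Tracks may be declared as a
partition (each record counts once across the track set) or as overlays
(independent annotations); both occur in practice — genomic element
versus replication timing versus nuclear localization — and nothing in
the rate definition distinguishes them, so the package treats any BED
set as a context and leaves exclusivity to the caller's track design.
Zero-count compartments report an explicit undefined (`NA`) log-rate
rather than `-Inf` or a pseudocount, so downstream plots and tests must
handle missingness explicitly.

# Cohort analytics

The exposure profile is the *mean* of the treated replicates' frequency
vectors (replicates weighted equally, matching how replicate spectra are
usually averaged for display); pooling counts instead — which weights
replicates by burden — is available via `method = "pooled"`. Cosine
similarity projects each tumor catalog onto the profile. PCA is centered
but not scaled: all 96 features share units, and correlation-mode
scaling would inflate sparse categories; component signs are fixed by
making the largest-magnitude loading positive. Age regression is
ordinary least squares of similarity on age with a two-sided t-test on
the slope. The Mann–Whitney cohort contrast uses exhaustive enumeration
of group assignments for `m + n <= 12` (exact even under ties) and the
tie-corrected normal approximation without continuity correction above
that; the switch point keeps the enumerated case at most `C(12, 6) =
924` assignments.

# The simulator

`simulate_pair()` emulates the study design the pipeline targets: a
solvent-control sample drawn from a baseline signature mixture and
treated replicates drawing part of their mutations from an exposure
signature. Defaults are fixed once as the package's study conditions: a
200 kb reference at 41% GC (the human genome-wide value) with planted
homopolymer and short-tandem-repeat tracts at 2 per kb; five synthetic
signatures with pairwise cosine below 0.3 (well-separated, so mixture
weights are identifiable); baseline weights 0.6/0.4 over two signatures;
300 control and 600 treated mutations per sample with a 0.5 exposure
fraction — hundreds of mutations per sample, the order of magnitude a
low-burden exposure experiment yields, while large enough for stable
refitting. Caller annotations are drawn from simple parametric
distributions (normal quality around 70, Poisson depth around 35,
binomial alt support) so the filter cascade has realistic material to
remove; read-level error processes are deliberately not modeled, since
the pipeline starts at variants.

Mutations are placed at index-matched trinucleotide positions without
collisions and with a one-base buffer (two placed SNVs can never form an
accidental doublet), which is what makes VCF-to-catalog round-trips
exact and lets the truth tables serve as generative oracles. All
randomness flows from one seed; artifacts are byte-identical across
reruns.

`simulate_cohorts()` generates per-sample catalogs whose exposure
admixture is `base + slope × (age − age_min)`, clipped to `[0, 1]` with
a warning, plus SV tables drawn from per-cohort class proportions. The
default two cohorts (50 samples each, ages 30–80, admixture 0.2 rising
at 0.006/year versus a flat 0) produce a detectable but not trivial age
trend and cohort contrast.

What passing tests on these simulations demonstrate is internal
consistency and statistical calibration of the method — parameter
recovery, attribution efficacy, test calibration — not fidelity to any
particular experiment: real exposure data have correlated error
processes, germline contamination, copy-number structure and signature
collinearity (real COSMIC signatures can be highly correlated) that the
well-separated synthetic signatures intentionally avoid.

# Problem sizes and budgets

The test suite and the acceptance script size their simulations to what
the questions need: 10,000 fuzzed mutations against a 100 kb genome for
classifier/oracle equivalence; 200 replicates of n = 20,000 multinomial
draws for refit recovery; 100 control/treated pair simulations for the
attribution-improvement property; 500 replicates for null-slope
calibration. These sizes give the relevant binomial checks narrow
confidence bands while keeping a full run in minutes on one CPU.

# Known limitations

* No de novo signature extraction (NMF); only refitting against a
  supplied matrix.
* No transcription-strand (192-context) classification and no
  clustered-mutation (kataegis) handling.
* DBS detection from VCF merges immediately adjacent same-sample SNVs;
  doublets split across samples or phased further apart are out of
  scope.
* Context tracks are taken at face value as BED interval sets; no
  enrichment testing between contexts is provided, only descriptive
  rates.
* The command-line layer covers the simulate-to-cohort path used by the
  reproducibility scripts; bring-your-own-data runs use the R API
  directly.
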