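Package: exposig
Title: Exposure Mutational-Signature Analysis from Somatic Variant Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds SBS96, DBS78 and ID83 mutation catalogs from filtered
    somatic variant calls, refits them against reference (COSMIC-style)
    signature matrices by non-negative forward selection, removes
    baseline (solvent-control) signatures by maximum a posteriori
    per-context attribution, normalizes mutation rates by genomic-context
    track length, and runs cohort-level analytics (cosine-similarity
    projection onto exposure spectra, PCA, age regression, Mann-Whitney
    cohort contrasts, structural-variant class proportions). Includes a
    deterministic simulator that generates reference sequence, signature
    mixture VCFs, control/treated sample pairs, context tracks and
    cohorts so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
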