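Package: mtdsrna
Title: Quantification and Characterization of Mitochondrial Double-Stranded RNA
Version: 0.1.0
Authors@R:
    person("mtdsrna", "maintainers", email = "mtdsrna@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mitochondrial double-stranded RNA (mtdsRNA)
    from stranded short-read RNA-seq and long-read dsRNA immunoprecipitation
    sequencing (J2 RIP-seq). Computes strand-stratified mitochondrial read
    fractions, per-base strand-specific normalized coverage, quartile-based
    sample stratification into high/intermediate/low mtdsRNA tiers, per-feature
    long-read counts with featureCounts-style overlap semantics, and an A-to-I
    RNA editing-site caller that cross-references RNA pileups against DNA
    replicate evidence. A deterministic synthetic-data generator (genome,
    annotation, stranded read pairs, RIP-seq-like long reads, editing
    injections, DNA evidence, nuclear decoy) makes every stage testable
    offline with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
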