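Package: EpiMutSig
Title: UV-Signature and Epigenetic-Regulator Mutation Analysis for
    Targeted Cancer Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of somatic mutation calls from targeted
    cancer gene panels, built around cutaneous melanoma cohorts.  Reads
    MAF-like tables and minimal VCF, applies tumor-only QC and germline
    filters, classifies coding consequences against toy transcript
    models, merges adjacent substitutions into dinucleotide events,
    classifies every event by ultraviolet mutational signature (single
    C>T, tandem CC>TT, C>T within a dinucleotide, G>T), annotates
    epigenetic-regulator genes by functional category, and produces
    cohort tallies, gene rankings, exact binomial confidence intervals
    and the comparative statistics (two-proportion z, chi-square,
    two-sample t) needed to test whether epigenetic regulators are
    enriched for mutations and for UVB-signature damage.  A seeded
    synthetic-cohort generator with ground-truth labels makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SomaticMutation, VariantAnnotation, Sequencing
Collate: 
    'EpiMutSig-package.R'
    'AllClasses.R'
    'cohort-stats.R'
    'consequence.R'
    'mutation-io.R'
    'qc-filter.R'
    'report.R'
    'simulate.R'
    'stats-tests.R'
    'uv-signature.R'
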