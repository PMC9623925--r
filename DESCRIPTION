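Package: cnvTriage
Title: Triage and Candidate-Gene Prioritization for Clinical CNV Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reusable pipeline for triaging chromosomal-microarray copy number
    variant (CNV) calls in clinical cohorts such as syndromic congenital heart
    disease. Stages: exclusion of aneuploidies and gross chromosomal
    aberrations, removal of common population CNVs by reciprocal-overlap
    matching against a DGV-style database, pathogenicity classification by a
    three-source consensus (MVP score bins, DECIPHER-style region verdicts,
    OMIM-style gene evidence), CNV-to-gene mapping, multi-tool candidate-gene
    consensus, phenotype-spectrum summaries, and cohort-level reporting
    (diagnostic yield, CHD categorization, chromosome and size distributions).
    Includes seeded synthetic-cohort generators with planted ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: CopyNumberVariation, GenomicVariation, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
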