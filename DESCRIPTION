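Package: kleptoscreen
Title: Alien Index Screening, Gene-Model Curation, and Developmental
    Expression Analysis for Kleptoplastic Sea Slug Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening draft sea slug (Sacoglossa) genome
    assemblies for contamination and horizontal gene transfer using the
    Alien Index, for curating gene models from masked and unmasked
    annotation runs, for developmental-stage differential expression with
    TMM normalization and a negative-binomial conditional exact test, for
    orthogroup presence/absence pattern analysis with hypergeometric
    functional enrichment, and for support-aware phylogeny
    post-processing (midpoint rooting, low-support collapsing, automated
    donor-clade checks). Includes a fully deterministic synthetic study
    generator with recorded ground truth so the complete pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    GenomeInfoDb,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
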