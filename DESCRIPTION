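Package: riboactivity
Title: Paired rDNA/rRNA Amplicon Activity Analysis for Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired 16S rDNA/rRNA amplicon surveys in which the
    rRNA:rDNA ratio of a taxon is used as a proxy for its metabolic activity.
    Provides count-table ingestion and rarefaction, taxon aggregation,
    abundance-activity ratio computation with four-quadrant classification
    of phylum-sample values, detection of rRNA-only features, alpha and beta
    diversity with PCoA ordination, UPGMA clustering and PERMANOVA, RPKM/TPM
    normalization for genome-resolved (MAG) expression summaries, and a
    synthetic paired-community simulator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    ape
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
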