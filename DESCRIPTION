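Package: ishannot
Title: Ordinal Tissue Expression Annotation Analysis for ISH Atlases
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing gene-by-tissue ordinal expression annotation
    matrices from in situ hybridization (ISH) screens. Provides a five-state
    annotation store (not analyzed, negative, weak, medium, strong) with
    per-tissue summary statistics, Boolean "sieve" filtering of genes by
    tissue-level expression predicates with gene-list set algebra,
    Spearman-distance tissue dendrograms built by neighbor joining with
    Newick export, confidence-thresholded protein-interaction neighborhood
    extraction at three zooming levels, GO fold-enrichment ratios between
    gene lists, morbidmap disease linkage, and a synthetic data generator
    that emulates the statistical structure of an annotated ISH atlas so
    every analysis is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
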