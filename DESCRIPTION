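Package: fsomtype
Title: Shape-Based Typing of DNA Methylation Profiles at Alternative-Splicing Event Borders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Groups alternative-splicing events (skipped exons and retained
    introns) by the shape of their DNA-methylation profiles around the
    exon-intron borders. Profile similarity is measured by dynamic time
    warping (optionally restricted to a Sakoe-Chiba band), clustering is
    performed with a self-organizing map whose variable-length prototypes
    can locally grow and shrink through accumulator-triggered index shifts,
    and the number of clusters is chosen by a light-weight consensus
    procedure based on the area under the consensus-matrix CDF. Downstream
    utilities associate the resulting clusters with splicing properties
    (inclusion level, expression, lengths) via Mann-Whitney tests, test
    splicing-motif enrichment with hypergeometric tests, and consolidate
    clusterings across samples by hierarchical meta-grouping of cluster
    median profiles. Includes seeded generators of synthetic methylation
    tracks and event tables so the full pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    ape,
    limma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
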