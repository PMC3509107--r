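Package: motifforge
Title: Unconstrained Transcription Factor Binding Motif Discovery from
    Multi-Species Promoter Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-scale, ab initio discovery of transcription factor
    binding motifs (TFBMs) from multi-species promoter alignments. Compiles
    dictionaries of conserved "DNA words" using conservation-curve and
    species-permutation-prefix filters, clusters words into motif
    predictions under a run-aware conglomerate distance, screens candidate
    clusters with a rank-based dynamic dimension selection (DDS) one-class
    filter, validates predictions against known position weight matrices,
    mines combinatorial binding patterns ("motifs of motifs") across
    promoters with a center-star alignment of motif occurrence strings, and
    annotates predictions by hypergeometric GO-term enrichment. Ships a
    synthetic alignment generator with planted motifs and planted
    combinatorial patterns so the whole pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
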