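Package: antcomp
Title: Comparative Antennal Transcriptome Profiling and Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of de novo antennal
    transcriptomes of non-model arthropods: sanitization of 454-style
    sequencing reads (internal linker splitting, taxonomic contaminant
    screening from homology hit tables), assembly summary statistics
    (N50, length histograms, coverage filtering), level-wise Gene
    Ontology term profiling with true-path propagation and manual
    annotation overrides, cross-species profile comparison (Pearson
    similarity, term overlap, binned percentage differences), and
    cutoff-based screening for chemosensory and immune gene-family
    candidates including an ionotropic-receptor dendrogram-readiness
    filter. A synthetic-data generator produces all pipeline inputs
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
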