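Package: kelpfold
Title: Hi-C Three-Dimensional Genome Architecture Analysis for Compact
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the three-dimensional folding of compact
    (algal-sized) genomes from Hi-C contact data: binning of read pairs,
    iterative matrix balancing, distance-expected and observed/expected
    maps, contact-probability curves with interaction decay exponent
    fitting, A/B compartment calling from the leading eigenvector with
    GC-based sign orientation and male/female compartment-switch tables,
    centromere-centred aggregate chromosomal analysis with
    centromere/telomere clustering scores and Rabl classification,
    diamond insulation profiles with boundary detection, Hi-C plus
    repeat-annotation centromere localisation, telomeric tract detection,
    and compartment-by-chromatin/expression statistics. A seeded
    synthetic-data generator with planted architecture ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
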