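Package: empiricscan
Title: Fitness Landscapes from EMPIRIC Deep Mutational Scanning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for bulk-competition deep mutational scanning of the
    EMPIRIC type: simulation of saturation-mutagenesis growth competitions
    with time-stamped barcoded reads, stringent read filtering and codon-level
    variant counting, estimation of raw fitness as the log2 enrichment slope
    and of stop-codon-normalized selection coefficients, cross-orthologue
    fitness-landscape correlation statistics with Kolmogorov-Smirnov and
    permutation tests, structural stratification of the distribution of
    fitness effects, transformative-mutation analysis, and principal component
    analysis of mutational-scan and alignment-frequency matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, Genetics, Software
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
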