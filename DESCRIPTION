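Package: agosort
Title: Argonaute Sorting and Quantification of Mosquito Small RNA Libraries
Version: 0.1.0
Authors@R:
    person("agosort", "developers", email = "agosort@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for Argonaute-immunoprecipitation small RNA
    sequencing experiments in Anopheles gambiae and similar designs. Quantifies
    mature miRNA strands against precursor hairpins, curates miR/miR* strands,
    measures Ago1/Ago2 partitioning with Fisher-exact star-strand enrichment,
    profiles structural determinants of sorting (5' nucleotide composition,
    duplex base pairing), classifies isomiR 3' tailing and trimming variants,
    tests replicate-free differential loading over a blood-meal time course
    with an MA-plot z-test, applies novel-miRNA retention filters and
    reciprocal-best-hit conservation calls, and ships a ground-truth simulator
    of the 18-library (3 pools x 6 time points) Ago-IP design so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
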