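Package: facpred
Title: Transcriptomic and Fitness Correlates of Facultative Intraguild
    Predation in Blow Flies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying facultative intraguild predation
    in the blow fly Chrysomya rufifacies. Implements parameter-swept
    splicing-graph (compacted de Bruijn) transcriptome assembly with k-mer
    coverage cutoffs, adapter/quality read filtering, best-hit homology
    annotation, a nested negative-binomial likelihood-ratio test for
    differential expression between predator and nonpredator siblings,
    cross-assembly consensus gene tallies, and the stratified categorical
    survival statistics of the laboratory predation assays (Fisher exact,
    Cochran-Mantel-Haenszel, Breslow-Day, proportion z-tests). Includes a
    seeded synthetic-data generator (gene models, negative-binomial counts,
    paired-end FASTQ reads) so every pipeline stage is testable without
    external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    igraph,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
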