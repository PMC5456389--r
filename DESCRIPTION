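Package: denfreq
Title: Differential Expression Number Analysis of Drug-Perturbation
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-gene differential expression numbers (DEN) from a
    probe-by-sample log-fold-change matrix of drug-treated samples, partitions
    genes into frequently and rarely regulated sets, and compares the sets
    across genomic position, tissue expression specificity, developmental
    stage, evolutionary conservation, SNP and disease-SNP density, protein
    interaction degree and subcellular localization using nonparametric group
    statistics. Includes a seeded synthetic-data generator with configurable
    planted effects so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    data.table,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
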