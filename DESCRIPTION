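Package: mitoprofile
Title: Descriptive Profiling of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the descriptive analysis of circular insect
    mitochondrial genomes: gene-arrangement accounting (sizes, overlaps,
    intergenic nucleotides, gene-order signatures), nucleotide composition
    and AT/GC strand skews, codon usage (RSCU and codons-per-thousand under
    configurable genetic-code family partitions), control-region feature
    detection (homopolymer stretches, microsatellites, long direct repeats),
    gene-junction motif extraction and consensus, and heuristic tRNA
    cloverleaf folding with base-pair classification. Includes a seeded
    synthetic mitogenome generator with a ground-truth manifest so every
    stage of the pipeline can be exercised and validated without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
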