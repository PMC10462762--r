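Package: ligar
Title: Decoding and Quantifying Liquid Glycan Array Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end dry-lab readout for liquid glycan array (LiGA)
    experiments, in which DNA-barcoded M13 glycophages display N-glycans at
    controlled mean densities. Provides dictionary handling for silent double
    barcodes (SDBs) with genetic-code validation, demultiplexing of paired-end
    amplicon reads into per-clone count matrices, differential-enrichment
    testing with invariant-clone (spike-in) or TMM normalization under a
    negative-binomial model with Benjamini-Hochberg FDR control, MALDI-TOF
    quantification of coat-protein glycosylation (Gaussian peak fitting,
    sialic-acid ghost-peak correction, display-density estimation, enzymatic
    conversion time courses), and dissociation-constant estimation from
    native-MS titrations of the 1:1 binding equilibrium. Seeded synthetic-data
    generators for every input make all stages testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    zoo,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
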