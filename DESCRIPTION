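Package: ncRNAscout
Title: Discovery of Plant Pre-miRNA Hairpins, Long Non-Coding RNAs and
    miRNA Targets from Genome Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested pipeline for genome-wide annotation of plant
    non-coding RNAs. Pre-miRNA hairpins are discovered by exhaustive
    homology scanning of known mature miRNAs against a genome followed by
    a filter cascade over thermodynamic and sequence statistics: minimal
    folding energy index (MFEI), adjusted minimum free energy (AMFE),
    normalized Shannon entropy (NQ) and base-pair distance (ND) of the
    Boltzmann base-pairing ensemble, base-pairing propensity (Npb), and
    simple-sequence-repeat signature density (R). Long non-coding RNAs are
    identified by a length / ORF / coding-potential / protein-similarity
    cascade, and miRNA targets are predicted on coding transcripts and
    lncRNAs with an expectation-penalty complementarity score and
    target-site unpairing energy. A transparent additive-energy folding
    engine (minimum free energy by dynamic programming and a McCaskill-
    style partition function with base-pair probabilities) backs all
    folding statistics, with an exhaustive enumeration oracle for small
    sequences. Seeded synthetic genomes, transcriptomes and target sites
    with ground-truth ledgers allow the whole analysis to be benchmarked
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'energy-model.R'
    'folding.R'
    'features.R'
    'io.R'
    'ssr.R'
    'orf.R'
    'coding-scorer.R'
    'lncrna.R'
    'mirna-scan.R'
    'mirna-cascade.R'
    'targets.R'
    'synthetic.R'
    'pipelines.R'
    'utils.R'
    'zzz.R'
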