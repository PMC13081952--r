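Package: magbench
Title: Ecosystem-Mirroring Simulation and Base-Pair Evaluation of
    Metagenome-Assembled Genome Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark metagenome assembly and binning pipelines
    against a known ground truth. Builds a two-level (species / strain)
    ANI-clustered reference database, converts a sample's taxonomic profile
    into a "mirror specification" (a ground-truth genome set with strain
    structure and abundances matching the sample), simulates paired-end
    reads from it, establishes contig-to-genome ground truth from filtered
    BLAST tabular alignments, and scores every contig bin at base-pair
    resolution (recall, precision, F-score per ground-truth genome).
    Includes contig-level bias analyses (coverage and tetranucleotide
    composition distance percentiles, prophage and shared-contig recall),
    MIMAG quality classification of bins, simulation-fidelity metrics
    (Shannon alpha, Bray-Curtis beta, MinHash/Mash distances), and seeded
    synthetic fixture generators so the whole pipeline is testable without
    external tools or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
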