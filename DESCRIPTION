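Package: rhizendo
Title: Compartment-Aware Pan-Genome and Phenotype Bias Analysis for Bacterial Isolate Collections
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for comparing closely related bacterial isolates collected
    from two habitat compartments (e.g. the rhizosphere and the root
    endosphere). Partitions ortholog clusters into a compartment-labelled
    core/pan-genome occupancy Venn, builds majority-rule consensus sequences
    from marker-gene alignments and scores per-strain identity, tests binary
    traits and pathway tables for compartment bias with contingency
    chi-square statistics (asymptotic and label-permutation), analyses
    phenotype-microarray carbon utilization matrices by compound class, and
    validates genome-scale metabolic model growth predictions against
    observed substrate utilization. Ships seeded synthetic-data generators
    that emulate the statistical structure of such studies so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
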