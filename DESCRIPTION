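Package: blockspec
Title: Block-Based Characterization of Protease Substrate Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies protease substrate specificity from collections of
    8-residue cleavage windows (P4-P4' in Schechter-Berger nomenclature).
    Builds the eight nested "blocks" of successive residues flanking the
    scissile bond, computes their Shannon entropies and the Euclidean
    distance matrix between protease entropy profiles, identifies
    statistically prominent residue combinations with a one-sided Fisher
    exact test against frequency-matched simulated backgrounds (Bonferroni
    corrected, majority vote over repetitions), and summarises results with
    correlation-matrix principal components analysis. Includes a greedy
    redundancy filter, a synthetic substrate-set generator with planted
    motifs for power analysis, readers and writers for window tables and
    position frequency matrices, and a pipeline runner with a command-line
    wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
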