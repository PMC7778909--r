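Package: gpcrsig
Title: Residue-Level Sequence and Structure Analysis for G Protein-Coupled
    Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for residue-level comparison of G protein-coupled
    receptors (GPCRs). Implements generic residue numbering in both
    sequence-based (Ballesteros-Weinstein style) and structure-based
    schemes, including conversion across helix bulges and constrictions;
    an amino-acid property taxonomy of 56 groups built from polarity,
    helical propensity and size combined with backbone bond distances;
    position-wise property conservation and z-scale descriptor summaries
    over structure-based multiple sequence alignments; a two-set sequence
    signature algorithm that ranks residue positions by conservation
    difference with Welch t-test statistics on five z-scale descriptors;
    signature matching against alignments; and segment-wise RMSD between
    coordinate sets after Kabsch superposition on the seven-transmembrane
    backbone. Synthetic fixture generators make the full pipeline testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
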