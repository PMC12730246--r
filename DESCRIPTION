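Package: tsh3scan
Title: Discovery and Analysis of Tandem SH3-Binding Short Linear Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and characterising short linear motifs
    (SLiMs) recognised by tandemly arranged SH3 domains, such as those of the
    p47phox (NCF1) organizer family. Provides positional character-class
    motif definitions with strong/weak/core variants, proteome scanning with
    sequence-shuffle null statistics, ortholog motif-conservation scoring in
    multiple sequence alignments, screening of multi-SH3 domain architectures
    for tandemization sequence signatures (GWW, C-[DE][DE], N-PxxPhiL,
    linker length), and RMSD-based classification of conformer ensembles
    against a tandem-SH3 reference geometry. A synthetic-data generator
    produces proteomes, ortholog families, domain architectures and
    conformer ensembles with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
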