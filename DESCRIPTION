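Package: plastdrift
Title: Comparative Analysis of Degraded Plastid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of plastid genomes undergoing
    structural degradation, as seen in holoparasitic plants. Detects the
    quadripartite structure (LSC/IRb/SSC/IRa) and reports gene context at the
    four inverted-repeat junctions; classifies protein-coding genes as present,
    pseudogenized (frameshift, premature stop, truncation) or lost against a
    non-degraded reference and clusters species on loss/pseudogene ratios;
    extracts intergenic spacers shared across genomes and ranks them by Kimura
    two-parameter divergence; screens shared genes for relaxed or positive
    selection with a Nei-Gojobori counting dN/dS estimator; and designs
    species-diagnostic SNP/indel barcode markers with conserved primer pairs.
    Includes a seeded synthetic-plastome generator with a truth manifest so
    every stage is testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    generics,
    rlang,
    stringr,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
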