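Package: serprot
Title: Annotation of Granule-Associated Hematopoietic Serine Proteases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating granule-associated hematopoietic serine
    proteases (chymases, tryptases, granzymes, neutrophil proteases).
    Assigns canonical chymotrypsinogen numbering by global alignment to a
    bundled reference scaffold, extracts the S1-pocket specificity triplet
    (positions 189/216/226), checks the His57-Asp102-Ser195 catalytic triad
    and canonical cysteine features (Cys93 dimerisation, Cys191-Cys220
    bridge), classifies primary cleavage specificity with a rule table,
    reconstructs protease loci from genome annotations using bordering
    marker genes with to-scale SVG maps, builds distance and neighbor-joining
    trees with bootstrap support and majority-rule consensus, and simulates
    protease families and loci for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    S4Vectors,
    tibble,
    dplyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    yaml,
    jsonlite,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
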