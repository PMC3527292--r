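Package: napmut
Title: Growth Phase-Resolved Effects of Nucleoid-Associated Protein
    Binding on Sequence Mutability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to relate the growth phase-specific binding of bacterial
    nucleoid-associated proteins (Fis, H-NS, IhfA, IhfB) to local sequence
    mutability across a strain phylogeny. Implements marginal ancestral
    reconstruction with high-confidence single-event change calling,
    genome uniqueness masking, binding-category stratified mutability and
    odds ratios, a permutation test for 5-methylcytosine (CCWGG) context
    hotspots, and a random-forest binding-randomization significance test,
    together with a synthetic-data generator so every stage runs with
    known ground truth and no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
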