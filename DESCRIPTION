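Package: proteosort
Title: Composition-Based Prediction of Organellar Sub-Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which translocated proteins of a bacterium carrying a
    membrane-bounded organelle (such as the anammoxosome of anammox bacteria)
    are targeted to the organelle rather than to the cell envelope.
    Implements a class-imbalance-aware random-forest protocol on amino acid
    and dipeptide composition features (repeated random splitting of the
    larger training class, out-of-bag vote pooling, tie-aware model
    selection), majority-vote combination of external signal-peptide
    predictors, parsing of signal-peptide n/h/c architecture with anchored
    segmental alignments and position frequency matrices, partition of a
    proteome into four subcellular sets, physicochemical profiling (GRAVY,
    aliphatic index, residue-class prevalences), in-silico tryptic digestion
    for cleavage-site validation against peptide evidence, and a seeded
    synthetic-data generator that emulates the compositional structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    randomForest,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
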