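Package: herdlink
Title: Multi-Country Pedigree BLUP Evaluation for Dairy Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pedigree-based multi-trait animal-model BLUP for dairy cattle
    herdbooks, run within country or on data pooled across countries that are
    connected through common sires. Builds the sparse inverse numerator
    relationship matrix with inbreeding, assembles and solves Henderson's
    mixed-model equations for 305-day milk yield, age at first calving and
    first calving interval with herd, herd-year-season and country fixed
    effects, estimates variance components by EM-REML, and predicts genetic
    gain under top-k sire selection with the breeders' equation, including the
    within- versus across-country percent-gain comparison. A seeded two-country
    herdbook simulator generates pedigrees and first-lactation phenotypes with
    the same statistical structure so the whole pipeline is testable without
    access to private national datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
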