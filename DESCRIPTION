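Package: pericentr
Title: Pericentric Inversion Detection from Chromosome-Arm Assignment
    Patterns in Allopolyploid Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring pericentric rearrangements in allohexaploid
    wheat from chromosome-arm shotgun hit data. Classifies homoeologous gene
    triplets into standard and nonstandard arm-location patterns from BLAST
    tabular hits against flow-sorted chromosome-arm libraries, calls pericentric
    inversions per chromosome under explicit count and co-mapping criteria,
    reconciles arm calls against deletion-bin EST locations, and bounds by
    exhaustive search how many nonstandard arm-location patterns a single
    genotype can produce. A seeded synthetic allohexaploid-genome simulator
    with planted rearrangements and ground-truth labels makes every stage
    testable without the original chromosome-arm sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
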