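Package: lineagedfe
Title: Lineage Tracking and Beneficial-Mutation Spectra in Barcoded Yeast Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for barcoded serial-transfer
    evolution experiments in budding yeast. Generates barcode-count
    trajectories with realistic serial-dilution dynamics (branching-process
    establishment, bottlenecks, finite sequencing depth, pre-existing
    mutations from the barcoding expansion), infers population mean fitness
    from a neutral reference band, per-lineage selection coefficients and
    establishment times, and inverts lineage frequencies into a
    fitness-dependent beneficial-mutation rate spectrum mu(s). Also provides
    conservative diploidization-rate bounds, pooled competition-assay fitness
    estimation with inverse-variance replicate combination, and
    mutation-catalog statistics (variant filtering, multi-hit tallies,
    loss-of-function contingency tests, additive-epistasis expectations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
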