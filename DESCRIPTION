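Package: thermomatch
Title: Thermal Mismatches and Energetic Balances in Consumer-Resource Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how environmental warming reshapes
    consumer-resource interactions through the balance of energetic gain and
    loss. Fits Sharpe-Schoolfield thermal performance curves to per-capita
    respiration, net photosynthesis and ingestion rates derived from
    respirometry and grazing assays, computes gain-to-loss energetic balances
    on a fine temperature grid, locates balance optima (Tm) and crossover
    temperatures (Tc), classifies intra- and inter-specific thermal mismatch
    regions, computes the consumer-resource energetic balance (CREB) and its
    trend, and relates these to per-capita interaction strength measured with
    the Dynamic Index. Includes a seeded synthetic-assay generator that
    emulates blocked respirometry and ingestion experiments for testing the
    full pipeline without laboratory data.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
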