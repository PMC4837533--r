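Package: seedgain
Title: Genetic Gain from Marker-Assisted Seedling Selection in Clonally
    Propagated Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models genetic gain from four seedling-selection strategies
    (phenotype-only, marker-only, two-stage, and index selection) for single
    traits in clonally propagated crops, where clonal propagation captures
    total genotypic value rather than only additive effects. Provides the
    variance partition over broad-sense heritability and DNA-test
    predictiveness, discrete marker-genotype distributions for a one-locus
    (dominance) and a two-locus (epistatic) segregating population,
    closed-form gain predictions based on truncated-normal selection
    intensities and exact enumeration over marker classes, and a replicated
    stochastic simulation engine with confidence intervals and
    derived-versus-simulated comparisons.
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
    purrr,
    readr,
    rlang,
    stats,
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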