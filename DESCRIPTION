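Package: owlfield
Title: Binocular Visual-Field Configuration and Phylogenetic Comparative
    Analysis for Birds of Prey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing avian binocular visual fields from
    ophthalmoscopic perimeter measurements and relating their size and shape
    to ecology while accounting for shared ancestry. Converts raw perimeter
    readings into parallax-corrected field profiles, binocular/cyclopean/blind
    sectors and summary statistics; quantifies binocular-field outline shape
    with elliptic Fourier analysis and principal components; and fits Pagel's
    lambda phylogenetic generalized least squares regressions with stepwise
    AIC model selection, simulation-based phylogenetic ANOVA, Brownian-motion
    ancestral state reconstruction and maximum clade credibility tree
    summaries. A seeded synthetic-data generator produces trees, ecological
    covariates and perimeter measurements with the statistical structure the
    analyses assume, so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    nlme,
    phangorn,
    phytools,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
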