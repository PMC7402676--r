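Package: littermix
Title: Meta-Analysis of Non-Additive Litter Mixture Decomposition Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesising litterbag decomposition experiments that
    compare species mixtures against additive expectations built from their
    component monocultures. Computes log response ratio effect sizes with
    sampling variances, pools them under a random-effects model
    (DerSimonian-Laird) with bias-corrected bootstrap confidence intervals,
    partitions heterogeneity across categorical subgroups, stages effects
    along 10% mass-loss intervals of the additive-null trajectory, and
    regresses mixture effects on initial chemical trait divergence (Rao's
    quadratic entropy) and site climate. Includes a synthetic-data generator
    that emulates the statistical structure of a global litterbag compilation
    so the whole pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
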