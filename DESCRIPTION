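Package: asrpath
Title: Comparative Analysis of Sex Determination, Demography, and Adult Sex Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analyses linking genetic sex-determination
    systems (XY versus ZW) to adult sex ratios via sex-biased demography in
    tetrapods. Implements sex-bias trait metrics, phylogenetic generalized
    least squares with maximum-likelihood Pagel's lambda, per-variable
    lambda-rescaled independent contrasts, d-separation confirmatory path
    analysis in two fitting flavours (per-variable contrasts and pairwise
    PGLS) with Fisher's C, AICc and CICc model comparison, Mk-model fitting
    and stochastic character mapping for binary sex-determination characters,
    simulation-based power analysis, and a synthetic data generator that
    reproduces the statistical structure of the study system at any scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
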