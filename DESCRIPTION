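Package: multistab
Title: Multi-Scale Diversity-Stability Partitioning for Replicated
    Grassland Nutrient Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multi-scale analysis of biodiversity-stability
    relationships in replicated fertilization experiments on grassland
    communities. Reads long-format species cover and aboveground biomass
    tables, partitions temporal stability of productivity into species
    stability, species asynchrony, alpha stability, spatial asynchrony and
    gamma stability, computes multiplicative alpha/beta/gamma diversity
    from abundance data, fits per-duration standardized path models
    linking diversity to stability at two spatial scales, pools path
    coefficients across experimental durations by inverse-variance
    meta-analysis with Cochrane Q treatment contrasts, and ships a
    fully parameterized synthetic community time-series generator for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    nlme
Config/testthat/edition: 3
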