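Package: phenospline
Title: Two-Stage Spatio-Temporal Analysis of High-Throughput Phenotyping Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of longitudinal high-throughput phenotyping
    (HTP) experiments on plants. A first stage corrects plant- or plot-level
    phenotypes for spatial field/greenhouse trends and experimental design
    factors separately at each measurement time, using a two-dimensional
    P-spline (PS-ANOVA) surface within a sparse linear mixed model, and
    propagates the correction uncertainty forward as precision weights. A
    second stage fits a three-level (population/genotype/plant) nested
    hierarchical P-spline growth-curve model by REML, yielding smooth growth
    curves, genotype deviations, first-order derivatives and pointwise
    confidence bands at every level of the hierarchy. Time-independent
    intermediate traits (maximum trait value, maximum growth rates, area under
    genotype deviations) are extracted from the estimated curves. A synthetic
    experiment generator with known ground truth supports simulation studies
    and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    splines,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
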