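Package: maltmet
Title: Quantitative Genetics of NMR Metabolomic Features in Malting Barley
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component analysis of plot-level NMR metabolomic
    features and malting-quality traits in multi-environment plant breeding
    trials. Provides marker quality control and construction of the VanRaden
    method-1 genomic relationship matrix, preprocessing of NMR bucket tables
    (region exclusion, probabilistic quotient normalisation, segment-wise
    spectral alignment, autoscaling), average-information REML estimation of
    univariate and bivariate mixed models with genomic and genotype-by-
    environment random effects, plot-level genomic heritability with a
    simulation-calibrated significance cutoff, genetic and phenotypic
    correlations between features and traits, and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
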