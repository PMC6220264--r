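Package: twinpath
Title: Twin and DNA-Based Models of Developmental Stability in Polygenic Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood twin structural equation models for the
    developmental stability of polygenic traits such as educational
    achievement: univariate ACE decomposition, multivariate Cholesky,
    the longitudinal genetic simplex model and the common pathway model,
    fitted to MZ/DZ group covariance matrices with likelihood-based
    confidence intervals and model comparison. Complements the twin
    models with desk-scale DNA-based methods: genetic relationship
    matrices, relatedness pruning, average-information REML estimation
    of SNP heritability, GRM principal components, polygenic scoring and
    incremental R-squared prediction across ages. A synthetic-data
    module generates twin cohorts, genotype panels and longitudinal
    polygenic-score cohorts with the exact covariance structure the
    models assume, so every analysis is reproducible as a
    parameter-recovery experiment without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
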