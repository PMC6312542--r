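Package: metgblup
Title: Multi-Environment Genomic Prediction with Factor-Analytic G x E Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genomic prediction of quantitative traits evaluated in
    multi-environment trials with little clonal replication. Provides a
    curation pipeline for combining genotypic and phenotypic data from
    multiple sources (germplasm name standardization, SNP-call merging,
    marker filtering, duplicate-profile detection, flanking-marker
    imputation), genomic (VanRaden method 1) and pedigree relationship
    matrices, linkage-disequilibrium decay summaries, a multivariate
    genomic mixed model y = Xb + Zu + r with uniform, compound-symmetry
    and first-order factor-analytic genotype-by-environment covariance
    structures fitted by average-information REML, BLUE/BLUP prediction
    via Henderson's mixed model equations, per-environment heritability
    and average genetic correlation estimators, within-location k-fold and
    leave-one-location-out cross-validation with predictive ability and
    prediction accuracy metrics, and a synthetic-data generator with known
    truth for validating the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
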