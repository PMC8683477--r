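Package: equusage
Title: Epigenetic Aging Models and Inbreeding Analysis for Equids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating epigenetic aging models from
    CpG methylation beta values, with an application to wild equids. Implements
    elastic-net epigenetic clocks on square-root transformed age with
    leave-one-out evaluation and cross-species application, the epigenetic
    pacemaker (alternating least-squares estimation of per-site rates and
    per-sample epigenetic states) with trend-curve age translation,
    genotype-based inbreeding estimation (method-of-moments F, sliding-window
    runs of homozygosity, F_ROH), age-acceleration regression with
    heteroskedasticity-robust covariance, and correlation-based EWAS with
    cross-tissue Stouffer meta-analysis. A synthetic-data generator produces
    methylation, genotype and phenotype datasets with known ground truth so
    every stage can be exercised and validated without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    sandwich,
    vcfR,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
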