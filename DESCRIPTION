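Package: gvburden
Title: Gene-Wise Variant Burden and Two-Step Extreme-Phenotype
    Association for Antidepressant Treatment Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step pharmacogenomic association pipeline for
    extreme-phenotype treatment-outcome cohorts. Computes per-sample,
    per-gene variant burden scores (the geometric mean of SIFT scores of
    carried deleterious variants), derives early-improvement and
    remission labels from longitudinal Hamilton Depression Rating Scale
    trajectories (with chained-equation imputation of missing follow-up
    scores), screens genes by covariate-adjusted logistic regression and
    the optimal sequence kernel association test (SKAT-O) with
    Benjamini-Hochberg false-discovery-rate control, and follows up
    candidate genes with carrier-model Fisher exact tests per variant.
    Includes a local hypergeometric gene-set over-representation step and
    a fully synthetic cohort generator (Hardy-Weinberg genotypes,
    annotated variants, planted gene effects, longitudinal scores with
    missingness) so the whole pipeline is testable without access to
    protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
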