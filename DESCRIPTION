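Package: seizomics
Title: Multi-Omic Biomarker Discovery for Infant Epilepsy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal multi-omic biomarker discovery
    in infant epilepsy cohorts such as tuberous sclerosis complex (TSC) birth
    cohorts. Implements Z-score/un-Z-score batch and drug-effect correction,
    linear mixed-model and age-tertile age correction of longitudinal analytes,
    assumption-gated two-group and Kruskal-Wallis/Dunn three-group differential
    analysis with Benjamini-Hochberg control and a dual-correction intersection
    rule, developmental trajectory clustering, and an exhaustive 1-3 variable
    logistic classifier search scored by Matthews correlation coefficient under
    Monte-Carlo cross-validation with whole-experiment permutation significance
    testing. Ships a synthetic cohort generator with planted ground-truth
    effects so that every stage is testable without access-controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1.0)
Imports:
    stats,
    utils,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
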