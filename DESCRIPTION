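Package: phipkit
Title: Analysis of Phage Immunoprecipitation Sequencing (PhIP-seq) Autoantibody Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-sequencing analysis of PhIP-seq autoantibody discovery
    experiments. Aggregates peptide-level read counts to genes, normalizes
    to pseudocounted read percentages, computes fold change over mock-IP
    (bead-only) background and control-referenced Z-scores with
    leave-one-out scoring of controls, calls disease-specific shared hits
    under multi-criterion thresholds, quantifies the effect of healthy
    control cohort size by random downsampling, classifies disease status
    with L1-penalized logistic regression under cross-validation, and
    computes radioligand-binding-assay antibody indices with
    mean-plus-3-SD positivity cutoffs. Includes a seeded
    Dirichlet-multinomial simulator of PhIP-seq count data with spike-in
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
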