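Package: xprediction
Title: Explainable Drug-Sensitivity Prediction from Sample-Specific Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates drug-sensitivity-specific (per-sample) gene regulatory
    networks with a kernel-weighted varying-coefficient elastic-net regression,
    derives regulatory-effect features from the fitted networks, classifies
    cell lines as drug sensitive or resistant with kernel SVM, random forest or
    a feed-forward neural network under repeated stratified cross-validation,
    and assigns every regulator-target interaction an importance p-value by
    feature ablation and a pooled two-sample t-test. Includes downstream
    marker-set analyses (pan-cancer edges, drug-drug similarity, class-specific
    markers) and a fully seeded synthetic-data generator with ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    quadprog,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
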