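Package: kdtrank
Title: Mechanistic Pathway-Based Ranking of Known Drug Targets
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks known drug targets (KDTs) by their regulatory relevance over
    a mechanistic signaling map. Circuit activities are computed from normalized
    gene expression by signal propagation over receptor-to-effector circuits;
    a multi-output random forest maps KDT expression to circuit activities;
    per-gene, per-circuit relevance is obtained from exact interventional
    Shapley values; a convex R-squared-gated quantile rule selects relevant
    KDTs per circuit; and selection stability across resamples is assessed with
    the Nogueira estimator, a bootstrap confidence interval and a matched-null
    effect size. Includes a synthetic pathway/expression generator with planted
    driver genes, fatty-acid dose arithmetic for supplement composition tables,
    and a reproducible pipeline driver with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
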