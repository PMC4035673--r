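Package: dtabias
Title: Small-Study-Effects Tests for Diagnostic Test Accuracy Meta-Analyses
Version: 0.1.0
Authors@R:
    person("dtabias", "maintainers", email = "dtabias@example.org", role = c("aut", "cre"))
Description: Tools to assess publication bias (small study-effects) in
    meta-analyses of diagnostic test accuracy. Implements per-study effect
    measures for 2x2 accuracy tables (diagnostic odds ratio, its log,
    variance, and the effective sample size), the three funnel-asymmetry
    tests commonly applied to such data (Begg's rank correlation, Egger's
    weighted regression, and Deeks' effective-sample-size regression),
    funnel-plot construction for the axis conventions found in published
    reviews, pairwise concordance of test results via Cohen's kappa,
    logistic moderator regression of concordance on meta-analysis
    characteristics, and a seeded simulator of diagnostic accuracy
    meta-analysis corpora with tunable heterogeneity, threshold variation
    and selective-publication mechanisms for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
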