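Package: metasynopsis
Title: Cumulative-Evidence Synopsis of Genetic Association Meta-Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for field-synopsis meta-analysis of genetic
    association studies. Converts study-level records (odds ratios with
    confidence intervals, genotype counts, or per-genotype means) to a
    common effect scale, pools them by inverse-variance fixed-effect and
    DerSimonian-Laird random-effects models with Cochran's Q, I-squared
    and tau-squared heterogeneity statistics, screens for small-study and
    publication bias (Egger and Begg tests) and runs leave-one-out,
    first-report and Hardy-Weinberg sensitivity analyses. Significant
    associations are graded by the Venice criteria and the false-positive
    report probability (FPRP), and combined into a final cumulative
    evidence level. Includes an offline phenome-wide Bonferroni scan, a
    greedy linkage-disequilibrium pruner, and a synthetic study-collection
    generator for calibration of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
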