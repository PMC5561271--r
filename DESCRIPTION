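Package: seedfc
Title: Seed-Based Resting-State Functional Connectivity Change Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for pre- versus post-task amygdala seed-based
    resting-state functional connectivity (rsFC) analysis in multi-site
    cohorts: spherical seed construction in stereotaxic millimetre
    coordinates, voxelwise Pearson correlation maps with Fisher r-to-z
    transformation, site residualization, group-by-time mixed ANOVA on
    change scores with conjunction and restriction rules, Monte-Carlo
    cluster-extent family-wise error correction driven by map smoothness,
    clinical-score correlates with Bonferroni control, and closed-form
    summary statistics (one-sample t, one-way ANOVA from group summaries,
    2x2 chi-square). Includes a synthetic multi-site BOLD cohort generator
    with planted seed-coupled networks and ground truth for recovery and
    calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
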