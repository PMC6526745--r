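Package: affwm
Title: Multilevel Behavioral Meta-Analysis and Multikernel Density
    Analysis for Affective Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Paired analytic engines for meta-analyses of working memory
    under affective versus neutral conditions.  The behavioral arm
    converts per-condition summary statistics into bias-corrected
    standardized mean differences (Hedges' g), fits multilevel
    random-intercept and mixed-effects meta-analytic models by REML with
    effect sizes nested in studies, and runs heterogeneity, moderator and
    publication-bias diagnostics (a multilevel Egger-type regression test
    and a rank-correlation approximation).  The imaging arm implements
    multikernel density analysis (MKDA) for peak-coordinate neuroimaging
    meta-analysis: per-contrast indicator maps from 10-mm spheres,
    square-root-of-N weighted density maps, Monte Carlo null simulation
    over a gray-matter mask with voxel-level and cluster-extent
    family-wise error control, difference maps with permutation
    inference, and Talairach/MNI coordinate conversion.  A synthetic-data
    module generates behavioral corpora and foci tables with known ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
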