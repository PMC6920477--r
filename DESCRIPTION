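Package: sdexpr
Title: Longitudinal Transcriptome Analysis of Therapeutic Sleep Deprivation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for longitudinal differential-expression studies of
    therapeutic sleep deprivation and similar repeated-measures designs
    with three timepoints (pre-intervention, post-intervention,
    post-recovery). Provides per-gene linear mixed-model likelihood-ratio
    contrasts (time effect, response-by-time and case-by-time
    interactions), baseline linear models, Benjamini-Hochberg FDR control,
    signed -log10(p) preranked gene-set enrichment with a weighted
    running-sum statistic, a Monte-Carlo over-representation test for
    targeted gene panels (with an exact hypergeometric cross-check),
    time-course gene-set analysis via mixed models with trend extraction
    and heatmaps, quantile normalization, readers for expression/metadata
    TSV and GMT gene-set files, a packaged circadian gene panel, and a
    synthetic-cohort simulator that emulates the study design (responders,
    non-responders, controls, dropout, subject random intercepts,
    age/sex covariates, injected effects) for power and calibration work.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
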