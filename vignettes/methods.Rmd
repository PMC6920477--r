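---
title: "Models and methods behind sdexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sdexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`sdexpr` implements a longitudinal blood-transcriptome analysis for
intervention studies with three same-clock-time samples per subject —
the motivating design is therapeutic sleep deprivation (SD) in
depression, with a pre-SD morning (T1), a post-SD morning (T2), and a
post-recovery-sleep morning (T3), in responders, non-responders and
healthy controls. The package covers five stages: data model and
normalization, a synthetic-cohort generator, per-gene mixed-model
likelihood-ratio contrasts with FDR control, gene-set enrichment
(preranked running-sum and Monte-Carlo panel over-representation), and a
mixed-model time-course gene-set analysis with trend extraction. It
deliberately starts from a gene-level expression matrix: probe-level
array processing (background correction, CDF annotation) is upstream
and out of scope; only quantile normalization is provided, since the
downstream statistics operate on the normalized gene-level matrix.

# The data model

An `expression_study` holds a genes-by-samples matrix of log-scale
intensities plus per-sample metadata (subject, timepoint, group, age,
sex, and a protocol-violation flag). Validation enforces one sample per
(subject, timepoint), constant group/sex within subject, and finite
values. Dropout is represented by absent samples — there are no
sentinel values, and every model uses available cases, which linear
mixed models tolerate without imputation.

Quantile normalization forces every sample to the across-sample mean of
order statistics, preserving within-sample ranks. Ties receive the mean
of the reference values across the tied ranks (the common dialect; on
continuous intensities ties have probability zero, so the exact-equality
invariants — identical sorted columns, idempotence — hold exactly in
practice). Whether to normalize all timepoints jointly or per timepoint
is genuinely open in this design; the package normalizes jointly by
default because the contrasts compare timepoints, and a per-timepoint
normalization would absorb exactly the global shifts the models test.
Users can normalize subsets via `subset_samples()` if they prefer.

# The synthetic cohort

No patient-level data ship with the package, so every statistical claim
is exercised on a generator whose defaults *are* the emulated design:

* participation 60/56/53 responders, 16/16/13 non-responders, 15/15/15
  controls across T1/T2/T3 — 91 samples at T1, 259 in total;
* patient ages N(43.5, 14.8²), control ages N(40.5, 15.9²), truncated
  to [18, 80]; sex counts per group as observed (36M/24F responders,
  7M/9F non-responders, 7M/8F controls);
* model: gene baseline (drawn N(7, 1.5²) log-intensity by default) +
  subject random intercept N(0, σ_u²) + age/sex covariate terms +
  injected effects + residual N(0, σ_e²), with σ_u = σ_e = 0.5
  log-intensity units by default — a within-subject correlation of 0.5,
  typical of repeated blood-array measures;
* dropout missing-at-random within group (one random permutation per
  group; the first k subjects participate, so monotone counts give
  nested dropout);
* two patients flagged as recovery-protocol violators at T3.

Injected effects are additive on the log scale: `time_main` (shared
change over timepoints), `group_by_time` (confined to one group — an
interaction), `baseline_shift`, and `set_coherent_trajectory` (a shared
profile over a whole gene set, supplying the between-gene coherence the
time-course test exploits). Profiles are anchored at zero at T1. A
`truth_table()` records, per gene and contrast, the effect each
injection targets, for parameter-recovery tests.

What the generator does **not** emulate: probe-level noise, array
artifacts (e.g. globin interference), heavy-tailed or count-like
intensity distributions, and gene–gene correlation beyond shared
subject effects and injected set coherence. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative assumptions, not robustness to real-array pathologies.

# Per-gene mixed-model contrasts

For each gene, nested linear mixed models with a subject random
intercept are fitted by maximum likelihood (ML, not REML, because the
compared models differ in their fixed effects) on the T1/T2 samples,
with age and sex as covariates:

* **M1** (patients): h1 adds the T2 indicator; tested term = time.
* **M2** (patients): h1 adds responder × T2; reference non-responder.
* **M3** (patients + controls): h1 adds patient × T2; reference control.

Each tested term contributes one parameter, so the likelihood-ratio
statistic 2(ℓ₁ − ℓ₀) is referred to χ²(1), two-sided via the signed
estimate: a positive estimate means higher expression at T2 (M1) or a
larger T2−T1 change in responders/patients (M2/M3). Fitting uses a
template-and-refit scheme (the random-effects structure is identical
for every gene, so both templates are fitted once and refitted per
gene), which keeps a transcriptome-wide run at thousands of genes in
the ~minute range. Zero-variance genes are recorded as
`converged = FALSE` with p = 1, never thrown; singular fits (σ_u → 0)
are retained, since the ML solution at the boundary coincides with the
ordinary-least-squares limit and the fixed-effect LRT remains well
defined there. On balanced paired data the M1 test is exactly the
paired-t information: the likelihood factorizes into per-subject
difference and sum spaces, giving the closed form n·log(1 + t²/(n−1))
when the between-subject variance is interior — the test suite verifies
agreement with the exact two-branch closed form to 1e-6.

Baseline (T1-only) group comparisons use ordinary linear models
`expression ~ group + age + sex` with a Wald test, fitted through one
shared QR decomposition.

FDR control is Benjamini–Hochberg per contrast across converged genes
(`bh_fdr()`, verified against a brute-force step-up oracle).
A known finite-sample limitation: the χ²(1) reference is slightly
liberal deep in the tail at these sample sizes (t-like tails), so when
many strong effects push the BH threshold to ~1e-3, single-run
empirical false-discovery proportions can exceed the nominal level;
the recovery tests average seeds for this reason.

# Enrichment

Ranked lists score each gene by `direction × (−log10 p)`, flooring p at
the smallest positive double; ties break by gene symbol so output is
deterministic. The preranked enrichment engine is written from scratch:
the enrichment score is the signed maximum deviation of a running sum
with hit increments |score|^weight (normalized) and miss decrements
1/(N−m); weight defaults to 1, the published default for this
statistic. Because the input is a ranked list, the only available null
is gene-label permutation of set membership; p-values are one-sided
within the sign of ES, NES divides by the mean |null ES| of matching
sign, and FDR q follows the pooled positive/negative-null convention,
with a within-direction Benjamini–Hochberg adjustment reported
alongside (`q_bh`). Hallmark-style collections are read from GMT; the
heme-metabolism set can be excluded at read time, the conventional step
for blood arrays where globin transcripts distort that set.

The circadian panel ships with the package: ten canonical clock genes
(PER1, NR1D2, PER3, NR1D1, PER2, ARNTL, NPAS2, CLOCK, CRY2, CRY1) plus
the top blood-rhythmicity predictor genes (DDIT4, CLEC4E, FKBP5, DAAM2,
TPST1, IL13RA1, SMAP2, HNRNPDL, FOSL2, FLT3, CDC42EP2, TMEM88, RBM3);
PER1 and NR1D2 appear on both source lists, so the union holds 23
unique symbols. `montecarlo_set_test()` estimates the probability that
a random same-size gene set contains at least the observed number of
nominally significant genes (uncorrected p < 0.05, by design
independent of the pipeline's FDR threshold), drawing without
replacement from the analyzed universe with 10,000 draws by default.
That null is exactly hypergeometric, so the analytic tail is always
reported beside the empirical estimate — an internal cross-check that
the tests assert to within three Monte-Carlo standard errors. The
panel test runs on the union panel by default; per-list screening is
available via `circadian_panel("clock")`/`circadian_panel("blood")`.

# Time-course gene-set analysis

For all three timepoints, member genes are standardized (per-gene
z-score over the analyzed cohort), stacked, and modelled with: h0 —
gene-specific intercepts plus a subject random intercept; h1 — adds
fixed timepoint effects and gene-specific random time deviations
(independent variance components for the T2 and T3 indicators). Both
models are fitted by ML; the LRT has 2 added fixed-effect parameters.
Timepoints are categorical — with three occasions a spline or linear
time basis would only constrain the display. T3 samples flagged as
protocol violations are excluded from this stage. Sets whose model
cannot be fitted (e.g. a single usable gene, or too few subjects) are
reported `converged = FALSE` and excluded from inference, with the rest
of the collection unaffected; q-values are Benjamini–Hochberg within
cohort over converged sets. The analysis runs separately per cohort
(patients, controls, responders, non-responders).

The null reference is configurable because the h1 model adds two
variance components at their boundary alongside the two fixed effects,
so no single χ² is exact. The package's calibration study (simulated
null sets at several design scales, 2,800 replicates in total) measured
rejection at nominal 0.05 of ~0.065 for χ²(2) and ~0.025 for the 50:50
χ²(2)/χ²(4) mixture. χ²(2) — the default — is the closest of the
closed-form options and sits within three binomial standard errors of
nominal at the 500-replicate scale the tests use; the mixture is the
conservative alternative, and a within-subject timepoint-permutation
reference (`ref = "perm"`) is exact by construction but costs a model
fit per permutation. Power under the default is high where it should
be: a coherent 1-residual-sd trajectory in a 20-gene set with 30
subjects is detected at p < 0.01 essentially always.

Trends are extracted per gene as the median standardized expression
over subjects at each timepoint, anchored to zero at T1, then grouped
by agglomerative hierarchical clustering (Euclidean distance, complete
linkage) into at most five trends per set — a display choice; the
statistics never depend on the clustering. Heatmaps draw trend rows of
all significant sets with a blue–white–red diverging palette keyed to
the median standardized expression, rows hierarchically ordered, and
support manual exclusion of sets whose within-set expression is too
heterogeneous to summarize by trend medians.

# Pipeline, determinism, and problem sizes

`run_pipeline()` chains the stages (optional simulation → normalization
→ M1–M3 → baseline models → panel screen and Monte-Carlo → preranked
enrichment → time-course analysis → summary tables, trend heatmaps and
a JSON manifest). All randomness — simulation, membership permutations,
Monte-Carlo draws — flows from explicit seeds, and the mixed-model
templates use a fixed deterministic dummy response, so two runs with
the same configuration and seed produce byte-identical TSV and PNG
outputs; the manifest carries a path-independent fingerprint of the
analysis parameters. Every silently-dropped entity (panel genes absent
from the universe, non-converged sets, excluded T3 samples) is surfaced
in logs and result objects rather than narratively.

The test and acceptance workloads use desk-scale problem sizes chosen
to make their statistical assertions sharp without being wasteful:
transcriptome nulls and recovery at 1,000–2,000 genes, enrichment
calibration over 1,000–2,000 random sets with 400 permutations,
time-course calibration over 250–500 simulated null sets, and power
runs of 20 replicates. At these sizes binomial/Monte-Carlo tolerances
(three standard errors) are decisive for every pass/fail claim the
suite makes.

# Known limitations

* The gene-level entry point means array- or platform-specific
  artifacts must be handled upstream.
* The χ²(1) per-gene reference is mildly liberal deep in the tail at
  n ≈ 70–90 subjects (see above).
* The time-course default reference is mildly liberal (~0.065 at
  nominal 0.05); the permutation reference is exact but expensive.
* The enrichment FDR follows the pooled-null convention and, like the
  original statistic, is not a strict step-up procedure; `q_bh` is
  provided for users who want one.
* The generator's Gaussian log-intensity model is a deliberate
  simplification; count-based (RNA-seq) data should be transformed and
  inspected before use.
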