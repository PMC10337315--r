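---
title: "Methods: synthetic PET cohorts, radiomic features, and model validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic PET cohorts, radiomic features, and model validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrad)
```

`petrad` implements a complete analysis chain for ¹⁸F-FDG PET radiomic
prediction of residual oesophageal tumour after neoadjuvant
chemoradiotherapy (nCRT): quantification, feature extraction, external
validation of published logistic models, scanner harmonisation with
penalised model redevelopment, and cohort-comparison statistics. This
vignette is the package's methodological record: what each stage assumes,
which parameters matter and why their defaults were chosen, what the
synthetic data generator does and does not emulate, and the numerical
conventions adopted where the field leaves choices open.

## The outcome and its dichotomies

The clinical endpoint is the Chirieac tumour regression grade of the
resection specimen: TRG 1 is 0% residual tumour (pathologically complete
response), TRG 2 is 1–10%, TRG 3 is 11–50%, TRG 4 is more than 50%; a
grade 5 is grouped with 4 throughout. `dichotomise_trg()` supports two
endpoints: `trg234` (any residual tumour, the primary endpoint) and
`trg34` (substantial residual tumour, relevant because 1–10% residual
disease is plausibly invisible on PET and can be caught at later response
evaluations).

## The synthetic cohort generator

No public imaging accompanies the clinical cohorts this package is built
around, so the generator is a first-class module: it defines the study
conditions under which every downstream property is tested.

**Clinical table.** `sim_config()` defaults emulate the pooled
development + validation cohorts (n = 262): TRG marginals
(0.214, 0.279, 0.286, 0.190, 0.031) over grades 1–5, cT dominated by cT3
(0.759), cN marginals with a rare unassessable cNx (~1 per 200 patients,
exercising the cN0/cNx grouping rule), 82.4% male, 80.9% adenocarcinoma,
age ~ N(66, 8²) years, and a development : validation split of 73 : 189.
Outcomes are drawn from a latent logistic model: each patient carries a
heterogeneity latent h ~ N(0, 1), and

  P(residual tumour) = logit⁻¹(α + β·1[cT3–4] + γ·h),

with β = 2.8 (advanced T stage strongly predicts residual disease; the
magnitude mirrors the published cT coefficients of 2.7–2.9 in absolute
value) and γ = 1. The intercept α is calibrated deterministically —
quadrature over h, exact summation over cT classes, root-finding — so the
TRG 1 marginal matches the configured 0.214 in expectation. TRG grade
within the residual arm is drawn from the configured conditional
distribution. This construction makes parameter recovery meaningful: the
true generating model is available to validate against.

**Images.** Each study is a 64 × 64 × 48 grid at 4 × 4 × 3 mm —
PET-like and deliberately anisotropic so the 2 mm resampling step is
non-trivial. The phantom is minimal rather than anatomical: a smooth
background (SUV ≈ 0.8), an oesophagus-like tube along z (SUV 1.5, radius
8 mm), and an ellipsoidal lesion (semi-axes 12 × 10 × 16 mm, base SUV 2.5)
whose voxel values add a Gaussian-random-field texture with correlation
length 6 mm. The texture amplitude is the single heterogeneity dial:
`base_amp · exp(0.3 h) + 0.5 · 1[residual]`, plus a 0.4 SUV mean shift for
residual tumour, so residual lesions are both hotter and more textured.
Scanner profiles then apply a Gaussian point-spread blur (FWHM in mm),
additive noise (SD in pre-gain SUV units), and a multiplicative gain
applied last, so gain is an exact linear factor. The default three
profiles (FWHM 5/6.5/7.5 mm, gain 0.90/1.00/1.20) are invented effect
sizes — no per-scanner magnitudes are published — chosen large enough
that between-scanner feature shifts are unambiguous and harmonisation has
something real to remove. The development cohort is assigned one scanner
and the validation cohort a uniform mix, mimicking single-centre
development and multi-centre validation.

What the generator does **not** emulate: attenuation and reconstruction
physics, partial-volume effects, respiratory motion, anatomy beyond the
tube, delineation uncertainty, or inter-feature correlation structures of
real tumours. Passing tests therefore demonstrate that the *pipeline* is
correct and self-consistent under known truth — not that real PET
radiomics carries the tested signal.

## Preprocessing

SUV conversion uses body weight (not lean mass) and assumes
decay-corrected activity, `SUV = activity × weight(g) / dose(Bq)`. Serum
glucose correction multiplies by glucose / 5.0 mmol/L — an EANM-style
normalisation adopted as the default because the original workflow states
only that a correction was applied; both the formula's reference level and
the correction itself are configurable.

Resampling uses trilinear interpolation for intensities and
nearest-neighbour for masks, preserving the physical extent within one
voxel on the convention `world = origin + index × spacing` (0-based).
Masks stay strictly binary and an emptied ROI is an error, not a silent
degradation. Feature extraction only sees in-mask voxels, so the pipeline
crops to the mask bounding box (+12 mm) before interpolating.

Discretisation defaults to a fixed bin number of Ng = 64 — common IBSI
practice, adopted because the development study's exact setting is not
recoverable from the published text; fixed bin size is available. A
constant ROI maps to the single level 1 and is treated as the degenerate
homogeneous case (entropies 0, joint maximum 1), not an error.

## Radiomic features

The feature vector spans six families (~100 features, prefixed `morph_`,
`stat_`, `hist_`, `glcm_`, `glrlm_`, `glszm_`). The published models'
six features — GLCM joint maximum, joint entropy, sum entropy, angular
second moment, inverse variance, and the intensity-statistics median
absolute deviation (the mean absolute deviation from the median) — are
covered by brute-force oracle tests at 10⁻¹⁰ tolerance on ROIs up to
5 × 5 × 5.

GLCM conventions: Chebyshev distance 1, the 13 unique 3D directions,
symmetric counting (each pair in both orders). Aggregation defaults to
averaging per-direction probability matrices, with merged counting as an
option — the IBSI permits both and the original study does not say which
it used; directions contributing no voxel pair are skipped from the
average rather than contributing a zero matrix. All entropies are log
base 2. For a single-level ROI the correlation feature takes its
homogeneous-limit convention (1) and the information correlations 0.
The morphological surface area counts exposed voxel faces — a voxel-scale
approximation of the IBSI meshed surface, documented as such; sphericity
inherits it. The feature count is provenance (a hash of the extraction
config is stored per row), not an invariant: the exact 101-name list of
the original studies is not published in recoverable form.

## External validation

A model specification is `LogO = β₀ + β_cT·1[cT ∈ {3, 4a, 4b}] +
β_f·feature` with `p = logit⁻¹(LogO)` the probability of TRG 1; cT4b is
grouped with cT3–4a because unresectable T4b patients were retained in
the cohorts. Discrimination is reported for residual tumour as the
positive class (score 1 − p); calibration is assessed in the model's
native TRG 1 orientation.

* **AUC** is the Mann–Whitney pair statistic computed via midranks —
  exact under ties, and verified against explicit pair counting.
* **Calibration slope** is the coefficient of a logistic refit of outcome
  on LogO (ideal 1); the **intercept** is calibration-in-the-large, from
  an offset fit with slope fixed at 1 (ideal 0), the standard convention;
  a joint-fit intercept is available behind a flag. Perfect separation is
  reported as non-convergence rather than returning a divergent slope.
* **Confidence intervals** are percentile intervals over a seeded
  nonparametric bootstrap of patients (2000 replicates by default,
  unstratified); replicates on which a statistic is undefined — e.g. a
  single-outcome-class resample — are redrawn, and more than 50% failures
  is an error.
* **Operating point**: the threshold is the largest observed score t with
  sensitivity(score ≥ t) ≥ 0.90, which maximises specificity subject to
  the sensitivity constraint, ties resolved toward the larger threshold.
  The 90% target is the sensitivity benchmark of endoscopic response
  evaluation; the published description ("chosen to obtain 90%
  sensitivity") does not pin down tie-breaking, so the rule here is
  explicit.

## Model extension

The redevelopment workflow pools cohorts and proceeds: per-scanner
z-scoring → correlation filter → LASSO → optimism correction.

* **Per-scanner standardisation** sets each feature to mean 0, SD 1
  within each scanner group (≥ 2 patients per scanner required),
  retaining the scaling parameters. It removes location/scale batch
  effects exactly — after it, an injected gain effect is statistically
  undetectable by construction — but cannot remove scanner effects that
  reorder patients within a scanner. Zero-variance features within a
  scanner are set to 0 with a warning.
* **Correlation filter**: the published rule names only the cutoff
  (|r| > 0.9). The elimination order here is greedy and deterministic:
  repeatedly take the currently worst pair and drop the member with the
  larger mean absolute correlation to all remaining candidates, ties
  toward earlier column order.
* **LASSO**: `glmnet` with seeded 10-fold cross-validation; the penalty
  defaults to the minimum-deviance rule (`lambda.min`), with the sparser
  1-SE rule available. Under a pure-noise null the 1-SE rule is the
  configuration that keeps spurious selections to at most a couple in the
  large majority of runs; `lambda.min` is known to over-select mildly and
  is kept as default for estimation quality.
* **Optimism correction** follows Harrell: each of 200 bootstrap
  resamples refits the entire pipeline (including penalty selection, so
  no information leaks), and the mean of (resample AUC − original-data
  AUC) is subtracted from the apparent AUC. When the full-data model
  selects nothing the apparent AUC is exactly 0.5 while bootstrap refits
  still overfit their resamples, so under a null the corrected AUC is
  slightly conservative (below 0.5 on some seeds); this is a property of
  the estimator, not a defect of the implementation.
* **Subsampling benchmark**: the comparator workflow's "three simple
  linear models" are not named in the published description; logistic
  regression, linear discriminant analysis, and Gaussian naive Bayes are
  the defaults here (plus a 200-tree random forest), over 100 partitions
  stratified by outcome with a 2/3 training fraction. Feature
  pre-selection — also unspecified — is univariate-AUC ranking computed
  on the training part only (top 10 by default), with clinical
  covariates always entering.

## Cohort statistics

2×2 comparisons use the chi-squared test **with** Yates continuity
correction: the published baseline table does not state the correction,
but only the corrected test reproduces all three recoverable printed
p-values (0.024 for nodal stage, 1.00 for the TRG distribution — where
the correction clamps the statistic to exactly 0 — and 0.02 for complete
response among cT1–2 patients); without it they come out near 0.016, 0.75
and 0.01. Fisher's exact test replaces the chi-squared automatically when
any expected cell is below 5. The Mann–Whitney U test is exact for
combined n ≤ 20 without ties and otherwise uses the tie-corrected normal
approximation with continuity correction. Whether the published age
comparison used the t-test or Mann–Whitney is ambiguous; age here uses
Mann–Whitney and is not treated as a recoverable quantity.

## Determinism and problem sizes

Every stochastic step threads an integer seed; a single pipeline seed is
expanded into per-stage streams by a fixed affine rule so stages can be
rerun in isolation, and two clean runs of `run_pipeline()` with the same
seed produce byte-identical CSV/JSON artefacts. The test suite sizes its
simulations to what each property needs rather than to cohort realism:
marginal-fidelity checks at n = 2000, calibration recovery at n = 5000
records (no images), LASSO recovery at n = 600 × 30 features, the
permuted-label optimism null at 200 bootstraps, harmonisation at n = 200
per scanner on feature tables, and image-based checks (scanner shifts,
heterogeneity ordering) at 40–100 studies on a reduced 32 × 32 × 24 grid.

## Known limitations

Surface area (hence sphericity) is voxel-face based, not meshed; GLRLM
and GLSZM aggregation choices follow the same averaged-direction
convention as the GLCM rather than offering every IBSI variant; the
synthetic phantom's simplicity means feature *values* should not be read
as clinically representative — only the relationships the generator
plants (texture–outcome, scanner–batch) are meaningful; and wavelet or
other filtered-image features are out of scope, as they were unavailable
to the studies this workflow re-implements.
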