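---
title: "Shape-mode analysis of myocardial strain-time curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-mode analysis of myocardial strain-time curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainshape)
```

## The problem

In single-ventricle (Fontan) patients, global circumferential and
longitudinal strain (GCS, GLS) from CMR feature tracking are usually
summarized by a single number — the peak (most negative) strain. The
strain-time curve, however, carries more: when the peak occurs within the
cycle, and how the myocardium relaxes afterwards (one uniform diastolic
slope, or two distinct early/late slopes, the counterpart of a
double-peaked diastolic strain rate). This package treats the whole curve
as the observation. Curves are placed on a common temporal footing,
decomposed by principal component analysis into orthogonal *shape modes*,
and each patient is assigned a score per mode — a scalar measuring how
much their curve resembles that deformation pattern. Scores then enter
ordinary survival and association analyses alongside standard
hemodynamics.

The analysis is strictly stratified: one model per strain type (GCS or
GLS) per ventricular morphology (dominant left, SLV, or dominant right,
SRV). Curve shapes and their clinical correlates differ between
morphologies, and pooling would let between-group differences masquerade
as shape modes.

## Model and procedure

For subjects $i = 1,\dots,N$ of one stratum, with strain vectors
$\varepsilon_i \in \mathbb{R}^{30}$ sampled at 30 cardiac phases:

1. **Temporal normalization.** Each subject's time axis is rescaled by
   the factor (stratum-mean cycle period) / (subject cycle period), where
   the subject's cycle period is $60000/\mathrm{HR}$ ms. This removes
   heart-rate variability while preserving curve shape; strain values are
   untouched.
2. **Phase resampling.** Each curve is linearly interpolated at 30
   equally spaced points spanning its sampled range (endpoints
   inclusive). Linear interpolation cannot overshoot, which matters on
   sparse cardiac-phase data. Note that because the phase grid is
   *relative* to each curve's own span, uniform time rescaling and
   fixed-phase resampling commute; the normalization step still matters
   for any analysis on the absolute time axis.
3. **PCA.** With mean curve
   $\bar\varepsilon = N^{-1}\sum_i \varepsilon_i$, the sample covariance
   (divisor $N-1$) of the centered vectors is eigendecomposed into
   orthonormal components $p_1, p_2, \dots$ with non-increasing
   eigenvalues $\lambda_n$. Components with
   $\lambda_n \le 10^{-12}\lambda_1$ are treated as numerical zero.
4. **Retention.** The smallest $k$ whose cumulative explained-variance
   fraction strictly exceeds 0.90 is kept. On both the study-scale and
   larger synthetic cohorts this yields $k = 3$ in every stratum.
5. **Scores.** $s_n^i = p_n \cdot (\varepsilon_i - \bar\varepsilon)$
   (centered convention, the default). The raw convention
   $p_n \cdot \varepsilon_i$ differs only by the per-component constant
   $p_n \cdot \bar\varepsilon$, so hazard ratios and correlations are
   identical under either; centered scores have mean zero and variance
   $\lambda_n$, which makes group-mean score tables interpretable around
   zero. The convention in force is recorded in every export.
6. **Interpretation.** `reconstruct_mode()` produces
   $\bar\varepsilon \pm c\,\sqrt{\lambda_n}\, p_n$, and
   `characterize_modes()` quantifies what each mode does to the curve —
   change in peak amplitude, shift of the peak phase, change of the
   recovery shape — and labels the modes automatically.

**Sign convention.** PCA signs are arbitrary, so a fixed rule keeps
outputs reproducible and cutoffs portable: $p_1$ is oriented so a
positive score deepens the curve's mean absolute deflection; every other
component so its largest-magnitude element is positive. Under this rule a
*higher* PC1 score means *stronger* (more negative) strain; published
conventions may differ by a sign flip, which is irrelevant to inference.

**Survival analysis.** Each covariate is tested alone against the
composite outcome (death, transplant, plastic bronchitis,
protein-losing enteropathy; first event wins, with the accepted event
list configurable) by Cox proportional hazards with Breslow tie
handling — ties are rare on a years-resolved clock, and Breslow is the
simplest exactly specifiable choice. Strain covariates are entered per 1%
*worsening* (an explicit sign flip) so HR > 1 reads "weaker strain, more
events". For covariates with Wald $p \le 0.05$ the Youden-optimal ROC
cutoff (direction chosen by the association sign; ties broken toward the
larger high-risk group) dichotomizes the cohort, and the groups are
compared by Kaplan-Meier estimates and the log-rank test. No
multiple-comparison adjustment is applied; the analyses are exploratory.
Multivariable models are out of scope — with handfuls of events per
stratum they would be unidentifiable.

**Group comparisons and associations.** Continuous variables are triaged
by three normality tests (D'Agostino-Pearson omnibus $K^2$, implemented
in-package; Shapiro-Wilk; Lilliefors/Kolmogorov-Smirnov), flagged
non-normal when at least 2 of 3 reject at $\alpha = 0.05$ (the tests are
listed without a combination rule in common practice; majority voting is
the symmetric choice). Skewed positive variables (typically the volume
indices) are natural-log transformed before correlation. Comparisons use
the unpaired t-test or Mann-Whitney accordingly; categorical tables use
chi-square, switching to Fisher's exact test when any expected cell count
is below 5. Associations report Pearson r with the OLS slope of y on x
(e.g. dEF/dGCS in EF percentage points per 1% strain).

## The synthetic cohort generator

No patient-level data are distributed, so every stage is exercised
against a generator whose *defaults are the study conditions* and whose
latent factors are recorded as ground truth.

**Curve template.** A subject's noiseless curve over phase
$p \in [0,1]$:

- descent: half-sinusoid from 0 at $p=0$ to the (negative) peak
  amplitude $A$ at $p = t_{pk}$;
- recovery: straight line from $A$ back to exactly 0 at end-cycle;
- late-diastolic notch: a tent-shaped deviation anchored at fixed phases
  (zero before $\max(t_{pk}, 0.55)$, deepest near phase 0.75, zero at
  1.0) of depth $w \cdot d_0$, where $w \in [0,1]$ is the biphasic
  weight and $d_0 = 5.4\%$ its scale. At $w = 0$ the recovery is affine
  (one uniform slope); as $w \to 1$ the early diastolic slope flattens
  and the late slope steepens — the biphasic relaxation pattern. The
  depth is capped at 80% of the local distance between the recovery line
  and the peak, so the peak stays the unique global minimum.

The requested $t_{pk}$ is snapped to the nearest sample phase, so
noiseless curves attain their peak exactly at a sampled phase — the same
quantization a phase-binned cine acquisition imposes. Anchoring the notch
at fixed cycle phases, with a depth that does not scale with $|A|$, keeps
the three factors' curve-space directions nearly orthogonal; an
amplitude-scaled, peak-anchored notch would confound the third mode with
an amplitude-by-shape interaction and make ground-truth recovery tests
ambiguous. Homoscedastic Gaussian noise (SD 0.55% per sample) is added;
within-curve noise of feature tracking is not characterized in the
literature we model, so a single tunable level is the honest choice.

**Population defaults.** Amplitude means/SDs are morphology- and
strain-specific (SLV GCS $-15.4 \pm 3.0$%, SLV GLS $-13.4 \pm 3.0$%,
SRV GCS $-11.1 \pm 2.6$%, SRV GLS $-11.7 \pm 2.8$%), with GCS-GLS
amplitude correlation 0.5 within subject. Heart rate: SLV $76 \pm 16$,
SRV $77 \pm 25$ bpm (truncated at 40). Time-to-peak fraction
$0.40 \pm 0.095$; biphasic weight $0.50 \pm 0.45$ clamped to $[0,1]$
(a wide, near-uniform spread: mono- and biphasic relaxation coexist in
these cohorts). The three factor spreads and the noise level were
calibrated jointly — once, against the explained-variance structure the
pipeline is designed to exhibit (top three modes > 90%, first > 50%,
second near a quarter, third a small residual, in every stratum) — and
then frozen. With amplitude SDs pinned to the cohort-table values and
the time-shift mode's variance scaling with $|A|^2$, the shares differ
mechanically between morphologies (SRV strata put less variance in the
timing mode), so exact equality of shares across strata is not
attainable, nor needed.

**Hemodynamics.** EF is linear in GCS amplitude plus noise
(SLV: $EF = 26.4 - 1.6\,A_{GCS} + N(0, 5.1^2)$;
SRV: $EF = 21.7 - 2.1\,A_{GCS} + N(0, 7.2^2)$), reproducing the sign and
approximate strength of the strain-EF coupling (r about $-0.6$ to
$-0.7$) and the morphology-specific dEF/dGCS slopes. Volume indices are
log-normal with morphology-specific medians/IQRs; cardiac index, age,
BSA and sex follow the cohort-table summaries. Volume indices are *not*
coupled to strain in the generator — a known simplification: the real
cohort shows moderate strain-volume correlations that synthetic nulls
here do not emulate.

**Events.** Exponential proportional hazards:
$h_i = h_0 \exp(\beta^\top z_i)$ with $h_0 = 0.06$/year and
$z_i$ the standardized latent factors (defaults
$\beta = (0.7, 0, -0.5)$ for amplitude/timing/biphasic: weaker strain is
riskier, a distinct late diastolic relaxation slope is protective,
timing carries no independent hazard). Censoring is uniform on
$(0.5, 5)$ years (staggered entry against an administrative close-out at
5 years); setting `entry_spread = 0` gives pure administrative censoring,
under which the event fraction has the closed form $1 - e^{-\lambda T}$
used in validation. These defaults produce roughly 8-11 events per
stratum of about 60 and a median follow-up near 2 years. Occasional
subjects (4%) are "acquired" with 20-29 phases instead of 30 and are
interpolated up by the preprocessing stage.

## What passing tests do and do not show

The generator emulates the *statistical structure* of a Fontan strain
cohort: three dominant, nearly orthogonal shape factors plus isotropic
noise, morphology-specific amplitude scales, and a hazard linear in the
latent factors. Real feature-tracking curves have correlated,
non-stationary noise, drift, segment-averaging artifacts, arrhythmic
beats, and shape variation beyond three modes. Passing recovery tests
therefore demonstrates that the pipeline is *correct* (it finds what is
there, with the right numbers), not that three modes suffice for any
particular real cohort — that is an empirical claim the retention rule
re-evaluates on each dataset.

## Numerical choices and degenerate inputs

- Covariance divisor $N - 1$; symmetric eigensolver; rank cut at
  $10^{-12}\lambda_1$; score/eigenvalue identities verified to 1e-8 or
  tighter in the tests.
- Fewer than 2 curves per stratum: the stratum is skipped with a warning
  (pipeline) or an error (direct fit). Identical curves: degenerate, an
  error. Fewer than 2 events, or a constant covariate: Cox refuses with a
  specific error rather than returning an unstable fit.
- `characterize_modes()` uses $\pm 1.5$ SD reconstructions: mild enough
  that each mode mainly deforms the one feature it encodes (large
  time-shift excursions distort the recovery geometry of *any* mode).
  The recovery-shape feature is scored by the notch depth of the
  recovery limb below its peak-to-end chord — unlike a raw late/early
  slope ratio, that measure is insensitive to where the timing mode has
  dragged the recovery window. Feature-to-mode assignment maximizes the
  total normalized descriptor score over all permutations.
- ROC cutoffs enumerate midpoints of consecutive distinct values; with
  perfectly separating covariates the mid-gap threshold achieves
  Youden's J of 1.
- Analysis scale: structural claims about the spectrum are evaluated on
  cohorts of 200 subjects per morphology stratum averaged over 20 seeds;
  at the study's own size (67 + 55) eigenvalue shares carry sampling
  noise of several percentage points, which the tests acknowledge by
  asserting at the larger scale.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 20230724)     # study-size defaults
cohort <- generate_cohort(cfg)
m <- build_curve_matrix(cohort$curves, "GCS", "SRV")
model <- fit_shape_model(m)
model
select_components(model)                  # 3
characterize_modes(model)
scores <- compute_scores(model, m)
records <- cohort$subjects[cohort$subjects$morphology == "SRV", ]
records$gcs_pc1 <- scores$scores[match(records$subject_id,
                                       scores$subject_ids), 1]
cox_univariable(records, "gcs_pc1")
```

The numbered scripts under `analysis/` run the same pipeline end to end
(simulate, preprocess, fit modes, outcome analysis, associations) and
write tidy tables under `results/`.

## Known limitations

Beyond the generator simplifications above: the temporal normalization
assumes a single representative beat per subject (regular sinus rhythm);
segment-level strain, strain-rate curves, rotations/nonlinear embeddings
and cross-stratum joint models are deliberately out of scope; and the
event model ignores competing risks — composite first-event coding is
the only outcome structure supported.
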