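---
title: "Methods: simulating and analysing intermittent fMRI neurofeedback for meditation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing intermittent fMRI neurofeedback for meditation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `nfmed`. The package simulates and analyses a closed-loop
meditation training design: participants practise focused-attention
meditation inside the scanner while intermittent feedback rewards
deactivation of the posterior cingulate cortex (PCC), a default-mode-network
hub whose activity tracks self-referential processing and mind-wandering. A
yoked-sham control group receives a matched participant's feedback instead
of its own.

## The generative model

### NF runs

A run lasts 600 s at TR = 0.8 s (750 volumes) and follows the block layout
rest–(cue, meditation, feedback)×3–rest–(cue, meditation, feedback)×3–rest
with 51-s rest and 26-s meditation blocks. Cue (3 s) and feedback display
(10 s) durations are configurable defaults chosen to fill a plausible
fraction of the run; the mandated blocks alone occupy 309 s and the
remainder is an unmodeled gap at the end of the run. Onsets are 0-based
seconds; a volume belongs to an event when its start time falls in
[onset, onset + duration).

Each target voxel is generated as

    baseline * (1 + (signal + drift + physio + thermal) / 100)

with all components in percent of a per-voxel baseline drawn from
U(800, 1200) arbitrary scanner units:

* **signal** — the meditation boxcar convolved with a canonical
  double-gamma HRF (response peak 6 s, undershoot 16 s, undershoot ratio
  1/6), scaled by the target amplitude (default −0.5% PSC, i.e.
  deactivation). The HRF kernel is normalised to unit sum so a long block
  plateaus at the configured amplitude. Only a configurable fraction of
  voxels (default 0.5) carries the effect, with mean-preserving U(0.8, 1.2)
  amplitude heterogeneity, so dynamic voxel selection is non-trivial.
* **drift** — a slow linear-plus-half-cosine trend (default 0.3%
  peak-to-peak), standing in for scanner drift.
* **physio** — smoothed Gaussian noise shared between the target and
  confound ROIs with per-voxel U(0.5, 1.5) loadings (default SD 0.2%),
  standing in for respiration-driven signal. The confound ROI carries this
  component and thermal noise but no meditation signal.
* **thermal** — white noise, default SD 0.5%.

The generator emulates the statistical structure the analyses assume — a
deactivation of known amplitude, a nuisance component shared with a
confound region, drift, and seed-coupling modulation — not the physics of
acquisition: there is no anatomy, no spatial autocorrelation within ROIs,
no motion, and no true respiratory waveform. Passing tests therefore validate
the estimators' arithmetic and calibration under the assumed structure,
not their robustness to real-scanner artefacts.

### Behavioural cohorts

One row per subject, defaults at the study's analysable size of 19 per
group. Post-meditation state-mindfulness (SMS) scores at six sessions over
a week (days 0, 3, 4, 5, 6, 7) follow subject-specific linear
trajectories: group mean slopes +0.05 (experimental) and −0.05 (control)
points/day for SMS-Mind and 0 for SMS-Body, between-subject slope SD 0.15,
stable subject offset SD 2, residual SD 3 points, plus additive effects of
the pre-session score (0.4), sleepiness rating (−1.0 per SSS point), age
(0.05/year) and sex (0.5) that the residualization step must remove.
Scores are clipped to the instrument ranges (15–75 Mind, 6–30 Body) after
noise, with clipping logged; subscale intercepts put expected scores near
mid-scale so clipping is rare (<1%).

Distress (DASS-21 total) difference scores are drawn with the group means
and SDs the design reports (−4.8 ± 5.0 experimental, −1.6 ± 3.6 control).
The gPPI coupling beta is drawn jointly with the DASS change at the
configured within-group correlation (0.71 experimental, 0 control).
Breath-counting task accuracy changes are shifted by a standardised group
effect (default −0.4 SD in the experimental group, on a 10-point SD);
probe accuracy is discrete — five probes, so percentages in steps of 20 —
which is why the probe endpoint uses a rank-sum test. Age is U(19, 50)
(the inclusion range), sex a balanced binary covariate.

Under these defaults the SMS-Mind slope difference is a small standardised
effect (d ≈ 0.18 after slope-estimation noise), so a single n = 19 cohort
rarely reaches significance; the Monte-Carlo suites verify direction and
unbiasedness instead. This was a deliberate choice of realistic noise over
a flattering signal-to-noise ratio.

## The scoring engine

**Incremental GLM.** The real-time estimator is defined by its contract:
coefficients at volume *t* equal ordinary least squares on volumes 1..*t*
(relative tolerance 1e−8, verified against full refits at every volume on
random instances). It is implemented with cumulative sufficient statistics
(X'X, X'Y, y'y); states are underdetermined until p + 1 volumes have
arrived and raise an error if queried earlier. Non-finite volumes are
rejected with a warning, leaving the state unchanged. Where a whole run is
already in memory the equivalent state is built directly from the data
slice (`glm_state_from_data()`); the equivalence is itself a tested
invariant. The design has intercept, linear trend and the HRF-convolved
meditation regressor; linear detrending was chosen because the real-time
platform's internal detrending order is not public.

**Voxel selection.** After each block, the max(1, floor(0.33·V)) voxels
with the most negative meditation-vs-rest t are selected; ties break by
ascending voxel id. The confound ROI's voxels are selected by largest |t|,
since a physiological control region's "response" has no preferred sign.

**Scoring.** Per-volume PSC = 100·(observed − baseline)/baseline, with the
baseline the cumulative fit's intercept-plus-trend prediction (the model's
estimate of the average rest signal so far). The scoring window is shifted
by 4 s for haemodynamic lag (configurable; the design does not state a
value). Block scores average the per-volume PSC of the selected voxels
over the shifted window; a per-block extremum ("peak") summary is exposed
as a config switch. The target PSC series is residualized against the
confound PSC series by cumulative least squares (per volume, the stricter
reading of "cumulative"); a constant confound degrades to an
intercept-only fit with a warning. Scores are scale-invariant: multiplying
all raw intensities by any c > 0 changes nothing downstream.

**Thermometer.** Residual PSC is mapped linearly from [0, −1]% onto levels
1..20, clipped at both ends, rounded half away from zero (−0.5% → 10.5 →
level 11). The display bounds are invented defaults — the design never
states its mapping — and the map is monotone: more negative PSC never
lowers the level.

**Yoked sham.** A sham schedule replays a donor's scores verbatim, in
order, with an exact count check; donors are matched by nearest
meditation-experience hours with id tie-breaks. The recipient's actual
scores are computed and logged throughout, enabling the blinding check.

**Blinding check.** The block design imposes a deterministic within-session
score profile (scores shrink toward zero across blocks as the cumulative
baseline absorbs the meditation effect) that is common to all subjects, so
raw block-level correlations between an independent donor and recipient
are structurally inflated. `sham_blinding_pvalues()` therefore centres
each block cell across an ensemble of independent pairs before
correlating per pair — the analogue, at block level, of checking
contingency across participants, where design-driven structure cancels.
Under non-contingent feedback the resulting p-values are approximately
uniform. For a single session log, `run_endpoints()` reports an
approximate version that partials out run and block-position effects.

## Offline inference

**Block GLM.** Voxel-wise least squares on raw intensities with
HRF-convolved condition regressors (rest implicit), intercept, trend and
optional nuisance columns; rank deficiency raises an error naming the
collinear columns. The meditation coefficient is rescaled by the fitted
baseline (intercept plus mid-run trend) into PSC units, so a noiseless
−0.5% injection is recovered exactly; t-statistics come from the raw fit
and are scale-free.

**gPPI.** Per voxel: intercept, trend, meditation regressor, mean-centred
seed series, and the interaction seed × centred-meditation. Centring the
psychological regressor before the product makes the interaction estimate
invariant to adding constants to the seed. No deconvolution is applied —
with 26-s blocks the interaction formed on the convolved regressor is
standard practice, and the generator defines ground truth on the same
quantity. A condition-number guard and rank checks reject collinear
designs (e.g. a run with no rest volumes).

**Cluster-level permutation test.** Maps are residualized against
covariates, then a pooled-variance two-sample t map is thresholded at the
cluster-forming p (0.005, one- or two-tailed), 6-connected clusters are
labelled (Rcpp breadth-first search, verified against an independent
igraph flood-fill oracle), and each observed cluster statistic is compared
with the permutation distribution of the maximum cluster statistic under
group-label exchange. Covariates are removed by residualization before
permutation; the Freedman–Lane scheme is out of scope and this simpler
scheme is exact only when covariates are balanced, a documented
approximation. FWE p-values use (b + 1)/(B + 1) rather than the plain
fraction so they are strictly positive and valid at any permutation count;
at B = 500 the attainable rejection threshold is 25/501 ≈ 0.0499, leaving
the 5% calibration intact. Fewer than 100 permutations are refused — the
tail is too unstable to report.

The default cluster statistic is extent (voxel count), with mass (summed
t) as an option. On sparse null grids extent is so heavily tied (the max
cluster is almost always 1–3 voxels) that the max-statistic test becomes
conservative — valid but far below nominal. Calibration checks therefore
run on the mass statistic, which is continuous; extent's validity (never
anti-conservative) is asserted separately. Desk-scale defaults: 20×20×10
grids, 500–1000 permutations with logged seeds; the study-scale 10,000
permutations are a parameter away. Optional Gaussian smoothing is off for
synthetic grids.

## Behavioural endpoints

The "one regression slope per participant" procedure is operationalized as
pooled covariate residualization — post-session scores regressed on
pre-session score, sleepiness, age and sex across all subject-timepoints —
followed by per-subject least squares on days. This is the only reading
that yields exactly one slope per participant from a repeated-measures
covariate adjustment; a per-subject adjustment alternative would consume
the six timepoints in covariate estimation. Exactness caveat: pooled
residualization leaks finite-sample covariate estimates into the
residuals, so even noiseless trajectories recover group slopes only to
~0.01 points/day, not exactly. Subjects with incomplete timepoints are
dropped listwise (logged); fewer than three timepoints excludes a subject
from slope fitting.

Slope group differences use one-way ANOVA (verified against a
sums-of-squares oracle); difference scores use `diff ~ group + age + sex`
ANCOVAs, which nest to the two-sample t-test as covariate effects vanish.
Cohen's d is t·sqrt(1/n1 + 1/n2) signed experimental-minus-control (the
second factor level minus the first). The probe-accuracy rank-sum test
enumerates all label assignments on pooled midranks for combined n ≤ 12 —
ties are handled natively, which is why the exact mode is hand-rolled —
and uses the tie-corrected normal approximation (no continuity correction)
beyond that. Benjamini–Hochberg adjustment is the standard step-up with
family size m = 5; it is permutation-equivariant and never below the raw
p, but adjusted values are not a fixed point of re-adjustment (e.g.
{0.1, 0.4} → {0.2, 0.4} → {0.4, 0.4}), so no idempotence is claimed.
Partial correlations use the residual method with df = n − 2 − k and the t
transform t = r·sqrt(df/(1 − r²)); p-values are reported at full precision
in machine output and 3 decimals in tables.

## Problem sizes and determinism

The test suite runs its Monte-Carlo suites at sizes chosen to bound
sampling error while staying desk-sized: 200 null datasets × 500
permutations for FWE calibration, 100 seeds for gPPI recovery and the
sham-blinding analogue, 40 cohorts at n = 2000/group for direction checks
and 300 at n = 19/group for unbiasedness. All randomness flows from
explicit seeds; `pipeline_run()` derives per-stage seeds from one global
seed by a documented hash, and identical configuration plus seed gives
byte-identical outputs. File writes are atomic (write-then-rename).

## Known limitations

* ROI time series only; no spatial preprocessing, motion correction or
  multi-echo handling — assumed upstream.
* Covariate handling in the permutation test is residualization, not
  Freedman–Lane.
* The confound model is a single shared nuisance component, far simpler
  than real respiratory/cardiac structure.
* The behavioural generator draws difference scores directly where only
  moments are reported; its baseline levels are plausible inventions.
* Real-data results of any specific study (cluster locations, effect
  sizes at n = 19) are not reproduction targets; the package validates
  arithmetic, contracts and calibration against its own ground truth.
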