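---
title: "Methods: accelerometric gait outcomes, local-level trends, and MRI correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometric gait outcomes, local-level trends, and MRI correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dogait` implements the analysis chain of a longitudinal motor-function
study in dystrophin-deficient dogs: trunk-worn triaxial sensors during
15-m runs, monthly follow-up from 2 to 12 months of age in a small
unbalanced cohort (5 dystrophic, 6 wild-type), clinical and
activity covariates, and end-stage muscle MRI. This vignette explains
the models, the tunable parameters, the synthetic-data generator that
stands in for the recordings, and the numerical and design choices
made where the protocol left them open.

## Signal processing

A trial is one sensor placement's recording of one 15-m run: three
acceleration channels in G (X caudal-cranial, Y medial-lateral, Z
ventral-dorsal), three angular-velocity channels in dps, a quasi-static
standing window, and the start-goal run segment. Processing is:

1. **Gravity-offset removal** (`remove_gravity_offset`): the mean of
   each *acceleration* channel over the standing window is subtracted
   from every sample of that channel. Angular velocity carries no
   gravity component and is left untouched. The operation is idempotent.
2. **Run segmentation** (`segment_run`): all six channels are restricted
   to the start-goal segment.
3. **Summaries** (`summarize_trial`): mean absolute values per axis
   (`Ax..Az`, `Gx..Gz`), the trial-averaged acceleration magnitude
   `AM = mean_k sqrt(ax_k^2 + ay_k^2 + az_k^2)`, and the acceleration
   ratios, computed *per sample* as `100 |axis_k| / AM_k` and then
   averaged.

Open points resolved here, as package policy:

- **Order of operations.** The offset is estimated on the standing
  window of the full recording and subtracted everywhere, *then* the
  run is segmented. The reverse order would discard the calibration
  window before it could be used.
- **Ratio averaging.** Ratios are averaged per sample, not computed as
  the ratio of trial means; the two differ (a unit test demonstrates
  it) and the per-sample average is the one consistent with components
  "averaged in each trial".
- **`AM_k = 0` samples** contribute no direction; they are dropped from
  the ratio average and counted (`n_dropped` attribute, aggregated into
  the run manifest). A trial that is entirely static is rejected at the
  ratio stage.
- **Shortened standing windows.** The nominal calibration stance is
  10 s; windows down to 1 s are accepted with a warning (some real
  trials only allowed 2–5 s of stance), shorter ones are rejected.
- **Saturation.** Samples at the ±8 G / ±1000 dps bounds are kept but
  counted (`n_saturated`), since clipping cannot be undone.
- **Sessions.** Each 15-m pass is one trial; a session summary (one
  dog, region, month) is the unweighted mean of its four pass
  summaries.

## The local-level trend model

Outcomes form panels of (dog *i*, month *t*) observations. Positive
outcomes enter through the log; percentage ratios through the logit of
`r/100`. On the transformed scale the model is

$$z_{it} \sim N(m_t + \beta x_{it},\ \sigma_0^2), \qquad
  m_t \sim N(m_{t-1},\ \sigma_1^2),$$

a local level (random-walk-trend) state-space model with a single
latent trend per group and an optional covariate coefficient. There is
deliberately **no subject-level random effect**: the model pools all
dogs of a group around one trend, exactly as the model equations are
written, and the package does not silently "improve" on that. Months
without observations are allowed; the trend simply evolves across the
gap, which widens the credible band there (a tested property).

**Inference.** The Gibbs sampler (`fit_local_level`) alternates:

1. a *joint* draw of `m_1..m_T` by forward-filtering
   backward-sampling — within a month, the `n_t` observations enter as
   conditionally independent measurements of the scalar state, so the
   filter sees the month mean with variance `σ0²/n_t`;
2. conjugate inverse-gamma draws of `σ0²` and `σ1²`;
3. a conjugate normal draw of `β`.

An exact Kalman/RTS smoother (`kalman_smoother`) computes the same
trend marginals in closed form for fixed variances; it validates the
sampler (and is itself validated against dense joint-Gaussian
conditioning in the tests).

**Priors** (all configurable via `prior_spec`): `m_1 ~ N(0, 10²)` on
the transformed scale, `σ0², σ1² ~ inverse-gamma(0.001, 0.001)`,
`β ~ N(0, 10²)`. These are weakly informative at the scale of
log-accelerations (order ±2) and logit-ratios (order ±3). The original
analysis was run in general-purpose MCMC software without stated
priors; the test suite includes a sensitivity check showing the
excludes-zero decision on a strong planted effect is unchanged under a
markedly tighter prior.

**MCMC defaults**: 4 chains × 10 000 iterations, 5 000 burn-in, thin 1,
per-chain seeds derived from one base seed. Convergence is summarized
by a split-chain potential-scale-reduction statistic (flagged, not
fatal, above 1.05) and an autocorrelation-based effective sample size.
Reported intervals are equal-tailed 2.5%/97.5% sample quantiles — the
plain reading of a "95% credible interval" — and a coefficient
*excludes zero* when 0 lies outside that interval.

**Covariates** are fitted one outcome at a time (matching how
coefficient forests are usually presented), on the raw scale by
default with a standardization flag; the packaged pipeline standardizes
the synthetic covariates so that β is per SD. Trend fits are run
separately per group, region and outcome; covariate fits on dystrophic
dogs only.

## MRI module

The input boundary is the ROI table — muscle, side, ROI index, mean
intensity, pixel count, shared background-noise SD — because ROI
delineation on the images was manual and cannot be reproduced from
data. `SNR = intensity / SD_air`; `average_snr` pools a muscle's ROIs
across both sides by pixel-count weighting, which is invariant to
splitting an ROI into sub-ROIs with the same SNR.

The group comparison uses a **Mann-Whitney U test computed exactly**,
including midrank ties, by enumerating all assignments of the pooled
ranks when the combined sample is ≤ 12 (the study is 5 vs 6; there are
only 462 assignments). The two-sided p is the proportion of assignments
whose U deviates from `n1·n2/2` at least as much as observed. A
tie-corrected normal approximation serves larger samples. Tests are
two-sided at the 5% level throughout; sidedness was not specified in
the protocol, and two-sided is the conservative reading. Pearson's
correlation (via `stats::cor.test`) relates month-12 AM per region to
each muscle's Ave SNR across dystrophic dogs. The fast/slow muscle
grouping (fast TC, EDL; slow GM, GL, FDS) is carried as metadata only.

## The synthetic-data generator

The generator defines the study conditions; it is not tuned per test.

- **Trials** are a standing window (gravity + noise) followed by a sum
  of ≤ 3 harmonics of the stride frequency per axis with seeded random
  phases, plus Gaussian sensor noise, clipped at the sensor range. The
  published waveforms are described only qualitatively, so the shape is
  the simplest periodic signal with the right contracts; downstream
  checks rest on the algebra of the summaries, not biomechanical
  realism. Per-axis amplitude scales (WT peak 1.6/1.0/2.2 G on X/Y/Z)
  are order-of-magnitude choices inside the ±8 G range and are
  configurable. Wild-type amplitudes peak around month 4 (thoracic) or
  7–8 (lumbar); dystrophic amplitudes are elementwise lower, decline
  with age, and the gait shifts gallop → trot with a slower stride.
- **Panels** are drawn from the local-level model itself (the natural
  generative check for the fitter), with the back-transform keeping
  logit100 outcomes strictly inside (0, 100) via the stable logistic.
- **Clinical scores** sum seven signs graded 1–5 (totals 7–35), each a
  non-decreasing step process that plateaus; the number of summed signs
  follows the seven sign categories of the protocol and is documented
  as an assumption. **Activity counts** are Poisson around a
  dog-specific baseline decaying with age at a severity-scaled rate.
- **MRI ROI tables** use fixed per-muscle baseline intensities and
  deterministic pixel counts, a subject-level intensity intercept,
  per-ROI noise, and a dystrophic group shift.
- **Missing data**: the dog-months absent in the original cohort
  (thoracic recordings for four dogs at specific ages, two
  clinical-score cells, two activity cells) ship as a packaged fixture
  (`study_missing_data()`), so pipelines always face realistic
  unbalance.
- **Per-dog gain.** The pipeline multiplies each dog's amplitudes by a
  log-normal gain (SD 0.12). Without it all dogs of a group would be
  identical and the across-dog MRI correlation would be degenerate;
  with it, panels have realistic within-month spread.
- **Planted gait-MRI association.** In the pipeline, each dystrophic
  dog's muscle intensities are shifted in proportion to its
  standardized month-12 lumbar AM with a per-muscle sign (fast muscles
  negative, GL/FDS positive, GM negative), so the correlation stage has
  a known truth to recover.

What passing tests on this generator **do not** show: robustness to
non-sinusoidal waveforms, sensor drift, mis-marked standing windows,
non-Gaussian observation noise, or trends that are not random walks.
The generator emulates the study design, not dog biomechanics.

## Reproducibility and problem sizes

Every generator and sampler is a pure function of its arguments
including a seed; sub-streams are derived by hashing the base seed with
stage/dog/month labels (`derive_seed`), so adding a dog never perturbs
another dog's draws. Study runs write only plain CSV/JSON and are
byte-identical under a fixed seed.

The test suite exercises: exact signal algebra; smoother-vs-dense-oracle
agreement on 200 random instances (T ≤ 5, ≤ 10 observations, 1e-8);
sampler-vs-smoother agreement on 10 panels with fixed variances (within
3 Monte-Carlo standard errors); coefficient recovery over 50 simulated
panels per β ∈ {−0.5, 0, +0.5} at the cohort's scale (6 dogs, 11
months, σ0² = 0.04, σ1² = 0.01) with 2 chains × 2 000 iterations per
fit — enough for interval decisions while keeping the suite's runtime
modest; exact Mann-Whitney enumeration against a bitmask oracle; and an
end-to-end strong-effect study at 2 chains × 1 500 iterations. The
acceptance script re-runs the full study at 2 chains × 4 000 iterations
and a 20-replicate recovery loop. For final inferences on real data the
defaults (4 × 10 000) are recommended.

## Known limitations

- One shared trend per group: no subject-level effects, no joint
  modelling across outcomes or regions, no model comparison (DIC/WAIC).
- The inverse-gamma(0.001, 0.001) variance prior is a convention, not
  an endorsement; with very few observed months `σ1²` is weakly
  identified and its posterior leans on the prior.
- Exact Mann-Whitney enumeration is quadratic in `choose(n, n1)`;
  beyond combined n ≈ 20 use the normal approximation.
- The MRI module starts at the ROI table; nothing is inferred from
  images, and `SD_air` conventions (per image vs per slice) are the
  caller's responsibility — one value per ROI row is accepted.
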