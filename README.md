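# dogait

Longitudinal gait analysis for canine models of Duchenne muscular
dystrophy, from wearable triaxial accelerometer/gyroscope recordings to
Bayesian trend models and muscle MRI correlation.

Dystrophin-deficient dogs (CXMD_J, GRMD) progressively lose motor
function between 2 and 12 months of age. A small hybrid sensor worn on
the dorsal thoracic or lumbar trunk during 15-m runs records triaxial
acceleration (±8 G, X caudal-cranial / Y medial-lateral / Z
ventral-dorsal) and angular velocity (±1000 dps) at 20 ms resolution.
`dogait` turns those recordings into per-trial outcomes, models their
monthly trends in small unbalanced cohorts, and relates end-stage gait to
muscle involvement measured on T2-weighted MRI. A synthetic-data
generator emulates the whole study design — waveforms, longitudinal
panels, clinical covariates, MRI ROI tables, and the missing dog-months
of the original cohort — so every stage is testable without recordings.

## What it computes

**Signal processing.** After subtracting the gravity (DC) offset
estimated on a quadrupedal standing window and restricting to the
start-goal run segment, each trial yields:

- mean absolute axis vectors `Ax, Ay, Az` (G) and `Gx, Gy, Gz` (dps);
- acceleration magnitude `AM_k = sqrt(Ax_k² + Ay_k² + Az_k²)` per
  sample, averaged per trial;
- acceleration ratios: per-sample `100·|axis_k| / AM_k`, averaged per
  trial.

**Trend modelling.** Outcomes form unbalanced dog-month panels fitted
with a Bayesian local-level state-space model on a transformed scale
(`log y_it` for magnitudes, `log(r_it / (100 − r_it))` for ratios):

    z_it ~ N(m_t + β·x_it, σ₀²),    m_t ~ N(m_{t−1}, σ₁²)

with one latent trend `m_t` per group, Gaussian observation noise σ₀²,
random-walk evolution σ₁², and an optional covariate coefficient β
(clinical score or spontaneous locomotor activity). The posterior is
sampled by a Gibbs sampler whose state draw is exact forward-filtering
backward-sampling; an exact Kalman/RTS smoother provides independent
validation. Trends are reported with equal-tailed 95% credible bands; a
coefficient "excludes zero" when 0 lies outside its 95% interval.

**MRI.** ROI signal-to-noise ratios `SNR = intensity / SD_air` are
pooled per crus muscle into the pixel-weighted bilateral average
`Ave SNR = Σ(SNR_i·Pixel_i) / Pixel_Total`, compared between groups by
an exact Mann-Whitney U test (midrank ties handled by full enumeration
at the study's 5-vs-6 size), and correlated with AM by Pearson's test at
the 5% level.

## Worked example

Process one synthetic dystrophic trial, then fit a covariate model to a
simulated panel:

```r
library(dogait)

profile <- default_gait_profile("DYS", month = 8, region = "lumbar")
trial <- generate_gait_trial(profile, seed = 42, dog_id = "13102MA",
                             region = "lumbar", month = 8)
trial <- segment_run(remove_gravity_offset(trial))
print(summarize_trial(trial), digits = 3)
#>    dog_id phenotype region month    Ax    Ay    Az    AM Ax_ratio Ay_ratio
#> 1 13102MA       DYS lumbar     8 0.291 0.185 0.378 0.557     54.5     34.3
#>   Az_ratio   Gx   Gy   Gz
#> 1     62.2 21.6 38.3 26.3
```

The dog moves at ~0.56 G overall magnitude, with the ventral-dorsal (Z)
axis carrying the largest share of the motion (62% ratio), as expected
for a galloping quadruped.

```r
dogs   <- sprintf("d%02d", 1:6)
months <- 2:12
scores <- standardize_covariate(
  generate_covariate_series("clinical_score", dogs, months,
                            severity = 0.8, seed = 2))
trend  <- simulate_latent_trend(months, m1 = 0.4, sigma1_sq = 0.01, seed = 3)
truth  <- true_panel_params(trend, sigma0_sq = 0.04, sigma1_sq = 0.01,
                            beta = -0.5, transform = "log")
panel  <- generate_panel(truth, dogs, months,
                         covariate_table = scores[c("dog_id", "month", "x")],
                         seed = 4)
fit <- fit_local_level(panel, mcmc = mcmc_control(chains = 4,
                                                  iterations = 4000,
                                                  burn_in = 2000, seed = 5))
fit
#> <local_level_fit> 66 obs over months 2-12 (log transform)
#>   sigma0^2 0.03678 [0.02564, 0.05318]; sigma1^2 0.003997 [0.0004498, 0.01617]
#>   beta -0.5284 [-0.6002, -0.455] (credible interval excludes 0)
```

The planted coefficient β = −0.5 (log-AM per SD of clinical score) is
recovered at −0.53 with a 95% credible interval [−0.60, −0.46] that
excludes zero: dogs with worse clinical scores move with lower
acceleration. `fit$trend` holds the per-month posterior trend with its
credible band on both the transformed and natural scales;
`compare_trends()` contrasts wild-type and dystrophic fits month by
month.

A full study — 11 dogs, both regions, months 2–12, four passes per
session, trend and covariate fits, MRI SNR comparison and gait-MRI
correlation — runs from a single declarative configuration:

```r
res <- run_study(strong_effect_config(seed = 1), "study_out")
res$trend_comparisons$AM_thoracic  # WT vs DYS trend, month by month
res$forest                         # covariate coefficients with 95% CIs
res$mann_whitney                   # per-muscle Ave SNR group comparison
res$correlations                   # AM vs Ave SNR, 2 regions x 7 muscles
```

All outputs are plain CSV/JSON in `study_out/`, byte-identical across
reruns with the same seed.

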