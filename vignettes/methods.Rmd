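---
title: "Biological age acceleration from wearable step counts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological age acceleration from wearable step counts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiage)
```

## Overview

`actiage` estimates **biological age acceleration (BAA)** — the number of
years of morbidity-equivalent aging added to, or subtracted from, a
person's chronological age — from minute-level step counts recorded by
wearable or phone sensors. The package covers the full chain:

1. **Step counting** from raw acceleration magnitude (`count_steps_per_minute`).
2. A small **convolutional network** mapping weekly step patterns to BAA
   (`baa_model_init`, `train_baa_model`, `predict_baa`), with
   distribution-alignment losses that remove device, season and
   missing-data batch effects.
3. **Gompertz mortality** fitting and closed-form life expectancy
   (`gompertz_fit`, `life_expectancy`).
4. **Resilience analysis**: the autocorrelation time of daily BAA
   fluctuations as a measure of how quickly an organism recovers from
   perturbations (`estimate_resilience`, `cohort_recovery_trend`,
   `nonresilient_fraction`).
5. The **subsampled Mann-Whitney / Fisher** group-comparison procedure
   (`mannwhitney_fisher`) and rank AUC (`roc_auc`).
6. A **synthetic-data generator** (`sim_config`, `simulate_cohort`,
   `simulate_step_series`, ...) that produces every input the pipeline
   needs, with the statistical structure the analyses assume.

Because real biobank or app data cannot ship with a package, all tests and
examples run on synthetic cohorts; the generator is first-class, tested
code.

## Step counting

Steps are counted from the Euclidean magnitude of acceleration, which is
about 1 g at rest. A step is a strict local maximum exceeding **1.3 g**.
To suppress local noise, a **480 ms window sliding by 160 ms** admits only
its highest peak; we implement this as an elimination rule — a candidate
is counted only if it is the highest in *every* window containing it.
The naive alternative ("each window nominates its maximum, nominations are
deduplicated") fails the defining bound of the procedure: with one peak
per 160 ms frame and monotonically increasing heights, every frame would
be nominated by the window it terminates, yielding 6 counts per 960 ms.
Under the elimination rule two counted steps can never share a window, so
they are more than 320 ms apart and **at most 3 steps are registered per
960 ms** — which is the stated purpose of the windowing. Counted steps
separated by less than **90 s** form walking bouts; bouts with fewer than
**5 steps** are discarded. Retained steps are bucketed into whole minutes.

Window grids are anchored at the trace start (the procedure does not
specify an anchor); ties in magnitude resolve toward the earlier peak; a
trailing partial minute is dropped. No low-pass filter is applied before
peak detection.

## The BAA network

Minute counts are one-hot encoded in bins of **4 steps/min** (64 bins,
top bin open-ended; counts ≥ 252 steps/min saturate). The encoder is a
stack of **16 one-dimensional convolutional layers, 16 filters each,
kernel 3**, elu activation, batch-normalised, with local max-pooling
(stride 2, 3 or 5) after every second layer. The pooling strides multiply
to 1440, so the block emits a feature vector **per day**; a final 1×1
projection reduces the 16 channels to **4 features per day** (the
architecture specifies 16 filters throughout yet 4 output features; the
1×1 projection is our reading of that reduction). Daily features are
averaged over a trailing **7-day window** and combined linearly with the
binary sex label:

    BAA(d) = w · mean(features[d-6..d]) + w_s · sex + b   [years]

so day `d`'s prediction uses days `d-6` through `d`, and the first six
days of any track are flagged invalid.

**Morbidity link.** Biological age is `age + BAA`. The morbidity
probability is `sigmoid(k · (age + BAA) + c)` with trainable `k > 0`
(parameterised `exp(log k)`) and offset `c` — the logistic approximation
to a proportional-hazards model, appropriate when events are rare. A raw
sigmoid of age in years would saturate, hence the trainable scale;
`k` is initialised at 0.09/yr (the Gompertz-like slope of morbidity
prevalence in human cohorts) and `c` at −0.09 × 65 so the initial
midpoint sits at biological age 65.

**Domain adaptation.** For each pair of domains (wrist vs hip research
devices; phone vs watch; summer vs winter; clean samples vs copies with
1-3 days zero-imputed) we fit a univariate Gaussian per feature to each
side's pooled weekly features and penalise the symmetrised
Kullback-Leibler divergence, summed over features. The estimator is the
per-feature Gaussian approximation with a variance floor of 1e-6. The two
sides of a pair are forwarded as one concatenated batch so batch-norm
statistics are shared — otherwise per-batch normalisation would hide the
very difference the loss is meant to remove. Missing days are zero-imputed
(and flagged) rather than masked out, and the missingness adaptation pair
teaches the encoder to ignore them; at inference zero-imputed days are fed
to the network as-is.

**Training.** Cross-entropy on the morbidity label plus
`adaptation_weight` (default 1) times the summed KL losses, minimised
with Adam. The full profile is **2000 iterations, batch 256, learning
rate 1e-3**, with the minor labelled domain contributing to the class
loss one iteration in five. The scaled-down profile used throughout the
test suite keeps the architecture's design at a size a laptop CPU handles:
4 layers of 8 filters (pooling strides 6, 6, 5, 8 — four pooling layers
cannot reach the required product 1440 with strides ≤ 5), 200 iterations,
batch 64, 12 samples per adaptation side, and **learning rate 1e-2**: a
tenth of the iterations needs roughly ten times the per-step movement, the
standard trade-off when shrinking a training schedule. In both profiles
the six scalars of the BAA head and the logistic link get a **10x
learning-rate multiplier** (`head_lr_mult`): their gradients are damped by
the logistic slope `k` (about 0.09/yr) while their operating point is at
years scale, so without larger steps they dominate the convergence time.
Training is deterministic given the seed; divergence (non-finite loss)
aborts with a diagnostic. The efficacy checks in the test suite train on
700 synthetic subjects with 150 held out — per-iteration cost does not
depend on cohort size, and several hundred subjects are needed before the
planted pattern's logistic effect (a fraction of a logit standard
deviation) is statistically resolvable.

**Edge behaviour.** Convolutions use zero padding, so feature vectors for
days at the very start and end of a series are influenced by the padding;
interior days are translation-equivariant. With the real 1440-minute day
the receptive field of the stack is small relative to a day and the effect
is confined to the outermost days.

## Gompertz mortality and life expectancy

With mortality rate `M(t) = M0 exp(Γ t)`, a cohort observed from
enrollment to end of follow-up contributes the negative log-likelihood

    -lnLH = Σ_all (M0/Γ) e^(Γ t_n) (1 - e^(-Γ Δt_n)) - Σ_dead (ln M0 + Γ t_n)

where `t_n` is the age at end of follow-up and `Δt_n` the follow-up
duration. We minimise over `(ln M0, ln Γ)` (positivity for free) with
BFGS from a moment-style start (`Γ0 = 0.09/yr`,
`ln M0 = ln(deaths/exposure) − Γ0 mean(t)`); the printed likelihood is
taken as complete (no additional left-truncation term). Life expectancy
uses the closed form

    t̄ = (1/Γ) ln(Γ/M0) − γ/Γ

with the Euler-Mascheroni constant γ = 0.5772156649 at double precision
(0.58 is display rounding only). The expression is asymptotically exact
for `M0/Γ → 0`; the package warns when `M0/Γ > 0.01` and the test suite
verifies agreement with the numerically integrated survival curve to
better than 0.1 years whenever `M0/Γ < 1e-3`.

## Resilience from BAA autocorrelation

Daily BAA fluctuates around a personal baseline; how fast the
autocorrelation function (ACF) of those fluctuations decays measures how
quickly the organism returns to equilibrium after perturbations — slow
decay ("critical slowing down") signals loss of resilience. We use the
biased normalised ACF estimator with lag products restricted to valid
(non-missing) days, and fit `C(k) = exp(−k/τ)` by least squares of
`ln C(k)` on `k` through the origin, over the initial run of positive ACF
values at lags 1–28 (the fit stops at the first zero crossing; the
exponential model has no support there). Log-linear rather than nonlinear
least squares keeps the estimator deterministic and testable; the
difference is immaterial at the noise levels exercised. Subjects whose
ACF decays too fast to resolve (fewer than 3 positive lags) have small τ
and are classified resilient; per-track mean removal is the only
detrending (season is handled upstream by the network's adaptation).

Cohort trends bin subjects into 5-year age bins, average rates per bin,
and fit a weighted linear regression of mean rate on bin-centre age; the
zero crossing of the declining trend estimates the age of complete
resilience loss, with a bootstrap over individuals for its confidence
interval. The **non-resilient fraction** per bin counts recovery times
exceeding **3 weeks (21 days)**; regressing `ln(fraction)` on age gives
the exponential growth rate α (1/year) and doubling time `ln 2 / α` — at
α = 0.087/yr the fraction doubles every ~8 years, the mortality-rate
doubling time of the human Gompertz law.

## Group comparisons

P-values depend strongly on sample size, so comparisons cap each group at
**500 samples per test**, repeat over **100 random subsamples**, and
combine the p-values by **Fisher's method** (`X = −2 Σ ln p_i` against
chi-square with `2·100` degrees of freedom). When a group already fits
under the cap the resamples coincide and the combination is degenerate;
the procedure is implemented faithfully (that is how the reported
p-values are defined) and the result flags `degenerate = TRUE`. The
Mann-Whitney test uses the exact distribution for groups of ≤ 20 and the
continuity-corrected normal approximation otherwise; subsampling is not
age-stratified.

## The synthetic-data generator

The generator emulates exactly the features the analyses rely on:

* **Circadian structure**: a two-peak weekday template (morning and
  evening commute bouts around 08:00 and 18:00, a midday shoulder, near
  silence 23:00–06:30) and a flatter, later weekend template. Daily
  totals are lognormal around 8,500 steps (subject-level spread 0.35 on
  the log scale, day-to-day ±20%).
* **The planted BAA signal**: latent BAA multiplies the morning bout by
  `exp(−pattern_link · BAA)` and the evening bout by its inverse
  (`pattern_link` default 0.06 per year), shifting activity later in the
  day **at fixed daily total** in `pattern_only` mode. The counts are
  drawn by a multinomial conditioned on the day total, so two subjects
  differing only in latent BAA have identical totals and different minute
  layouts — a correct model must beat the mean-steps baseline by reading
  the pattern, not the level. The strength of this link is a free
  simulation parameter; no quantitative value is available to match.
* **Batch effects**: phones record a binomially thinned fraction
  (default 0.6) of true steps; winter scales totals by 0.8; with
  probability `missing_day_rate` a subject loses 1–3 whole days,
  zero-imputed and flagged, matching the "up to 3 zero-imputed days"
  convention.
* **BAA dynamics**: daily latent BAA follows a discretised
  Ornstein-Uhlenbeck (AR(1)) process
  `x(d+1) = x(d) e^(−1/τ) + σ √(1 − e^(−2/τ)) ε`, whose ACF is exactly
  `e^(−k/τ)`. Individual relaxation rates are drawn log-normally
  (log-sd 0.5; no inter-individual distribution is documented, so a
  log-normal was chosen once as the natural positive-support model)
  around a mean that declines linearly with age,
  `r̄(age) = r0 (1 − age/110)`: zero at 110 years, with `r0 = 0.157/day`
  placing the mean recovery time near two weeks at age 60 ("a few
  weeks").
* **Survival**: event times are drawn by inverse-CDF from the Gompertz
  hazard `M0 = 2e-5/yr`, `Γ = 0.09/yr` evaluated at *effective* age
  (chronological + latent BAA), so BAA carries real mortality signal;
  morbidity is Bernoulli with logistic probability in biological age
  (slope 0.09/yr, midpoint 65 y).

What the generator does **not** emulate: real marginal distributions of
biobank step counts, tri-axial acceleration (magnitude only), intra-day
autocorrelation of activity beyond the template, device-specific noise
spectra, or informative missingness. Passing tests therefore demonstrate
that the algorithms recover planted structure of the kind the analyses
assume — not that the trained network transfers to any real device.

## Numerical choices and degenerate inputs

* Optimisation on log-parameters is clamped to ±30 to keep `exp()` away
  from under/overflow during line search; non-finite likelihood values
  return a large penalty.
* The KL estimator floors variances at 1e-6 (gradient set to zero on the
  floored side).
* Max-pooling breaks ties toward the earlier sample; gradient checks use
  a wide bin alphabet because pooling ties are genuine kinks of the loss.
* Constant tracks, zero-variance groups, single-class labels, cohorts
  with no deaths, and all-missing series raise errors rather than
  returning `NA`.
* Problem sizes in the test suite were chosen for a single CPU: cohorts
  of a few hundred subjects for network training, 50,000 for the Gompertz
  round trip, 100 replicates per planted τ for the resilience recovery,
  and the 4-layer/8-filter encoder profile. Each size is stated in the
  test that uses it.

## Known limitations

* The hand-written network trains on CPU only and at desk scale; the full
  2000-iteration, 16-layer profile is implemented and tested for shape
  and gradient correctness but not exercised end-to-end in the test
  suite.
* The adversarial-discriminator variant of domain adaptation is not
  implemented; the KL formulation is.
* Per-user ACF fits with cohort averaging of rates are implemented;
  pooled cohort-level ACF fitting is a possible variant that is not.
* The Gompertz module fits no covariates (no Cox-type extension) and
  handles only the enrollment-to-end-of-follow-up observation window.
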