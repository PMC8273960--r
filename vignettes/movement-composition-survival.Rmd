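---
title: "Compositional survival analysis of daily movement behaviours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional survival analysis of daily movement behaviours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilrsurv)
```

## The problem and the model

Time-use epidemiology asks how the daily balance of sedentary behaviour
(SB), light-intensity physical activity (LIPA) and moderate-to-vigorous
physical activity (MVPA) relates to disease incidence. The three durations
are not free to vary independently: they partition a finite waking day, so
a model that enters them as separate covariates either drops one
arbitrarily or conditions on an impossible contrast (one behaviour changes,
nothing compensates). `ilrsurv` treats the triple as a *composition* —
only relative information matters — and analyses it in Aitchison geometry.

Each subject's minutes are closed to a 960-min (16-h) waking day and mapped
to two isometric log-ratio pivot coordinates. Under the SB-first pivot
order,

$$z_1 = \sqrt{2/3}\,\ln\frac{SB}{\sqrt{LIPA \cdot MVPA}}, \qquad
  z_2 = \sqrt{1/2}\,\ln\frac{LIPA}{MVPA}.$$

$z_1$ contrasts SB against the geometric mean of the two activity
behaviours; $z_2$ contrasts LIPA against MVPA. Re-ordering the pivot
(LIPA-first, MVPA-first) yields two further *rotations* — orthogonal
reparameterisations of the same two-dimensional space in which each
behaviour takes its turn as the first coordinate. The three rotations are
implemented as pivot-order permutations with the same
$(\sqrt{2/3}, \sqrt{1/2})$ coefficients, so the first coordinates of the
three rotations sum to zero and all pairwise Aitchison distances agree
across rotations; both identities are enforced by property tests.

The coordinates enter a Cox proportional hazards model alongside
conventional covariates:

$$h(t \mid x) = h_0(t)\, \exp(\beta_1 z_1 + \beta_2 z_2 + \gamma^\top c).$$

Because the rotations are orthogonal maps, the partial likelihood, linear
predictors and every derived contrast are identical across them — only
$(\beta_1, \beta_2)$ rotate. The package exploits this as a free internal
consistency check (agreement to $10^{-6}$ is asserted in the test suite).

## Assumptions

* **Proportional hazards** for the coordinates and covariates, checked via
  the Grambsch–Therneau scaled-Schoenfeld test (`ph_check()`, delegating to
  `survival::cox.zph`).
* **Cause-specific censoring**: deaths from causes other than the study
  outcome censor follow-up; no subdistribution (Fine–Gray) hazard is
  estimated. This answers the aetiological question, not the predictive
  one.
* **Strictly positive compositions**: a recorded zero is an observation
  below the measurement resolution, handled by imputation before the
  log-ratio transform (below).
* **Ties** in follow-up time (times recorded in days) are handled by the
  Efron approximation, the default of modern survival tooling.

## Zero imputation

One 60-s epoch is the resolution of the input data, so the default
detection limit is 1 min/day. `impute_zeros_lrem()` treats zeros as
left-censored values in additive log-ratio space: with three parts and at
most one zero per row, each censored row contributes one censored alr
coordinate, whose conditional distribution given the observed coordinate is
univariate normal. The EM algorithm replaces censored coordinates by
truncated-normal conditional moments (E-step) and updates the alr mean and
covariance (M-step), starting from multiplicative replacement at 65% of the
detection limit, with tolerance $10^{-8}$ on parameter change and at most
500 iterations. The observed-data log-likelihood is recorded per iteration
and must be non-decreasing; the test suite additionally verifies the fixed
point against a direct numerical maximisation of the censored likelihood.
Imputed cells land strictly inside $(0, \text{limit})$; donor parts are
rescaled so row totals are preserved exactly. Multiple imputation is out of
scope — the EM fixed point is a deterministic single imputation.

## From accelerometer epochs to compositions

`classify_epoch()` applies intensity cut-points to 60-s epoch-average
accelerations (ENMO, milligravity): SB below 40 mg, LIPA in [40, 100),
MVPA at or above 100 mg. The LIPA band is half-open so the bands are
exhaustive and disjoint at any fractional acceleration; a 45 mg SB/LIPA
boundary is available as the usual sensitivity setting. A day is *valid*
when worn time covers at least 2/3 of the waking period; subjects need at
least 2 valid weekdays and 2 valid weekend days, otherwise they are
excluded (recorded in an exclusion ledger, never silently dropped). With a
full week of valid days the subject mean is the plain mean; otherwise
weekday and weekend means are combined with calendar weights 5/7 and 2/7 —
the natural choice when no other weighting is stated. Non-wear epochs are
excluded from counting; wear flags are inputs (the upstream non-wear
imputation and sleep detection of raw-accelerometer processing are outside
this package's scope).

## Reference compositions and reallocation

Hazard ratios for coordinates are hard to read directly, so results are
expressed as isotemporal reallocations: move $\delta$ minutes from one
behaviour to another, hold the third fixed, and contrast against a
reference composition. Two families of references are built in:

* **MVPA-anchored** (`build_reference_mvpa()`): MVPA fixed at 10, 21
  (daily equivalent of the 150 min/week guideline, `round(150/7)`) or
  30 min, with SB taking 77% of the remaining waking time by default — the
  typical population share of non-MVPA time. The share is an explicit
  argument, and fractional minutes are kept exactly rather than rounded to
  display values; rounded h:min presentations of such references are
  mutually inconsistent at the minute level, which is why the package
  computes from exact fractions and rounds only for printing.
* **SB-anchored** (`build_reference_sb()`): SB and MVPA fixed (e.g. SB at
  9 h or 14 h, roughly the 5th and 95th cohort percentiles, MVPA 10 min),
  LIPA absorbing the remainder.

For a fitted model, `log HR = \beta_z^\top (z_{new} - z_{ref})` with
standard error $\sqrt{\Delta z^\top \Sigma_z \Delta z}$ from the coordinate
block of the coefficient covariance: covariates are held at identical
values on both sides of the contrast, so their terms cancel exactly and
the delta method needs no approximation beyond the usual Wald normality
(level fixed at 95%). A displacement that would drive the donor behaviour
to zero or below is infeasible and reported as a flagged cell, mirroring
the "not observed" entries of a reallocation table. A bootstrap
re-estimation of the interval was considered and set aside: the contrast
is linear in the coefficients, so the delta method is exact given
asymptotic normality of $\hat\beta$.

Reallocation effects are intrinsically asymmetric: because the coordinates
are logarithmic in the parts, removing 10 min from a 21-min MVPA budget
moves the coordinates further than adding 10 min, so the adverse log-HR of
a loss exceeds the protective log-HR of an equal gain whenever MVPA is
protective. Only in the $\delta \to 0$ limit do the two directions agree
(first-order antisymmetry, verified numerically at $\delta = 0.01$ min).

`hr_surface()` evaluates the HR of every composition on a regular minute
grid against the reference, restricted to observed behaviour ranges, and
`plot_hr_ternary()` renders it in ternary coordinates with the reference
marked; the colour scale is clipped to [0.8, 1.3] for display only.

## The synthetic cohort generator

The motivating cohort data are access-restricted, so the package ships a
generator (`sim_config()`, `simulate_cohort()`) that reproduces the
*statistical structure* the analysis assumes and makes every stage testable:

* **Compositions** are logistic-normal: bivariate normal ilr coordinates
  (SB-first) back-transformed to the 960-min simplex. A logistic-normal
  rather than a Dirichlet matches the geometry of the analysis and lets the
  mean and covariance be calibrated directly. The default
  `mean_ilr = (1.588, 1.002)` and covariance
  `((0.1955, 0.0961), (0.0961, 0.1410))` were obtained once by
  moment-matching (Nelder–Mead on a fixed 200,000-draw sample) so the
  behaviour means are (692.1, 209.5, 58.4) min/day with SDs
  (88.4, 65.1, 37.6) — the target cohort's descriptives. The implied
  SB–activity correlation is negative, as it must be on a closed budget;
  the printed descriptives do not pin down the covariance uniquely, so the
  calibrated values are documented assumptions.
* **Covariates** follow `default_covariate_spec()`: age normal(68.9, 5.6)
  years, 26.7% women, and categorical sociodemographic, lifestyle and
  cardiometabolic factors with realistic prevalences; effects enter the
  log hazard through `gamma`, centred at their population means so effect
  sizes do not shift the baseline calibration. Covariates are independent
  of the composition by default, which lets tests isolate what adjustment
  does; confounding can be emulated by shifting `mean_ilr` per stratum in
  user code.
* **Outcomes**: event times by inverse transform from a Weibull baseline
  (default shape 1, scale 76.02 years — calibrated so the default
  configuration yields a 9.0% cumulative incidence, ~299 events in 3319
  subjects); independent exponential competing mortality (rate 0.012/yr);
  administrative censoring uniform on 6.0–7.5 years, emulating staggered
  entry with a fixed end of follow-up. The resulting mean follow-up is
  ~6.2 years (SD ~1.5). Times are rounded to whole days so ties occur, as
  they do with registry-linked follow-up. True coordinate effects default
  to $\beta_z = (0.30, 0.15)$ (SB-first), making MVPA protective.
* **Recorded zeros**: MVPA is truncated to zero with probability
  `zero_rate_mvpa` (default 1%, a parameter because the true rate is not
  observable from published descriptives) to exercise the imputation path.
* **Waking duration** varies normal(960, 40) min per subject; recorded
  minutes sit on the subject's own waking day. The ilr transform is
  scale-invariant per row, so closure to 960 min changes nothing in the
  coordinates — the non-normalised sensitivity analysis instead keeps raw
  minutes and adjusts for `waking_min`.
* **Epoch streams** (`simulate_epochs()`): 960 one-minute waking epochs per
  day with accelerations at fixed in-band values (noise-free, for exact
  round-trip tests) or multinomial counts with uniform in-band values.

What the generator does *not* emulate: measurement error in the
accelerometer, informative censoring, confounding by indication,
repeated-measures compositions, or the selection processes of a real
cohort. Passing tests on synthetic data therefore demonstrate that the
estimator recovers the truth *under the model's own assumptions* — they
cannot certify the assumptions for any particular real dataset.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route: closure
and ilr against hand-evaluated constants; the EM imputation against direct
numerical maximisation of the censored-data likelihood; aggregation against
counting oracles and hand arithmetic; the Cox layer against rotation
invariance, null recovery, a step-change hazard that the PH test must
detect, and an injected stratum shift that the interaction test must
detect; reallocation against a hand-evaluated closed form and the
first-order antisymmetry limit. The heavier simulation studies use 200
replicates of n = 3319 (~9% events) for bias and coverage of
$\hat\beta_z$, and 500 null replicates of n = 2000 for the empirical size
of the Wald, interaction and proportional-hazards tests — sizes chosen so
Monte-Carlo error is small relative to the acceptance bands while the
whole suite stays fast on one CPU (about half a minute). The type-I
simulations use a reduced covariate set (age, sex, hypertension, diabetes)
for speed; the fitted model matches the generating model either way.

## Sensitivity analyses

`run_pipeline()` exposes the standard robustness toggles: the 45 mg
SB/LIPA cut-off; exclusion of events in the first 2 years of follow-up
(reverse causation), either dropping those subjects — the default, since
their exposure cannot be re-used once their event is discarded — or
censoring them at the event time; a non-fatal-only outcome with fatal
events censored at death; and the non-normalised analysis adjusting for
waking duration. Each stage logs rows in/out, and every input subject ends
in exactly one of the analysis set or the exclusion ledger.

## Numerical choices and limitations

* Closure sets the third part by subtraction so row sums are bit-exact;
  downstream invariants are therefore testable at machine precision.
* Internal units are fractional minutes throughout; rounding is
  display-only (`h:min` formatting).
* The joint effect-modification test is a 2-df Wald test on the two
  interaction coefficients; per-coordinate Wald p-values are reported
  alongside, since either convention appears in applied work.
* Collinear covariates abort the fit with the offending terms named,
  rather than silently dropping columns.
* Compositions are fixed at three parts; sleep is outside the composition
  (the waking-day framing), and amalgamations beyond the three pivot
  rotations are not provided.
* The EM imputation requires at least one behaviour with no zeros to
  anchor the alr transform, and at most one zero per subject — both are
  guaranteed in this 3-part waking-day setting but would need
  generalisation for higher-dimensional compositions.
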