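---
title: "Methods: factorial iron requirement and population risk of inadequate intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial iron requirement and population risk of inadequate intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironear)
```

## The problem

Whether a population's dietary iron intake is adequate cannot be judged
against an RDA: the RDA is set so that an *individual* consuming it has a
small (~2.5%) risk of inadequacy, and comparing population intakes to it
grossly overstates the prevalence of deficiency. What is needed is the full
*requirement distribution* — its median (the EAR) and upper percentiles (the
RDA) — and a method that confronts it with the *intake distribution*.
`ironear` implements that chain for non-pregnant, non-lactating women of
reproductive age (WRA): evidence synthesis of iron-loss studies, a factorial
requirement model, maximum-likelihood intake fitting, and probability-
approach risk estimation under fortification and supplementation scenarios.

## The factorial requirement model

The daily physiological requirement of absorbed iron equals the iron lost,
which for WRA has two additive components.

**Basal loss** (skin, gut, urine) scales with body weight:
mean = 14 µg·kg⁻¹·d⁻¹ × 55 kg = 0.77 mg/d. Its variability combines the CV
of the per-kg loss (29.2%) with the CV of body weight (15.6%). The default
combination is quadrature, CV² = 0.292² + 0.156², giving SD 0.25 mg/d — the
value that reproduces the published 0.77 ± 0.25. The exact variance identity
for a product of independent variables adds a cross term
(0.292²·0.156², under 2% of the variance, SD 0.257) and is available as
`basal_loss_model(cv_method = "product")`. The component is modelled as
normal, truncated at zero when sampled; at CV ≈ 33% the truncated mass is
~0.1%, so moments are essentially unaffected (whether the original
computation truncated is unknowable and numerically irrelevant).

**Menstrual loss** is right-skewed and modelled as lognormal *per cycle*.
Published studies report either iron loss (mg/cycle) or blood loss
(mL/cycle); blood is converted via Hb concentration (135 g/L unless the
study reports otherwise) × 3.39 mg iron/g Hb. A study reporting only a range
(min, max) is read as a pair of percentiles (2.5th/97.5th by default, ranks
overridable per study), giving the closed-form quantile-matching solution
implemented in `lognormal_from_range()`. Per-study (µ, σ) are pooled by
sample-size-weighted means — of σ itself, the literal reading of
"weighted mean of the estimates"; inverse-variance-style pooling of σ² is
available via `sigma_method = "variance"`. The pooled parameters are
Lognormal(2.13, 1.04) mg/cycle: a median of exp(2.13) ≈ 8.4 mg per cycle,
i.e. ≈ 0.30 mg/d — the physiologically sensible reading, and the only one
that reproduces the downstream EAR. We record this unit interpretation
explicitly because published parameter pairs rarely state it.

**Convolution and bioavailability.** The requirement is basal + menstrual/28.
A normal-plus-lognormal sum has no closed form, so the distribution is
approximated by Monte Carlo (default 10⁶ draws, seeded). Dividing by the
dietary bioavailability (8% for a cereal-dominated diet; the package also
pools published absorption studies, below) yields the *dietary* requirement.
A lognormal summary is fitted to the dietary draws by log-moment matching —
at 10⁶ draws the difference from quantile matching is negligible.

```{r requirement}
req <- derive_requirement(n_draws = 1e5, seed = 1)
req
ear_rda(req, 0.975)
```

**EAR/RDA extraction.** `ear_rda()` reads the median and the 95th/97.5th
percentile from the *fitted lognormal* by default. This matters in the upper
tail: the simulated distribution is the sum of a moderately skewed and a
heavily skewed variable, and its raw 97.5th percentile (~39 mg/d on the
dietary scale) is heavier than the fitted lognormal's (~35 mg/d). The fitted
reading is the default because the requirement distribution is *carried
forward* to risk estimation in fitted form, and because the canonical
results (EAR 14.4 → recommended 15; RDA 30 at the 95th, 35 at the 97.5th
percentile) are percentiles of Lognormal(2.67, 0.45). The empirical reading
remains available (`method = "empirical"`) and agrees at the median within
Monte Carlo error. Reported recommendations round the EAR *up* (a
requirement should not be understated) and the RDA to the nearest integer.

## Absorption pooling

Stable-isotope absorption studies in Indian WRA (packaged as
`read_absorption_studies()`) are pooled within (anaemia status × cereal)
strata with weights 1/SE (SE = sd/√n, inverse-SE as literally described, not
inverse-variance), then across strata with population weights. The exact
survey proportions behind the published 8.7% are not printed; the defaults —
53% anaemic (national WRA prevalence) and cereal shares 65/30/5 for
rice/wheat/millet — were fixed once and yield 8.77%. Strata with no study
(normal-status wheat and millet) have their weight renormalised over the
cereals that do have studies; with `renormalize = FALSE` this is an error.
The EAR itself uses 8%, the value in the current recommendation.

## Intake model and risk engine

Per-capita daily iron intakes per group (state) are fitted by maximum
likelihood; candidate families are lognormal and gamma (both closed-form or
Newton profile MLE), selected by AIC — intakes are right-skewed, so the
normal family must be requested explicitly. No within-/between-person
deconvolution is applied: the source intakes are 30-day household-recall
per-capita values, fitted directly. Fortification (10 mg/d) and
supplementation (14 mg/d ≈ 100 mg/wk) are deterministic location shifts —
every consumer receives the full dose — implemented exactly on the CDF
(`shift_intake()`), never by refitting.

The **probability approach** computes the population risk of inadequacy as
E[1 − F_req(X)] over the intake distribution, by Monte Carlo with the fitted
lognormal requirement CDF (empirical-CDF mode available; the two agree
within Monte Carlo error). The **EAR cut-point** method, P(X < EAR), is
provided for comparison; it is accurate when both distributions are
symmetric and intake variance dominates, conditions that fail for the skewed
iron requirement — which is why the probability approach is the default.
Risk of excess is the closed-form tail probability
P(X + doses > TUL = 45 mg/d). `scenario_table()` assembles per-group
baseline, post-fortification, and post-supplementation risks with a
cross-group median/IQR summary using linear-interpolation quantiles (with 35
groups the median is the 18th order statistic, which reproduces the
published 65% (IQR 48–78) from the printed columns; see
`state_risk_estimates()`).

```{r risk}
summarize_risk_table(state_risk_estimates())
```

## What the synthetic generators emulate

State-level intake microdata are not redistributable, so
`generate_intake_survey()` emulates their salient features: group medians
uniform on 7–21 mg/d (the reported span of state medians) and lognormal (or
moment-matched gamma) within-group spread with log-SD 0.3–0.5 — a
calibration chosen so baseline inadequacy risks span roughly 25–93%, the
published between-state range; it is a generator choice, not a survey value.
The generator does **not** emulate household size adjustment, seasonality,
measurement error, or intra-household allocation — a green end-to-end test
establishes that the *pipeline* recovers known truth, not that the synthetic
survey equals the real one.

`generate_menstrual_studies()` draws per-study losses from known lognormal
truth and reports the sample min/max as the "range". Under the default
`rank_convention = "fixed"` the emitted ranks are 2.5%/97.5% — deliberately
the same approximation applied to published ranges. This inflates the
recovered σ by ~20% at n = 40–100, because the expected extreme of n normal
deviates lies beyond ±1.96 (≈ ±2.34 at n = 65); the test suite *quantifies*
this bias rather than hiding it. With `rank_convention = "plotting"` the
generator emits the Blom plotting positions (i − 0.375)/(n + 0.25) of the
extremes, under which recovery is unbiased to within sampling noise —
parameter-recovery acceptance runs in this mode. The same caveat applies in
reverse to real published ranges: quantile-matching a min–max range with
fixed 2.5/97.5 ranks overstates σ unless the study's n is near 40.

## Numerical choices and edge cases

* All stochastic stages take an explicit integer seed, save and restore the
  caller's RNG state, and are byte-reproducible; table cells in
  `scenario_table()` use independent seeds derived deterministically from
  the master seed.
* `convolve_requirement()` refuses fewer than 10⁴ draws (percentile error),
  `fit_intake()` fewer than 30 observations, and both reject degenerate
  (zero-spread) inputs; a reported range with lower = upper is an error, not
  a σ = 0 lognormal.
* Gamma MLE uses the Newton iteration on the shape profile likelihood with
  Minka's closed-form start; it converges in a handful of iterations and has
  no optimizer failure modes on positive data.
* Risks are kept at full precision internally and rounded to integer percent
  only in written reports.

## Limitations

Pregnancy/lactation and adolescent growth requirements, helminth-related
losses, partial-coverage or compliance modelling of interventions,
bioavailability estimation from diet composition, and biomarker-based
validation are all out of scope. The requirement model treats basal and
menstrual losses as independent, uses male-derived basal loss data (no WRA
measurements exist), and inherits whatever selection bias the underlying
loss and absorption studies carry.
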