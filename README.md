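# ironear

Estimation of the dietary iron requirement distribution for non-pregnant,
non-lactating women of reproductive age (WRA), and of the population risks
of inadequate and excess iron intake under fortification and supplementation
policies.

## Who this is for

Nutrition epidemiologists and policy analysts who need a transparent,
reproducible EAR/RDA derivation and state- or group-level risk estimates —
rather than comparing median intakes to an RDA, which conflates individual
and population reference values.

## The model

The physiological requirement of absorbed iron for WRA is factorial — the
sum of independent daily losses:

* **basal loss** `B ~ Normal(14 µg·kg⁻¹·d⁻¹ × 55 kg, CV = √(0.292² + 0.156²))`
  = 0.77 ± 0.25 mg/d, truncated at 0;
* **menstrual loss** `M ~ Lognormal(µ = 2.13, σ = 1.04)` mg per 28-day
  cycle, pooled across studies by quantile-matching each study's reported
  range (`Φ((log L − µ)/σ) = p`, `Φ((log U − µ)/σ) = q`) and sample-size
  weighting.

The dietary requirement is `R = (B + M/28) / b` with bioavailability
`b = 0.08`, simulated by Monte Carlo (no closed form for a normal +
lognormal sum) and summarised as a fitted lognormal — `Lognormal(2.67,
0.45)` at the defaults. EAR = median = 14.4 mg/d (recommended value 15);
RDA = 95th or 97.5th percentile = 30 or 35 mg/d.

Population risk of inadequate intake uses the probability approach,
`100 · E[1 − F_R(X)]`, over a usual-intake distribution `X` fitted per group
by maximum likelihood (lognormal/gamma, AIC-selected); the EAR cut-point
method `100 · P(X < EAR)` is included for comparison. Fortification
(+10 mg/d) and supplementation (+14 mg/d) are exact location shifts, and the
risk of exceeding the tolerable upper level is `100 · P(X + dose > 45)`.

## Worked example

```r
library(ironear)

req <- derive_requirement(seed = 1)   # published-constant defaults, 1e6 draws
req
#> Dietary iron requirement distribution (1000000 draws, bioavailability 0.08)
#>   fitted Lognormal(2.667, 0.452); EAR 14.4 mg/d, RDA(95th) 30.3 mg/d
round(ear_rda(req, 0.975), 2)
#>   ear   rda
#> 14.40 34.89
```

The EAR of 14.4 mg/d is the median dietary intake at which half the
population meets its requirement; the 97.5th-percentile RDA of ~35 mg/d is
the intake at which an individual's risk of inadequacy is ~2.5%.

Risk estimation on a synthetic six-state survey (medians drawn from
7–21 mg/d):

```r
sv   <- generate_intake_survey(n_groups = 6, n_per_group = 2000, seed = 2)
fits <- fit_intake_groups(sv)
scenario_table(fits$fits, req, seed = 3)
#>   group_id risk_cutpoint_ref risk_inadequate_baseline ...
#> 1 group_01                99                       76
#> 2 group_02                67                       39
#> ...
#> Cross-group summary (percent):
#>                  risk_inadequate_baseline     43  32  69
#>             risk_inadequate_fortification     12   8  22
#> risk_inadequate_fortification+supplementation   1   1   3
#>     risk_excess_fortification+supplementation  26   7  42
```

Reading: in `group_01` (a low-intake state) the expected proportion of women
whose usual intake falls short of their individual requirement is 76% at
baseline; 10 mg/d of fortification cuts it to 25%, and adding
14 mg/d of supplementation to 3% — while the risk of exceeding the 45 mg/d
upper level rises in the high-intake groups (up to 47% here). The packaged
table of published per-state estimates is available as
`state_risk_estimates()`; its new-EAR baseline column summarises to a median
of 65% (IQR 48–78%).

Evidence-synthesis utilities: `lognormal_from_range()`, `blood_to_iron()`,
`estimate_menstrual_loss()` (pooling the packaged synthetic 10-study table
to exactly (2.13, 1.04)), and `pool_absorption()` (8.77% with the default
national weights).

The full pipeline with provenance (`requirement.json`, `risk.csv`,
`summary.txt`, `config.json`):

```r
run_pipeline(default_config(seed = 1), out_dir = "ironear_out")
```

or from the shell, `Rscript inst/cli/ironear.R run --seed 1 --out out/`.

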