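# apgsi

Pharmacokinetic–pharmacodynamic modelling of age-dependent amyloid-β
accumulation and γ-secretase inhibition in the Tg2576 mouse.

Tg2576 mice accumulate brain amyloid-β (Aβ40/42) with age: flat levels in
young animals, a steep rise, and a plateau past ~20 months. γ-secretase
inhibitors (GSIs) such as MRK-560 block Aβ production, yet their apparent
efficacy collapses with age, and insoluble Aβ only responds to weeks of
treatment. `apgsi` is for preclinical PKPD modellers who want to work with
the integrated model that explains all three observations, fit it to
(synthetic or their own) event-record data, and use it for study design.

## The model

* **PK** — two-compartment disposition with first-order absorption, in
  closed form, superposed over dose events. Oral bioavailability in the
  standard vehicle is dose-dependent,
  `F(D) = θ2 + (1 − θ2) / (1 + (θ1·D)^θ3)`, and brain exposure is an
  instantaneous partition of plasma, `C_br = θ4·C_p` (θ4 = 0.31).
* **Amyloid progression (AP)** — a logistic function of age per Aβ variant:
  `AP(a) = baseline + (α − baseline)·a^P/(EC_i^P + a^P)`; soluble Aβ40 runs
  47 → 6640 pg/mg (141-fold), insoluble 30 → 39,900 pg/mg (1330-fold).
* **Turnover** — soluble Aβ40 is an indirect-response pool with production
  `k_out,sol·AP(age)` (k_out,sol = 1.1 h⁻¹, a 38-min half-life) inhibited by
  the drug; insoluble Aβ40 is a slow pool (k_out,insol = 0.001 h⁻¹, ~30-day
  half-life) fed by `SCALE(t)·A_sol` with a time-logistic SCALE.
* **Drug effect** — three candidate models: absolute (A), relative (B), and
  the final model (C) in which `IC50 = A_sol / SL`: with SL = 514 the IC50
  grows from 0.11 μmol/L at the young baseline to ~12 μmol/L at 25 months,
  which is why identical exposures stop working in old animals.
* **Estimation** — naive-pooled maximum likelihood with log/logit
  transforms, explicit-gradient bounded quasi-Newton, observed-information
  standard errors, and OFV-based model comparison.
* **Synthetic data & diagnostics** — generators for cross-sectional ages
  and the 23 transcribed in-house study designs; visual predictive checks,
  unpaired-t effect summaries, and the duration-grouped soluble-vs-insoluble
  reduction regression.

## Worked example

Simulate one month of daily 6 μmol/kg oral MRK-560 in a 5-month-old versus
a 15-month-old animal and summarise the soluble suppression:

```r
library(apgsi)

dosing <- data.frame(time_h = seq(0, 24 * 27, by = 24), amount = 6,
                     route = "oral", vehicle = 1)
young <- simulate_pkpd(5,  dosing, duration_h = 24 * 30)
old   <- simulate_pkpd(15, dosing, duration_h = 24 * 30)

young
#> Integrated PKPD simulation (model C): age 0-5.99 months, 820 time points, 28 dose events
#>   terminal soluble Abeta40 33.53 pg/mg (drug-free reference 58.73), insoluble 29.1 pg/mg

average_soluble_reduction(young, age_to_hours(5)  + c(24 * 14, 24 * 28))
#> [1] 82.94055
average_soluble_reduction(old,   age_to_hours(15) + c(24 * 14, 24 * 28))
#> [1] 13.64815
```

The same regimen suppresses soluble Aβ40 by ~83% at 5 months but only ~14%
at 15 months — the age-fading efficacy that drug-effect model C encodes.
Recovering parameters from synthetic data works the same way:

```r
ds  <- generate_cross_sectional(500, c(3.5, 26),
                                ap_params(variant = "sol_ab40"),
                                noise_spec(), seed = 101)
fit <- fit_ap(ds, "sol_ab40")
fit
#> Logistic amyloid-progression fit (sol_ab40)
#>   n = 500 observations, OFV = 6915.46, converged
#>   alpha          5925. (SE 468.)
#>   ec_i           19.62 (SE 0.531)
#>   p              6.308 (SE 0.228)
#>   baseline       41.20 (SE 2.31)
#>   sd             0.4682 (SE 0.0163)
```

The generating plateau (6640 pg/mg) is recovered within about 11% at this
sample size and 51% residual CV, with the truth inside ±2 SE.

See `vignettes/amyloid-pkpd-methods.Rmd` for the full model description,
numerical choices and limitations.

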