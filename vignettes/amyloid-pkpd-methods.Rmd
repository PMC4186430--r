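---
title: "Modelling age-dependent amyloid accumulation and gamma-secretase inhibition in Tg2576 mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling age-dependent amyloid accumulation and gamma-secretase inhibition in Tg2576 mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(apgsi)
```

## The problem

Tg2576 mice overexpress human APP with the Swedish mutation and accumulate
amyloid-beta (Abeta) in the brain with age: after a flat phase in young
animals, soluble and insoluble Abeta40/42 rise steeply and plateau past
roughly 20 months.  A gamma-secretase inhibitor (GSI) such as MRK-560 blocks
Abeta production, but its apparent efficacy fades with age: single doses
that suppress soluble Abeta40 by ~70% in 5-month-old animals do nothing
measurable in 18-month-old animals, and insoluble Abeta40 only responds to
multi-week treatment.  `apgsi` implements an integrated
pharmacokinetic-pharmacodynamic (PKPD) model that reproduces these three
observations quantitatively, together with the estimation, simulation and
diagnostic machinery needed to work with it.

## Model components

### Pharmacokinetics

Plasma MRK-560 follows a two-compartment disposition model with first-order
absorption, evaluated in closed form and superposed over dose events
(`plasma_concentration()`).  Parameters (`pk_params()`) default to the
reported estimates: `ka` 0.41/h oral and 0.81/h subcutaneous, `CL` 0.12
L/h/kg, `V2` 0.28 L/kg, `Q` 7.6 L/h/kg, `V3` 2.9 L/kg.  Oral
bioavailability in the standard vehicle is dose-dependent,

\[
F(D) \;=\; \theta_2 + \frac{1-\theta_2}{1+(\theta_1 D)^{\theta_3}},
\]

which runs from 1 at vanishing dose to the high-dose asymptote
\(\theta_2 = 0.22\), with study-specific \(\theta_1 \in [10^{-4}, 0.2]\)
(default 0.01; overridable per study) and shape \(\theta_3 = 0.5\).  The
cyclodextrin vehicles and the subcutaneous route use fixed fractions (1,
0.7, 0.8).  Brain exposure assumes instantaneous equilibration of unbound
drug, so total brain concentration is a fixed multiple of plasma
concentration, \(C_{br} = \theta_4 C_p\) with \(\theta_4 = 0.31\)
(`brain_concentration()`); measured brain concentrations can be corrected
for the 1.3% residual blood volume (`blood_contamination_correct()`).

### Amyloid progression

Drug-free Abeta levels follow a logistic (Hill) function of age in months
(`ap_level()`):

\[
AP(a) \;=\; \mathrm{baseline} + (\alpha - \mathrm{baseline})
\frac{a^{P}}{EC_i^{P} + a^{P}} .
\]

`ap_params()` carries the fitted values per variant, e.g. soluble Abeta40
rising from 48 to 6640 pg/mg with inflection at 20 months, insoluble Abeta40
from 29 to 39,900 pg/mg with inflection at 17 months — 141- and 1330-fold
increases over the observed young-age levels.  The baseline term is additive:
the reported fold changes identify \(\alpha\) itself as the plateau, and a
purely multiplicative logistic could not hold the flat young-age phase.

### Integrated turnover model

Soluble Abeta40 is a turnover (indirect-response) pool whose production is
driven by the progression curve and inhibited by the drug:

\[
\frac{dA_{sol}}{dt} = k_{out,sol}\, AP(a(t))\,\bigl(1 - I(C_{br}, A_{sol})\bigr)
 - k_{out,sol}\, A_{sol},
\]

with \(k_{out,sol}\) fixed at 1.1/h (38-min half-life, a literature value —
the rate is not identifiable from terminal sampling).  Tying production to
\(k_{out,sol} \times AP\) makes the drug-free steady state equal the
progression curve exactly, which is why no separate production constant is
estimated.  Three drug-effect models are available (`pd_params()`):

* **A (absolute)**: production is reduced by an absolute rate
  \(E_{abs} C/(IC_{50}+C)\) pg/mg/h, clamped so production stays
  non-negative;
* **B (relative)**: fractional inhibition \(I_{max} C/(IC_{50}+C)\) with a
  fixed IC50;
* **C (relative, Abeta-dependent IC50)**: as B but with
  \(IC_{50} = A_{sol}/SL\) (`ic50_of_level()`).

Model C is the final model: with \(I_{max} = 0.86\) and \(SL = 514\) the
IC50 is 0.11 umol/L at the young baseline (57.1 pg/mg) and about 12 umol/L
at the 25-month soluble level, which is what makes the same exposure
effective in the young and ineffective in the old.  The orientation of the
slope (`IC50 = a_sol / SL`, not `SL * a_sol`) is the only one that
reproduces both printed anchors.

Insoluble Abeta40 is a second, much slower turnover pool fed by the soluble
pool through a time-dependent logistic scaling (`scale_function()`):

\[
\frac{dA_{insol}}{dt} = k_{out,insol}\bigl(\mathrm{baseline}_{insol} +
 \mathrm{SCALE}(t)\, A_{sol}\bigr) - k_{out,insol} A_{insol},
\qquad
\mathrm{SCALE}(t) = \alpha_2 \frac{t^{P_2}}{EC_{i2}^{P_2} + t^{P_2}},
\]

with \(k_{out,insol} = 0.001\)/h (a ~30-day half-life) and
\(\alpha_2 = 6.5\), \(EC_{i2} = 7610\) h, \(P_2 = 9.1\).  SCALE's argument
is time since birth in hours: the reported \(EC_{i2}\) carries hour units,
and 7610 h is ~10.4 months under this package's fixed convention of 730.5
h/month.  The alternative reading (SCALE as a function of the soluble level
itself) is structurally possible but incompatible with those units, and is
not implemented.  A consistency check supports the reconstruction: the
implied insoluble plateau \(\alpha_2 \times 6620 = 43{,}030\) pg/mg agrees
with the independently fitted 39,900 pg/mg within 8%.  The insoluble
baseline sits inside the production term so that young-age levels
(28.9 pg/mg) are maintained before SCALE switches on.

Inhibition is driven by **total** brain concentration by default,
consistent with the umol/L-scale IC50 anchors; `pd_params(drive_unbound =
TRUE)` switches to unbound brain concentration.

### Simulation

`simulate_pkpd()` integrates the two-state system from birth (initial
conditions at the young-age baselines) so the progression term is a
function of absolute age; study dosing is shifted by the age at study
start.  The right-hand side is compiled C behind `deSolve::lsoda`, with the
drug input computed in closed form inside the derivative, and integration
restarts at every dose instant so the stepper never straddles a forcing
discontinuity.  Default tolerances are `rtol = 1e-8`, `atol = 1e-10` pg/mg.
A pure-R right-hand side (`pkpd_rhs()`) plus any `deSolve` method is
available via `compiled = FALSE`; the test suite uses it as an independent
integration oracle (agreement within 0.5%, typically 1e-6).

```{r sim-example}
dosing <- data.frame(time_h = seq(0, 24 * 27, by = 24), amount = 6,
                     route = "oral", vehicle = 1)
sim <- simulate_pkpd(5, dosing, duration_h = 24 * 30)
sim
plot(sim)
```

## Estimation

All fitting is naive-pooled maximum likelihood (`fit_ap()`, `fit_pkpd()`).
Terminal Abeta sampling is destructive — one animal, one observation — so
between-subject and residual variability are confounded at the
pharmacodynamic level and subject-level random effects are not estimable
from these data; pooling recovers the fixed effects, which is all the
downstream science uses.  Between-subject PK variability is still available
in the *simulation* direction (`noise_spec()`), reflecting the reported
log-normal spreads on `V2` (179%), `V3` (50%) and the brain:plasma ratio
(61%).

Residual error is proportional by default, realised as a mean-parameterised
log-normal: the mean (not the median) of the distribution equals the model
prediction and its coefficient of variation equals the error SD.  The same
parameterisation is used by the synthetic-data generator, so recovery stays
unbiased even at the 83% CV reported for insoluble Abeta40.  Additive and
additive-on-log-scale kinds are also available (the source analysis reports
"additive" error but quotes it in percent; proportional is the reading that
matches the reported 51%/83% values).

Positive parameters are log-transformed and `Imax` logit-transformed during
optimisation (bounded quasi-Newton, `stats::nlminb`).  Two numerical
choices matter on an ODE-based objective:

* gradients are explicit central differences with step 1e-4 on the
  transformed scale — solver-noise at the integration tolerance makes the
  optimizer's internal square-root-of-machine-epsilon differences useless;
* during fitting the integrator runs at `rtol = 1e-6` and restarts only at
  the first dose, capping the step length over the dosing span instead of
  restarting at all later doses (the oral input is continuous there, with
  derivative kinks only); this is ~5x faster and agrees with the strict
  scheme to ~1e-6.  Because that tolerance puts a noise floor under the
  objective, the function-reduction tolerance defaults to 1e-5 and a
  "false convergence" report from `nlminb` is accepted as converged only
  when the objective had already stagnated (< 0.1 improvement on the -2logL
  scale over the final quarter of evaluations).

`fit_ap()` uses 10 jittered starting points (log-uniform within a factor
10); the integrated `fit_pkpd()` defaults to a single start from the
supplied initial values because one 13-parameter fit costs tens of seconds
— `n_start` raises it when the extra robustness is wanted.  Standard errors
come from the numerically differentiated observed information at the
optimum, delta-method-mapped to the natural scale; parameters at a bound or
with log-scale SEs above 2 are flagged as possibly non-identifiable (this
is how a plateau fitted to young-only data announces itself).
`compare_models()` ranks fits of different drug-effect structures on the
same data by objective-function value (-2 logL).

## Synthetic data

`generate_cross_sectional()` emulates the drug-free cross-sectional design
(one terminal observation per animal, ages uniform over 3.5-26 months
unless given explicitly).  `generate_study()` realises one study design —
ages from the stated start range, once-daily dosing, terminal cohorts per
sampling time — through the full PK and turnover model;
`table1_designs()` ships the 23 transcribed in-house MRK-560 designs.
`generate_benchmark_dataset()` bundles the scaled-down recovery setting
used by the package's own validation: six studies spanning young (~5.5-6
months) and old (~14-20 months) animals plus a 150-animal drug-free
cross-section, at the reported residual CVs with between-subject PK
variability off (the fixed-effect recovery target).  All generators are
deterministic given a seed (R's default Mersenne-Twister).

What the generator deliberately does **not** emulate: litter/cage and assay
plate structure, body weight, sex (all animals in the source studies were
female), LLOQ censoring beyond a threshold flag, and inter-laboratory
differences in absolute Abeta scale.  Green recovery tests therefore show
that the estimation machinery is correct under the model's own assumptions
— they do not certify the model against real-world assay artefacts.

## Diagnostics

`vpc()` simulates replicate datasets under the observed design (the source
analyses used 1000 replicates) and overlays 5th/50th/95th percentile bands,
binned by termination age for Abeta endpoints and by sampling time for
concentrations.  `effect_summary()` is the vehicle-versus-treated unpaired
t-test (equal-variance Student by default — the era-typical Prism setting —
with Welch available), reporting means ± SEM, percent change, and
significance at 0.05 with no multiplicity correction.
`soluble_insoluble_regression()` fits the duration-grouped regression of
observed insoluble reduction on model-predicted average soluble reduction
(`average_soluble_reduction()`); the intercept is left free, since forcing
it through the origin is an extra assumption the data do not require.

## Problem sizes and known limitations

The bundled validation runs at desk scale by design: recovery experiments
use 500 cross-sectional animals or the six-study benchmark (~440 animals)
over 20 seeds, VPCs use a few hundred replicates, and the repeated-seed
integrated fits cap the quasi-Newton at 70 iterations — the objective has
stagnated well before that, so the cap trims only polishing steps.  These sizes give
parameter-recovery spreads comfortably inside twice the reported standard
errors; larger designs only sharpen them.

Known limitations: the exact algebraic forms of the source model equations
are reconstructed from their surrounding description and parameter tables
(the printed equations are not machine-readable), validated against every
printed numerical anchor; study-specific bioavailability values
(\(\theta_1\)) are published only as a range, so absolute effect sizes of
individual historical studies are not reproducible targets; models A and B
ship with configurable rather than published parameters (their final
estimates were published only in supplementary material not available
here); and Abeta42 has progression parameters but no drug-effect model, as
no drug-effect data existed for it.
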