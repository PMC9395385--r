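---
title: "Multifactor assessment of supercritical CO2 extraction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifactor assessment of supercritical CO2 extraction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfeperf)
```

`sfeperf` scores candidate operating conditions of a supercritical CO2
extraction (pressure $P$, temperature $T$, water content in ethanol
$\omega$) on extraction performance, operational cost and chemical
safety, and combines the three into a rank-based overall index. This
vignette documents the underlying models, every tunable that matters,
the numerical choices, and the limits of what the shipped tests
demonstrate.

## The design and its coding

The experimental layer is a three-factor central composite design:
$2^3$ factorial corners at coded $\pm 1$, six axial points, and
replicated centre points. Coding is the standard
$(x_\text{actual} - \text{centre})/\text{step}$ with the step equal to
the factorial half-range (3 MPa, 5 °C, 10 % v/v for the case study).

Axial levels are stored **verbatim** in each `factor_spec` rather than
derived from a single axial distance $\alpha$. In the packaged case
study the printed axial levels imply coded distances of 1.33 (pressure),
1.40 (temperature) and 1.30 (water) — there is no single $\alpha$
consistent with all three, so recomputing levels from one would change
the design matrix and every downstream statistic. `ccd_design()` warns
when the axial distances are unequal (the design is then not rotatable)
but builds the design exactly as specified. `ccd_design()` emits runs in
factorial–axial–centre order; the packaged case-study table keeps its
original run order.

## Response-surface models

`rsm_fit()` fits, by ordinary least squares on the coded factors, one of
three nested polynomials: `linear` (A, B, C), `2FI` (plus AB, AC, BC) or
`quadratic` (plus A², B², C²). Coded-scale fitting is deliberate:
coefficients are then in response units per coding step and comparable
across factors, matching the convention of the common DOE packages. The
intercept is fitted and reported but is not a comparison target.

Diagnostics follow standard response-surface practice:

* $R^2$, adjusted $R^2$ with the usual df correction;
* PRESS from leave-one-out residuals $e_i/(1-h_{ii})$ and predicted
  $R^2 = 1 - \mathrm{PRESS}/SS_\text{tot}$;
* per-term partial $t$ tests (identical to Type III partial $F$ tests
  for these single-df terms), significance declared at $p < 0.05$;
* lack of fit: the residual SS is split into pure error (within groups
  of replicated design points — the six centre runs give 5 pure-error
  df in the case study) and lack-of-fit; when there are no replicates,
  or the model saturates the distinct points, the test is reported as
  *unavailable with a reason*, never as a silent `NaN`.

Degenerate inputs are handled explicitly: a constant response flags the
$R^2$ family as undefined (with a warning) rather than dividing by a
zero $SS_\text{tot}$; a rank-deficient model matrix raises an error
naming the collinear columns.

`predict()` codes incoming points and evaluates the polynomial; points
outside the coded box spanned by the axial levels trigger a warning (the
polynomial extrapolates there) but still return a value, since nearby
out-of-box evaluations are routine in practice.

### Optimization

`rsm_optimize()` maximizes the fitted surface over the coded axial box
by multi-start L-BFGS-B from a deterministic $4^3$ grid of starts, plus
the analytic stationary point of the quadratic form when it is interior.
Convergence is effectively to machine precision (`factr = 10`); ties
within $10^{-8}$ are broken by the first-found start, making results
reproducible. Models without curvature (linear, 2FI) attain their
optimum on the box boundary, which the bounded search handles naturally.
A note on the case study: the maximum of the fitted solubility quadratic
over the design box does **not** coincide with the single optimum point
quoted in the original study; the package therefore exposes per-response
optimization and, for comparisons, evaluates the model at explicitly
supplied conditions.

## Synthetic responses

`synth_response()` evaluates a user-specified coded-scale polynomial at
the design points and adds i.i.d. Gaussian noise. It emulates exactly
the data-generating process the RSM layer assumes — a low-order
polynomial plus homoscedastic noise — which is what makes it the right
instrument for parameter-recovery tests (zero-noise round trips to
$10^{-9}$; coefficient RMSE shrinking monotonically over noise SD
$\{0.5, 0.1, 0.01\}$ with 50 seeds each) and for null-calibration tests
(pure-noise responses reject terms at about the nominal 5 %). It does
*not* emulate real extraction data: no heteroscedasticity, no run-order
drift, no curvature beyond the quadratic, no measurement floor. Passing
recovery tests therefore validates the estimator, not the adequacy of a
quadratic for any particular herb. The default `noise_sd = 1.0` is the
pooled SD of the six replicated centre-point yields in the case-study
table (4.9–7.5 g/g %, SD 0.98), so default simulations are about as
noisy as the real replicates. Seeding is scoped: the generator restores
the global RNG state, and a given seed always reproduces the same table.

## Operational cost

The cost model is the variable-cost line
$OC = 2.73\,COL + 1.23\,(CUT + CRM)$ in RM/year. The source tables give
prices (herb 70 RM/kg; ethanol 86 RM per 2.5 L; CO2 224 RM per 30 kg
cylinder; labour 1800 RM/month) but no consumption or duty figures, so
the following are package defaults, chosen once as a realistic lab-scale
duty cycle and documented here rather than tuned:

| field | default | rationale |
|---|---|---|
| `runs_per_year` | 240 | one run per working day, 240 days |
| `annual_hours` | 1920 | process equipment on 8 h/day |
| `equipment_hours["chiller"]` | 5760 | the chiller holds CO2 liquid around the clock on operating days |
| `sample_mass` | 0.003 kg | the 3 g vessel charge of the case study |
| `co2_mass` | 1.0 kg | consistent with gram-per-gram solubilities at ~0.1 g extract per run |
| `cosolvent_volume` | 0.10 L | co-solvent at a few percent of solvent flow |

The electricity tariff is 0.365 RM/kWh (the Malaysian grid tariff;
configs may declare `tariff_unit: sen/kWh`, converted by /100 on load
with a message). Under these defaults utilities are the largest cost
component, led by the 13.82 kW chiller — the qualitative ordering the
tests assert. The exact percentage split depends on the duty-cycle
assumptions above and is intentionally **not** asserted anywhere.

Across operating conditions, only the water fraction changes the bill
(water displaces priced ethanol in the fixed co-solvent volume); the
default model takes per-run energy as independent of $P$ and $T$ because
no per-condition energy data exist for the unit. Waste treatment and all
fixed capital are out of scope.

## Chemical safety

Mixture properties of the ethanol–water co-solvent:

* boiling point and Hansen parameter: mole-fraction-linear mixing;
* volume to mole fractions via 20 °C handbook densities and molar
  masses (the density table shipped for 65 °C / 17–25 MPa is reference
  data; the conversion temperature is configurable through the solvent
  YAML);
* flash point: the Le Chatelier condition
  $\sum_i x_i \gamma_i P_{i,\mathrm{sat}}(T) / P_{i,\mathrm{sat\,FP}} = 1$
  over flammable components only (water contributes zero), solved by
  bracketed root finding (`uniroot`, default bracket −50…150 °C,
  tolerance $10^{-6}$ °C, with an explicit error when the bracket holds
  no root). Vapour pressures are Antoine (mmHg/°C convention fixed in
  the config schema so the ratio is dimensionless). Activity
  coefficients default to the van Laar model with standard
  ethanol(1)–water(2) constants $A_{12}=1.6798$, $A_{21}=0.9227$ —
  ethanol–water is strongly non-ideal, and ideal $\gamma=1$ is available
  as `activity_model = "ideal"` for transparency. The solver is tested
  against an independent 0.01 °C brute-force scan to ≤ 0.02 °C.

The four logistic hazard scores map onto $[0,100]$: flammability
(decreasing in flash point, °C), toxicity (decreasing in TLV–STEL, ppm),
reactivity (increasing in the NFPA rating 0–4) and explosiveness
(increasing in UEL−LEL, vol %); their sum is the CSTS. Argument units
are fixed in the schema to prevent silent drift.

**Composition policy.** Water has no TLV–STEL, no NFPA-flammability
relevance and no explosive range, so toxicity, reactivity and
explosiveness are scored on the flammable component's parameters,
composition-independent; only flammability varies with the blend,
through the mixture flash point. This reproduces the observed pattern
that CSTS differences across water ratios are driven by flammability
alone, and it makes CSTS strictly decreasing in water content (the
driest blend is the most hazardous). A `flash_point_method =
"pure_cosolvent"` switch scores flammability on the neat co-solvent
instead, for sensitivity analysis. CO2's asphyxiant hazard and the
BLEVE/overpressure scenarios are carried as a static qualitative
register (`hazard_tables()`), not scored: the logistic scheme covers the
co-solvent chemistry only.

## The overall index

Neither the rank scale nor its orientation is standardized, so the
package fixes them as: ranks $1\ldots n$ with $n$ = best; solubility
oriented higher-is-better, cost and CSTS lower-is-better (the stated aim
being the highest solubility at the lowest cost in the safest
environment); ties share the mean of their positions; the three indices
are summed unweighted. An alternative min–max normalized (0–1) scoring
sits behind `scale = "normalized"` for sensitivity checks — it is a
different weighting and can pick a different winner, so no published
claim is attached to it.

Replicated centre points are one *condition*, so `assess_conditions()`
collapses them to a single record with their mean solubility by default
(15 conditions in the case study); `group_centers = FALSE` ranks all 20
rows instead. Both modes select the same winning condition on the
packaged data, so the published best condition does not hinge on this
choice. Measured solubilities are ranked by default; passing a fitted
model ranks predictions instead (`fit =` argument), since the source is
silent on which was used. The winner's tie-break (higher solubility
index, then lower cost) is deterministic.

## Problem sizes and runtime

The test-suite simulations are sized to be decisive yet quick: 50 seeds
per noise level for recovery, 100 replicates for null calibration and
for rank-invariance properties, 200 draws for the noise-SD check, a
$51^3$ grid as the optimizer oracle, and 0.01 °C scans for the flash
point oracle. The full suite runs in under a minute on one core.

## Known limitations

* Only $k=3$ CCDs: no fractional factorials, Box–Behnken, blocking or
  randomized run order.
* No multi-response (desirability) optimization; responses are
  optimized separately.
* The cost model is variable-cost only, linear, and condition-dependent
  only through the water fraction; no scale-up economics.
* Safety scoring covers the binary co-solvent; no consequence modelling
  (overpressure, dispersion), and the van Laar constants are
  temperature-independent.
* Rank indices discard magnitude information by construction: a
  condition barely better on two cheap criteria can outrank one vastly
  better on the third. That is inherent to the method, not a defect of
  the implementation — inspect `performance_table$table` when the
  margins matter.
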