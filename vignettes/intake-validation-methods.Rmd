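---
title: "Methods: predicting and validating beef-cow dry matter intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting and validating beef-cow dry matter intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowintake)
```

## Scope and units

`cowintake` works at the level of the *treatment mean* — the per-diet,
per-group average from a confinement feeding trial — not the individual
animal or the repeated daily measurement. Units are fixed throughout: kg
for weights, kg/d for intake and milk yield, Mcal/kg DM for diet net
energy for maintenance (NEm). Live body weight entering through CSV files
is converted to shrunk body weight by the standard 4% shrink
(`SBW = BW × 0.96`); metabolic body weight is `SBW^0.75`. Production
stage is carried categorically and mapped to a 0/1 indicator
(nonlactating/lactating) only inside model formulas, so data files never
contain magic numbers.

## The prediction equations

Eight closed-form equations are implemented (see `intake_equation()`).
Three points deserve explanation:

* **Equations C and F scale with full SBW, not SBW^0.75.** That is how
  these tabular-guideline regressions were defined, and the package
  reproduces them verbatim rather than "correcting" the scaling.
* **The two pooled-stage models share one structure.** The NEMI model
  predicts daily NEm intake per unit metabolic weight
  (`NEMI = 0.224·NEm + 0.0346·STAGE − 0.142`, Mcal/kg^0.75/d) and
  converts to feed intake as `DMI = NEMI·SBW^0.75/NEm`; the direct model
  predicts kg/d in one step
  (`DMI = 3.27·STAGE + 9.21·NEm + 0.133·SBW^0.75 − 14.38`). Because the
  lactation effect is an intercept shift, the lactating-minus-nonlactating
  difference of the direct model is exactly 3.27 kg/d for every cow — a
  21% increase for the 545-kg reference cow on a 1.3 Mcal/kg diet.
* **NEMI units.** The NEMI coefficients are on a Mcal scale
  (0.224·1.3 − 0.142 ≈ 0.15 Mcal/kg^0.75/d ≈ 150 kcal); the package uses
  Mcal throughout, which is the only choice dimensionally consistent with
  the `NEMI·SBW^0.75/NEm` conversion to kg/d. At NEm = 0.9 Mcal/kg the
  converted intake for a 545-kg nonlactating cow is 1.37% of SBW by exact
  arithmetic; a published rounding of the same quantity gives 1.35%, and
  the acceptance check therefore uses a ±0.05 percentage-point band.

Diet NEm outside the validity window (default 0.7–2.1 Mcal/kg) produces a
warning rather than an error, because the response-curve use case
legitimately extrapolates the quadratic equations beyond the data range;
only NEm ≤ 0 is an error.

## Validation statistics

`unity_regression()` fits observed intake on predicted intake by OLS and
tests the line against y = x. Both marginal t-tests (a = 0, b = 1) and
the joint 2-df F-test are computed, because the underlying workflow's
"F-test" could be read either way; the marginal tests are the reporting
default. Two error scales are kept deliberately distinct:

* **RMSD** (`rmsd()`) uses denominator *n*: it is the average distance of
  observations from the unity line, a population-style prediction error.
* **Sy.x / RMSE** uses denominator *n − 2* (two estimated parameters): it
  is the scatter about the *fitted* line.

RMSD ≥ RMSE always, with equality exactly when the fitted line is the
unity line — this identity is enforced by tests, as is the exact
additivity of the Theil partition: SSPE decomposes into
`n(ȳ − x̄)² + (b − 1)²Σ(x − x̄)² + residual SS` with cross-terms vanishing
by OLS orthogonality. The percentages are kept at full precision
internally and rounded only for display. When SSPE = 0 the partition is
undefined; `theil_decomposition()` signals this with a `perfect` flag and
`NA` percentages rather than an error, so that `evaluate_equation()` can
still report the (perfect) regression statistics.

## Outlier screening

`flag_outliers()` regresses observed DMI on diet NEm, SBW^0.75 and the
stage indicator (main effects only) and flags |studentized residual| > 3.
Externally studentized (leave-one-out) residuals are the default — the
convention of the SAS-style workflow this mirrors — with internal
studentization as an option. Screening is a single pass: the report never
re-screens after removal, since iterated outlier rules change the test's
meaning. A `by_stage` option screens within stage (dropping the stage
term); the pooled model is the default because the stage indicator keeps
both stages on one plane while doubling the residual degrees of freedom.

## Refitting the pooled-stage models

`fit_nemi_model()` and `fit_dmi_model()` implement backward pruning over
the candidate terms (NEmxSTAGE for the NEMI model; NEmxSTAGE and
SBW^0.75xSTAGE for the direct model; NEm² for both): interactions leave
first, highest p-value first, then the quadratic, refitting after each
drop at p > 0.05. Main effects are never dropped. One further guard
converts a visual judgment into a testable rule: if a retained quadratic
makes the implied intake-versus-NEm curve non-monotone (decreasing
anywhere) over the observed NEm range — the "illogical concave curve"
pattern — the model is flagged overparameterized and the linear form is
reported. Monotonicity is checked on a 101-point grid at the mean
metabolic weight for each stage present, with a 1e-10 slack for floating
point.

Fits are unweighted OLS on treatment means. Whether means should be
weighted by animals-per-mean is genuinely open; unweighted is the default
because the mean counts are usually unavailable, and a weights option was
deliberately left out rather than half-supported. Milk yield is never a
candidate predictor: its measurement protocol (machine milking versus
weigh-suckle-weigh) and timing vary too much across trials for a pooled
coefficient to be meaningful; the lactation effect is carried entirely by
STAGE.

`milk_response_summary()` spreads the fitted stage adjustment over mean
milk yield (3.27/6.56 ≈ 0.50 kg DMI per kg milk at the overall mean;
3.27/7.3 ≈ 0.45 at the machine-measured mean), and
`lactation_energy_budget()` compares the energy cost of lactation
(milk × 0.72 Mcal/kg + 2.2 Mcal/d maintenance increment) with the energy
the intake response delivers (3.27 × diet NEm). The defaults 0.72 and 2.2
are the standard milk-energy concentration and the 20% lactation
maintenance increase for a typical cow; both are arguments, not
constants. The budget returns exact values; at diet NEm = 1.3 the balance
is negative (−2.67 Mcal/d exact; −2.6 from the 1-decimal rounded terms),
meaning a moderate-energy diet cannot cover lactation through the intake
response alone.

## Path analysis

The path model treats diet NEm and STAGE as exogenous and SBW^0.75 and
DMI as endogenous, in a recursive, just-identified structure. For such a
model the structural solution coincides with sequential standardized OLS
— `SBW^0.75 ~ NEm + STAGE` then `DMI ~ NEm + STAGE + SBW^0.75` on
z-scored variables — so no structural-equation machinery is needed; the
tests verify the coincidence against a correlation-algebra oracle to
1e-8. The binary STAGE is standardized by its sample standard deviation,
the convention consistent with covariance-matrix fits. Indirect effects
are exact products of the constituent paths and total effects exact sums;
significance (t-tests, stars at 0.001 and 0.05) is reported for direct
paths only, since the delta-method error of a product was not part of the
reference output being mirrored.

## The synthetic generator

`simulate_cow_data()` draws per-stage SBW, NEm, BCS and (lactating) milk
yield from truncated normal distributions whose default mean/sd/min/max
are the documented summary structure of the evaluation dataset (53
nonlactating means: SBW 589 ± 76.7 on [420, 730], NEm 1.25 ± 0.16 on
[0.93, 1.54]; 32 lactating means: SBW 510 ± 69.3 on [404, 692], NEm
1.21 ± 0.15 on [0.99, 1.49], milk 6.56 ± 2.3 on [3.0, 11.3]). Intake is
the configured generating model (the pooled-stage direct model by
default) plus Gaussian noise, default sd 1.31 kg/d — the residual scale
of that model. Sampling is by rejection, which is exact and cheap at
these mild truncations (bounds sit 1.5–2.5 sd from the means). A
summary-statistics discrepancy exists between two published descriptions
of the nonlactating data (DMI 13.2 ± 2.9 / SBW 578 ± 83.9 versus
12.9 ± 2.90 / 589 ± 76.7); the tabulated per-stage values are used as
canonical defaults.

Variables are drawn independently by default because only marginal
summaries are documented — no covariances. An explicit
`sbw_nem_correlation` knob (latent Gaussian correlation, pairs rejected
jointly against both truncation boxes) lets simulations reproduce the
observed tendency of cows on energy-dense diets to be heavier, which is
what gives the path analysis its indirect effect; the sign tests use 0.3.

What the generator does *not* emulate: within-study correlation and
study-level random effects, animal-level variation inside a mean,
non-Gaussian intake errors, BCS or days-pregnant effects on intake, and
any SBW–milk or NEm–milk dependence. Passing tests on synthetic data
therefore demonstrate that the machinery is correct and that the
qualitative validation patterns (under/overprediction directions, path
signs) follow from the model structure — not that the equations are
accurate on real cows.

## Numerical and design choices

* CSV I/O writes doubles with 17 significant digits so a written table
  reads back bit-equal; empty cells are the only missing-value code, and
  unparseable cells are row-indexed errors, never silent `NA`s.
* Degenerate validation inputs fail loudly: constant predictors, n < 3,
  length mismatches. Perfect prediction is a flagged state, not an error.
* In pruning, an inestimable or exactly-interpolated term (p = `NA` under
  zero residual variance) is treated as droppable (p = 1).
* `prune = FALSE` in the fitting functions keeps the full candidate
  model. The simulation study of estimator quality in the test suite uses
  it: unbiasedness and 95% CI coverage are properties of the *unselected*
  OLS estimator, and conditioning on data-driven pruning would mix
  post-selection distortion into what is being measured. Pruning behavior
  is assessed separately, as the rate (about the 5% test size) at which a
  true-zero interaction survives.
* Simulation sizes in the tests: parameter recovery uses 200 replicates
  of n = 500 per model; moment-fidelity checks use n = 10,000 per stage;
  oracle comparisons use 5–10-point instances at 1e-8. These sizes make
  Monte-Carlo error small relative to every asserted band while keeping
  the default suite fast.

## Known limitations

The refit machinery reproduces the *procedure* of the original pooled
analysis; the original 85 real treatment means are not distributed, so
the published fit statistics for them cannot be recomputed here, only the
structure of the analysis exercised on synthetic analogues. The
equations' validity window is the documented data range (roughly NEm
0.93–1.54 Mcal/kg); the quadratic equations in particular are unreliable
extrapolated beyond about 1.6 Mcal/kg, where they bend downward by
construction. Body condition score is carried and validated as data but
never used as a predictor, matching the printed formulas.
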