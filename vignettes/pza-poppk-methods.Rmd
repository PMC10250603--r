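---
title: "Methods: population pharmacokinetic modelling of pyrazinamide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetic modelling of pyrazinamide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pzapk)
```

## The model and its assumptions

`pzapk` models steady-state plasma concentrations of pyrazinamide under
once-daily oral dosing with a one-compartment, first-order
absorption-elimination structure. All patients are assumed to be at
steady state (non-steady-state patients are an exclusion criterion in the
TDM setting this package targets), so the closed-form repeated-dose
superposition solution applies and pre-dose samples are troughs,
identical to `t = tau` by periodicity. Because dosing is oral, only
apparent parameters (CL/F, Vd/F) are identifiable; bioavailability is
absorbed into them.

Individual parameters are log-normal around covariate-adjusted typical
values:

* fixed allometric scaling on lean body weight with exponents 0.75
  (clearance) and 1 (volume), referenced to 48 kg — the exponents are
  structural constants and are never estimated;
* one estimated categorical covariate: a fractional clearance shift for
  patients aged >= 70 years with diabetes mellitus (geriatric DM). The
  cutoff is configurable (`age_cutoff`); 70 is the default because the
  inclusive ">= 70" reading is the one consistent with the subgroup
  definitions used downstream;
* diagonal interindividual variability (IIV): `eta ~ N(0, diag(omega^2))`
  on the log scale for CL, V and Ka, with the volume IIV conventionally
  held fixed during estimation to stabilise an otherwise
  weakly-identified variance under sparse sampling;
* additive residual error with SD `sigma` on the concentration scale.
  Only the additive model is implemented: it is the error structure of
  the final model, and the proportional/combined alternatives were
  examined and rejected during that model's development.

The IIV magnitudes in published parameter tables are frequently printed
without an explicit scale. `pza_model()` therefore accepts `omega` as
percent CV (default, converted by `omega^2 = log(1 + (cv/100)^2)`), as an
SD, or as a variance (`omega_scale`). The default values (1% CV on CL, 3%
fixed on V, 100% CV on Ka) read the printed entries as %CV; under this
reading nearly all between-subject variability in elimination is absorbed
by the additive residual, which is consistent with the large residual SD
(3.41 ug/mL) relative to typical concentrations of ~30 ug/mL.

## Estimation: FOCE with interaction

The marginal likelihood has no closed form. The engine uses first-order
conditional estimation: for each subject the penalised least-squares
inner problem

    min_eta  sum_j (y_j - f_j(eta))^2 / sigma^2  +  eta' Omega^-1 eta

is solved by Gauss-Newton with backtracking line search (convergence at
gradient norm < 1e-6, or when the quadratic model predicts an objective
decrease below 1e-6 — the gradient alone is badly scaled when a variance
is nearly zero). The subject's contribution to the objective is then the
linearised marginal form

    OFV_i = log|V_i| + r_i' V_i^-1 r_i,
    V_i = G_i Omega G_i' + sigma^2 I,   r_i = y_i - f_i(eta_hat) + G_i eta_hat,

with `G_i` the sensitivity of the predictions to `eta` at the conditional
mode. With interaction, the residual covariance is evaluated at the
conditional (not population) prediction; under the purely additive error
model that term is constant, so the interaction correction is identically
zero and FOCE-I coincides with FOCE. All `2*pi` constants are dropped, so
only OFV differences are meaningful; the quadrature oracle used in the
test suite applies the same convention. Random effects whose omega falls
below 1e-5 are treated as structurally absent, which makes the pooled
(no-IIV) likelihood an exact special case.

The outer problem optimises log-transformed typical values, IIV log-SDs
and log-sigma with `nlminb` (box bounds keep omega in [1e-3, 5] and sigma
in [1e-3, 200]). Categorical covariate coefficients are estimated as
`phi = log(1 + effect)` so that every covariate enters log-linearly and
the individual-parameter map stays positive by construction; reported
effects are back-transformed with delta-method standard errors. Standard
errors come from the central-difference Hessian of the OFV
(`vcov = 2 H^-1`). `nlminb`'s "false convergence" diagnostic is
re-examined by probing each free parameter by +/- 1e-3: if no probe
improves the OFV by more than 0.05 (far below any likelihood-ratio
threshold), the solution is accepted — this matters for boundary
solutions, e.g. when an IIV variance collapses.

Empirical Bayes (MAP) estimates reuse the inner mode, so `estimate_ebe()`
is by construction consistent with the objective. Eta shrinkage is
reported as `100 (1 - SD(eta_hat)/omega)`, clipped to [0, 100].

## Covariate machinery and selection

Continuous covariates use the power form `(value/median)^theta` (the
exponent is the estimated log-linear coefficient); binary covariates use
`1 + theta * flag`. Stepwise selection accepts, per forward step, the
largest OFV drop meeting the threshold: 3.84 (p < 0.05, 1 df) for the
first covariate and 6.63 (p < 0.01) for subsequent additions — published
descriptions of this procedure mix the two thresholds, so both are
explicit arguments — and backward elimination removes covariates whose
deletion raises the OFV by less than 6.63. Ties break by candidate order,
making the search deterministic. Composite candidates such as
age-cutoff-by-DM are materialised as derived binary columns before the
search.

## Validation machinery

* **pcVPC**: observations (and each simulated replicate of the design)
  are scaled by `median(PRED in bin)/PRED` with population predictions,
  using quantile-based time bins (8 by default; the binning of the
  original analysis is not stated, so this is a package choice). BLQ rows
  enter as their M5-imputed values.
* **Bootstrap**: subjects are resampled with replacement to the original
  size and the model refitted per replicate; medians and percentile
  intervals are summarised over converged replicates. 1000 replicates is
  the conventional reporting scale; 50-200 is a practical desk scale and
  is what the test suite uses.
* **External validation**: MPE (`mean(pred - obs)`) and APE
  (`mean(|pred - obs|)`) under population (`eta = 0`) or individual
  (MAP) prediction. Intervals are reported both as 2.5-97.5 percentiles
  of the per-observation errors and as min-max ranges, because published
  error tables are often empirical ranges. With a single observation per
  subject the individual mode estimates `eta` from the same observation
  it is scored on; this circularity is inherent to sparse TDM validation
  and is why both modes are always reported.
* **Forecasting**: `AUC(0-24) = dose/CL_i` at a normalisation dose
  (1200 mg by default) and `Cmax` by bounded maximisation of the
  steady-state profile; attainment is scored against the conventional
  efficacy targets AUC >= 363 ug.h/mL and Cmax >= 30 ug/mL (inclusive).
  Comparator models are user-supplied through the registry; no
  third-party parameter sets are built in.

## The synthetic cohort

The generator emulates the study population the package is designed for:
Korean adult TB patients, 66.6% male, age median 54.5 y (19-96), lean
body weight median 48.1 kg (23.1-63.79), total body weight derived from
LBW by a normal ratio (median ratio 1.264). Ages and weights are drawn
from Beta distributions rescaled to the printed ranges; the Beta shapes
are matched to the printed medians via the `(a - 1/3)/(nu - 2/3)`
median approximation, and the age concentration (`nu = 4`) was chosen so
that the geriatric fraction is ~22%, matching the reported subgroup
sizes (110 of 486 aged >= 70). Diabetes prevalence is age-dependent
(8.5% below 70, 20.9% at or above), reproducing the reported
32/344/23/87 split of the four age-by-DM groups. Age and LBW percentiles
are coupled by a Gaussian copula (rho = -0.3) so older subjects are
lighter, and LBW medians are sex-shifted (51/42.5 kg) to reproduce the
overall median. Doses follow the guideline rule: 25 mg/kg (the midpoint
of the 20-30 mg/kg band) rounded to the nearest marketed total daily
dose {500, 1000, 1200, 1250, 1500, 1600, 2000} mg, capped at 2000 mg.
Sampling is outpatient (one uniform draw on (0, 24]) or inpatient (>= 2
distinct draws from pre-dose/1/2/5 h); the inpatient fraction (0.3) is a
package choice, as the original split is not reported. Observations are
censored at LLOQ 2 ug/mL: raw values are kept with a BLQ flag, and
`impute_blq()` applies the M5 rule (LLOQ/2 = 1 ug/mL) as an explicit
preprocessing step. The fed/fasted, renal and liver flags are generated
at the reported prevalences but have no effect on the simulated
concentrations; they exist so covariate-selection null behaviour can be
tested.

What the generator does *not* emulate: non-adherence, non-steady-state
patients, co-medication effects, assay error structure beyond additive
noise, or any correlation between random effects (Omega is diagonal).
Passing recovery tests therefore demonstrate that the estimation engine
is consistent under the stated design, not that the published estimates
are correct for real patients.

## Numerical choices

* The flip-flop singularity `Ka -> ke` is evaluated by its analytic limit
  when `|Ka - ke| < 1e-6 Ka`; the limit form is second-order accurate in
  the gap, so the profile is continuous to well below assay precision.
* `cmax_ss` brackets the maximum on a 481-point grid and refines it by
  golden-section search; the test oracle is a 1e-3 h grid.
* Sensitivities `G` use central differences with step 1e-4 on the eta
  scale; the outer Hessian uses central differences with relative step
  1e-4.
* Recovery and acceptance runs use 500-subject cohorts with three
  samples per subject (1/2/5 h) over three seeds — large enough for the
  fixed effects to be estimated within a few percent, small enough that
  the full pipeline runs in minutes on one CPU. The type-I-error study
  for covariate selection uses 200 replicates of a 40-subject,
  two-sample design for the same reason.
* Starting values for recovery fits are deliberately displaced from the
  generating values (e.g. CL 3 L/h, V 30 L, no covariate effect) so that
  convergence to the truth is informative.

## Known limitations

Single-dose (non-steady-state) data are supported only for testing, not
fitting; the error model is additive only; Omega is diagonal; there is no
censored-likelihood (M3) handling of BLQ data beyond M5 imputation; and
absorption-delay variants (lag time, transit compartments) are
deliberately out of scope. OFV values are comparable only as differences,
and between this engine and other NLME implementations only up to their
respective linearisation and convergence tolerances.
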