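---
title: "Modeling sFLT1 secretion kinetics: models, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sFLT1 secretion kinetics: models, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system and the model family

Endothelial cells constitutively secrete soluble FLT1 (sFLT1, also called
sVEGFR1), a truncated VEGF receptor isoform that sequesters VEGF in the
extracellular space and thereby shapes angiogenic patterning. The package
models one well-mixed intracellular pool `I` (all of ER, Golgi and
vesicles aggregated; immature plus mature protein) and one extracellular
pool `X` (conditioned media), both in molecules per cell, coupled by four
core first- or zeroth-order processes:

* production (rate `alpha`, #/cell/h),
* secretion (`I -> X`, rate constant `beta`, 1/h),
* intracellular degradation (`I -> 0`, rate constant `gamma`, 1/h),
* extracellular degradation (`X -> 0`, rate constant `delta`, 1/h).

The base delay model adds a fixed maturation delay `tau` (h): secretion and
intracellular degradation act on `I(t - tau)`, reflecting the transit time
through the secretory pathway before a newly made molecule can be exported
or degraded:

$$\frac{dI}{dt} = \alpha - \beta\,I(t-\tau) - \gamma\,I(t-\tau), \qquad
  \frac{dX}{dt} = \beta\,I(t-\tau) - \delta\,X(t).$$

Two further optional processes give a family of eight candidate structures
(`model_family()`): first-order internalization of extracellular protein
(`epsilon * X`, adding a `+epsilon X` term to `dI/dt`) and exponential
decay of labeled production during the chase phase of a pulse-chase
experiment (production `alpha * exp(-kappa t)` instead of an abrupt stop).
Absent processes are encoded as exact zeros of `tau`, `epsilon`, `kappa`
rather than separate equations, which keeps one right-hand side and makes
the parameter count `4 + (number of included processes)`.

Only M1 (no optional processes, the plain ODE model) and M2 (maturation
delay only, the base delay model) have intrinsically fixed labels. The
assignment of M3–M8 to the remaining six flag combinations is a package
convention (M3 production decay, M4 internalization, M5 delay+decay,
M6 delay+internalization, M7 decay+internalization, M8 all three); every
result that matters — parameter counts, AICc ranking — depends only on the
flags, not the labels.

Because `I(t-\tau) = I(t)` at steady state, all candidates share the
closed-form steady states

$$I_{ss} = \frac{\alpha}{\beta+\gamma}, \qquad
  X_{ss} = \frac{\beta}{\delta} I_{ss},$$

with characteristic half-times `ln 2/(beta+gamma)` and `ln 2/delta`
(`steady_state()`, `characteristic_times()`).

## Experimental protocols as simulation events

Two protocols are simulated exactly as the emulated experiments run
(`simulate_constitutive()`, `simulate_pulse_chase()`):

* **Constitutive secretion.** A pre-simulation from `(0, 0)` runs the
  system to intracellular steady state (declared when `I` changes by less
  than 0.5% over a 20 h chunk, with a floor of 1e-6 #/cell so the
  production-free system converges immediately; at most 200 chunks). The
  media change at `t = 0` resets `X` to zero, leaves `I` untouched, and the
  main simulation of 24 h or 72 h starts from a constant intracellular
  pre-history at the attained steady state.
* **Pulse-chase.** From `(0, 0)` — only the labeled cohort is tracked, and
  no labeled protein exists before the pulse — 20 minutes of production,
  then a media change and a 10 h chase with production off (or decaying
  with `kappa`). The intracellular history from the pulse carries across
  the media change; `X` is zeroed exactly.

Both protocols report `(I, X)` on a 1-minute grid, and all downstream
observation mapping reads simulated values at whole-minute times from that
grid.

## The integrator

The delay equations are solved by the method of steps: each accepted step
never exceeds `tau`, so the delayed argument always falls in already
completed history, which is stored as a sequence of cubic Hermite
interpolants (value and derivative at both step ends). The embedded pair is
Bogacki–Shampine 2(3) with FSAL, implemented in C++; integration restarts
exactly at delay-induced break points (`t0 + k tau`) and at every protocol
event, because the delayed term propagates derivative discontinuities at
multiples of `tau`.

Numerical choices worth knowing:

* Default tolerances are absolute 1e-4 / relative 1e-3 for delay models and
  1e-12 / 1e-8 for delay-free models, initial step 1e-2 h; all exposed via
  `solver_settings()`.
* Delays below 1e-6 h are integrated on the plain ODE path (no history
  bookkeeping); this is far below any physiologically meaningful maturation
  time and below the solver's resolution of the dynamics.
* Negative concentrations arising from the numerical approximation are
  clamped to zero at reporting time only; clamping anything larger in
  magnitude than `10 * abs_tol` raises a warning, because a large negative
  value signals solver failure rather than roundoff and must not be hidden.
* The pre-history before the first integrated time is the constant initial
  state — cells carry no tracked protein before plating, and both protocols
  start at `(0, 0)`.
* With `(beta+gamma) * tau` beyond the delayed-feedback stability threshold
  (about `pi/2`) the model is genuinely oscillatory-unstable; during
  optimization such parameter regions surface as integration failures and
  are handled by the large-residual path described below.

The test suite checks the integrator against two independent routes: a
brute-force fixed-step fourth-order integrator with linear history
interpolation (step 1/1200 h), and the packaged `deSolve::dede` solver.

## Data model, units, and the cost function

Datasets are long tibbles (`sflt_data()`): one row per observed point with
study, scenario (`constitutive`/`pulse_chase`), species (`X`/`I`), time,
value, unit kind, normalization reference time and omission flags.
Replicates at a time point are collapsed to their mean at load; omitted
points stay in the table but are excluded from fitting and from the
observation count used by AICc.

Simulations are #/cell internally; `predict_on_dataset()` maps them to
each dataset's scale — relative datasets are divided by the simulated value
at their reference time (X at 24 h for constitutive, X at 8 h for
pulse-chase, I at 0 h), absolute datasets are multiplied by a per-study
conversion factor (`unit_map()`). The conversion factor is configuration,
not a fitted parameter. The cost is the plain, equally weighted sum of
squared differences between observed and predicted values across all
retained points of all datasets; a switch to relative residuals
(`relative_residuals = TRUE`) is provided for comparison but is not the
scoring definition.

## Calibration and model selection

`multistart_fit()` draws log-uniform initial guesses inside per-parameter
boxes (`sampling_ranges()`: `alpha` 1e3–1e7 #/cell/h, rate constants
1e-3–10 1/h, `tau` 0.25–4 h) and runs box-constrained Levenberg–Marquardt
least squares on the log10-transformed parameters. The log scale is a
deliberate choice: it conditions a search that spans orders of magnitude
and keeps every rate positive without penalty terms. Any simulation
failure during a line search contributes a large finite residual (1e6 per
point) instead of raising, so one pathological start can never kill a
multistart batch; such runs end flagged `converged = FALSE`. Ties for the
best fit break by earliest run index, making results reproducible under a
fixed seed.

Ensembles are filtered to runs within 10% of the minimum cost
(`filter_fits()`), then summarized (`summarize_ensemble()`) with nine
statistics per parameter and per compound constant. Quartiles use linear
interpolation between order statistics (`stats::quantile` type 7) and the
MAD is reported raw, without the 1.4826 normal-consistency factor; both
ratio conventions (median/IQR and IQR/median) are emitted so either
convention of summarizing spread can be compared directly.

Model scoring uses the small-sample corrected Akaike criterion with the
natural logarithm,
`AICc = n ln(C/n) + 2k + 2k(k+1)/(n-k-1)`, where `k` is the free-parameter
count plus one (the residual variance). `score_model_family()` applies the
full multistart to each candidate and ranks by AICc; candidates with no
converged fit are flagged and left unranked.

## Identifiability: what the data pin down

Temporal secretion data constrain `delta` and `tau` directly, but not
`alpha`, `beta`, `gamma` individually: only the product `c1 = alpha*beta`
and the sum `c2 = beta+gamma` are pinned, leaving one degree of freedom.
`parameters_from_beta()` walks that manifold (`alpha = c1/beta`,
`gamma = c2 - beta` for any `beta` in `(0, c2]`), `beta_grid()` builds the
five canonical sets at `beta = {0.2, 0.4, 0.6, 0.8, 1} * c2`, and
`steady_state_bounds()` gives the implied bounds (`I_ss >= c1/c2^2`,
`alpha >= c1/c2`). All manifold members produce identical extracellular
time courses while their intracellular steady states scale as `1/beta` —
which is why an absolute intracellular measurement would close the last
degree of freedom.

`sflt_median_params()` carries the median calibrated parameter set of the
delay model (`alpha = 1.419e5`, `beta = 5.123e-2`, `gamma = 1.215e-1`,
`delta = 5.743e-2`, `tau = 1.958`); it is the baseline for sensitivity and
inhibition analyses and the ground truth of the synthetic generator.

## Sensitivity analysis

`local_sensitivity()` uses the one-sided discrete definition — each
parameter increased by 10%, outputs re-simulated, relative change divided
by 0.10 — rather than a symmetric derivative, because that is the
procedure the analyses it supports used. Outputs are `X72h`, `I72h`
(equal to `I_ss` during constitutive secretion) and `T50_X`, the first
grid time at which `X` crosses half its *theoretical* steady state; with a
1-minute grid the `T50_X` sensitivities carry a quantization of order
0.1–1%, which the tests' tolerances reflect. `global_scan()` multiplies
one parameter at a time by 25 log-spaced factors over 1e-2–1e2 (both
knob-adjustable); scan cells whose pre-simulation cannot reach steady
state — notably extreme maturation delays, where the delay interferes with
the steady-state initialization itself — are reported as failed cells with
the error message rather than silently dropped. `compound_scan()` explores
the constrained manifold directly, holding one compound constant fixed.

## Inhibition simulation and inversion

Chemical inhibition reduces one parameter to `(1-f) p` at the media change
after an unperturbed pre-simulation; genetic (siRNA-like) inhibition
applies the reduction from before the pre-simulation, assuming full
effectiveness by `t = 0`. `estimate_inhibition()` inverts an observed
perturbed/control ratio by bisection (tolerance 1e-4 on `f`, comfortably
below the two-digit percent scale at which such estimates are reported)
after checking the response curve for monotonicity on a 0.05-spaced grid;
non-monotone responses abort with a diagnostic rather than returning a
root. Observed ratios beyond the full-inhibition response are flagged
`exceeds_full_inhibition`, ratios on the wrong side of 1
`wrong_direction` — these flags, not specific percentages, are the
reproducible content of inhibitor comparisons, because published percent
inhibitions derive from experimental fold-change ratios that are not
available as numbers.

## The synthetic-data generator

`generate_study()` emulates the *structure* of three published HUVEC
secretion studies — an ELISA-like 72 h constitutive course of extracellular
sFLT1 in absolute units (sparse grid 0–72 h, the 3 h point omitted as
below the limit of quantitation), a Western-blot-like 24 h constitutive
course of both species in relative units, and a pulse-chase 10 h course of
both species in relative units (the 10 h extracellular point omitted as
trend-inconsistent) — with the default grids chosen so the retained points
total 26 observations, the size of the emulated compilation. The defaults
(ground truth = median calibrated set, `sigma = 0.1`) are fixed study
conditions, not tuning knobs.

Noise is multiplicative log-normal, applied to every sampled raw value
*before* normalization. Consequently the reference point of a relative
dataset is itself noisy and its noise propagates to every point of that
dataset (the reference point itself is exactly 1, as in real normalized
data). This emulates how normalization to a measured reference behaves,
and it has a real statistical consequence: the effective noise on relative
points is about `sigma * sqrt(2)` and is correlated within a dataset, so a
single noise realization at `sigma = 0.1` can shift the least-squares
optimum of slowly identified quantities like `delta` beyond 10%. Tests
that assert tight recovery therefore either use noise-free data (where
recovery of `delta` and `tau` is near-exact) or must be read as checks of
the identifiability *structure* — tight `delta`, `c1`, `c2`, loose
`alpha`, `beta`, `gamma` — rather than of single-realization accuracy.

What the generator does **not** emulate: Western blot saturation, ELISA
limits of quantitation (the omitted points are flagged by design, not by a
censoring model), replicate structure, digitization error, or cell
proliferation. Passing recovery tests on these fixtures therefore shows
the pipeline is self-consistent and identifies what the model makes
identifiable; it does not certify accuracy on real assay data with
different error structure.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes a single CPU handles in
minutes, as the package's own scaling choice: multistart ensembles of
16–24 starts for calibration checks, 8 starts per candidate for the
two-model AICc recovery (20 noise replicates), 5 starts per candidate for
the eight-model family ranking, oracle trajectory comparisons on 5 random
stable parameter sets, and noise-monotonicity checks at
`sigma = {0.2, 0.05, 0}` with 2 seeds each. The production-scale analysis
the functions support (1000-start ensembles) runs the identical code path
with larger `n_starts`.

## Known limitations

* A fixed maturation delay is a simplification of a stochastic transit
  process; the single intracellular pool cannot distinguish whether
  internalized protein re-enters the matured or pre-maturation pool (with
  internalization absent from the selected model, nothing downstream
  depends on this).
* The constitutive scenario masks `tau` entirely, so constitutive-only
  data cannot constrain it; pulse-chase data are essential.
* Percent-inhibition comparisons to specific inhibitors require the
  experimental fold-change ratios as inputs (`estimate_inhibition()`
  takes them as arguments); the package deliberately ships no such
  numbers.
* At parameter combinations with `(beta+gamma)*tau` beyond the delayed
  feedback stability threshold the model oscillates unstably; the
  calibration treats these regions as failed evaluations, which matches
  how such fits behave (they never converge to secretion-like data).
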