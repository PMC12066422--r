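---
title: "Methods: whole-body PBPK/PD simulation of aldosterone synthase inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK/PD simulation of aldosterone synthase inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asipbpk)
```

## The model and its assumptions

`asipbpk` integrates a linear whole-body PBPK model: 14 perfusion-limited
tissue compartments plus arterial and mixed venous blood. Every tissue is
assumed flow-limited — drug in tissue equilibrates instantaneously with the
emergent blood, so distribution is governed by blood flow `Q_T` and by the
tissue:blood partition coefficient. For a non-lung tissue,

$$\frac{dA_T}{dt} = Q_T\,\frac{A_{ART}}{V_{ART}} - \frac{Q_T}{V_T\,K_{p,T}/bpr}\,A_T,$$

with the lung fed from the venous pool instead. Oral doses enter an absorption
depot that feeds the gut compartment with first-order rate `gi_ka`
(bioavailability is fixed at 1 — no separate F is carried). Systemic
clearance `CL_app` acts on *venous plasma* concentration
$C_p = (A_{VEN}/V_{VEN})/bpr$ and routes drug to a cumulative "eliminated"
compartment, closing the mass balance exactly.

Three structural choices deserve note, each made because the model is
specified by whole-body parameters only:

* **Elimination site.** Only a whole-body apparent clearance is available
  (no hepatic intrinsic clearance), so elimination is taken from the venous
  pool rather than the liver.
* **Parallel perfusion.** All tissues are perfused in parallel from the
  arterial pool; there is no portal (gut→liver) routing. First-pass loss is
  therefore absorbed into the calibrated clearance.
* **Kp dialect.** The compound records store *tissue:plasma* partition
  coefficients (the convention of the source tables), while the rate equation
  needs *tissue:blood*; the conversion divides by the blood:plasma ratio
  before use. The global `Kp_scaler` is applied to the tissue:plasma value,
  i.e. before that conversion.

The system is linear, which the test suite exploits: dose-proportionality of
AUC and Cmax, superposition of multiple-dose profiles from time-shifted
single-dose profiles, and conservation of total mass are all checked to
solver tolerance.

### The pharmacodynamic layer

Only unbound drug is assumed active. Plasma concentration is converted to
free molar units, $C_{free} = C_p \cdot f_{up} \cdot 1000 / MW$ (nmol/L), and
each enzyme's inhibition follows the Emax model

$$E = E_0 - I_{max}\frac{C_{free}}{C_{free} + IC_{50}}.$$

The package reports the positive inhibition magnitude (0% = no inhibition,
`Imax` = complete inhibition), matching how inhibition-rate curves are read;
defaults are $E_0 = 0\%$, $I_{max} = 100\%$. Because single summary
conventions differ between studies, `inhibitionSummary()` evaluates the
steady-state interval at three exposures — peak, trough and time-average —
and reports all three. IC50s are carried as published even where they
originate from monkey adrenal homogenate assays; the per-record `provenance`
field records this but does not change behaviour.

## The reference physiology

The source model never publishes its virtual subject, so the package defines
one: a 70 kg reference adult with cardiac output 390 L/h (6.5 L/min), organ
volumes following standard reference-man organ weights at unit density, and
regional flows as conventional fractions of cardiac output. `rest_of_body`
absorbs the remaining mass and flow so that the non-lung flows sum *exactly*
to cardiac output and total volume (67.44 L including 5.2 L blood, split
venous:arterial 3:1) stays anatomically plausible. Any internally consistent
reference set is admissible here; this one is config-overridable per tissue
via `referenceSubject(overrides = ...)`, with lung flow recomputed after
overrides so the flow-balance invariant can never be broken by construction.
Both volumes and flows scale linearly with body weight — the simplest
defensible allometry for a single-virtual-subject use case. Population
variability is out of scope.

A consequence worth keeping in mind: simulated endpoints that depend on the
physiology (AUC, Cmax, half-life) can only be compared with published values
at a tolerance, not bit-exactly — the published simulations used an
unpublished subject. The package's calibrated 2.5 mg Baxdrostat run lands
within a few percent of the published post-calibration AUC0-24 and Cmax,
well inside the conventional two-fold band that `twoFoldCheck()` encodes
(boundary inclusive: a ratio of exactly 0.5 or 2 passes, since only ratios
*beyond* two-fold are considered significant deviations).

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `dtOut` | h | 0.1 | output grid; dense enough that linear-trapezoid AUC error is immaterial |
| `rtol`, `atol` | — | 1e-8, 1e-10 | lsoda tolerances, fixed for reproducibility |
| `kpFactor`, `clDivisor` | — | 0.85, 4.7 | the published two-parameter calibration, applied identically to all compounds |
| `nTail` | samples | 5 | terminal half-life regression window |
| `radius` | cm | 1.25 | small-intestinal radius in `gikaFromPeff` |
| `imax`, `e0` | % | 100, 0 | Emax model constants |
| body weight | kg | 70 | reference subject |

MAD designs default to 10 doses at a 24 h interval plus a one-interval
washout (264 h horizon): ten intervals exceed five terminal half-lives for
every calibrated library compound, so the last interval is at steady state.
SAD designs default to a 96 h horizon so the terminal phase is observable.

## Numerical choices

* **Integration.** `deSolve::lsoda` (stiff-capable) on the constant-matrix
  linear system; dosing is implemented as depot impulses through solver
  events, so the integrator restarts at dose times and impulses are exact.
  Solver output at exactly a dose time reports the pre-dose state.
  Negative states beyond a small tolerance abort with the offending
  compartment named; sub-tolerance solver noise is clamped to zero.
* **AUC.** Linear trapezoid with interpolated boundary samples when the
  bounds are off-grid. At the default output density the difference from
  log-linear integration is negligible.
* **Cmax/Tmax.** The earliest grid point attaining the maximum (ties resolve
  early).
* **Half-life.** OLS of log-concentration on time over the last `nTail`
  positive post-peak samples; a non-negative slope raises an explicit "no
  terminal phase" error rather than returning a bogus value.
* **Calibration.** Exhaustive grid search minimising RMSE between simulation
  and observation at the observed sampling times; deterministic tie-break
  toward the smallest `kpFactor`, then the smallest `clDivisor`.
* **Missing Kp values.** Only 11 tissues have published partition
  coefficients. Stomach uses gut's value, pancreas spleen's (adjacent
  splanchnic organs with similar perfusion character), and `rest_of_body`
  the mean of the 11 published values — each then multiplied by the
  Kp scaler.
* **Rounding.** Internal computation is full-precision; values are rounded
  to 2 decimals only when compared against published tables.

## What the synthetic recovery study emulates

The calibration-recovery test generates "observed" data from the model
itself: a 2.5 mg single dose sampled at 15 clinical-style time points over
96 h (about four terminal half-lives, so clearance is identifiable from the
tail), with 5% multiplicative lognormal-like noise at a fixed seed. The grid
spans 0.75–0.95 in steps of 0.05 for the Kp factor and 4.3–5.1 in steps of
0.2 for the clearance divisor. Noiseless data recover the generating factors
exactly; noisy data recover them to within one grid step. This demonstrates
the estimator's correctness and stability — it does *not* demonstrate that
the model family is correct for real compounds, since the data generator and
the fitted model coincide by construction. Real calibration data additionally
carry structural misfit (absorption delays, enterohepatic recirculation,
nonlinearities) that this study cannot probe.

Likewise, the five-compound library reproduces published *parameter tables*;
simulated endpoints inherit whatever error those parameters and the chosen
physiology carry. Passing tests show internal consistency and agreement
with the published endpoints at the stated tolerances, not clinical validity.

## Known limitations

* Strictly linear kinetics: no saturable clearance, transporters, or
  enzyme interplay; no inter-individual or inter-occasion variability.
* IV dosing is not a user-facing route (a constant venous infusion exists
  only as a steady-state test harness).
* The permeability regression `log10(Peff) = 0.6795 log10(Papp) − 0.3355` is
  implemented exactly as published; its operand units are as-published and
  undocumented at the source, so absorption constants cannot be back-derived
  from monolayer permeabilities with certainty.
* Two published post-calibration table entries disagree with their own
  arithmetic at the final printed digit (3.1553 printed as 3.15; 0.7735
  printed as 0.78); the package computes, and tests assert, the arithmetic.
* The published selectivity index of BI689648 (149) disagrees with the ratio
  of its own published IC50s (310/2.1 = 147.6); the package stores the IC50s
  and computes the ratio.
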