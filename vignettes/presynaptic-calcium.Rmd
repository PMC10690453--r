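---
title: "Methods: aSN-activated PMCA and presynaptic calcium dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aSN-activated PMCA and presynaptic calcium dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcasyn)
```

`pmcasyn` connects three levels of description of the same biology —
steady-state enzymology of the plasma membrane Ca²⁺-ATPase (PMCA), the
buffer chemistry that sets free Ca²⁺ in activity assays, and a dynamical
model of a presynaptic terminal in which alpha-synuclein (aSN) modulates
the pump. This vignette records the models, the parameter choices and
their rationale, the numerical decisions, and what the synthetic-data
generators do and do not emulate.

## Enzymology

### Hill fits

Ca²⁺-titration ATPase data are fit with the Hill equation

$$v(C) = \frac{V_{max}\,C^{n}}{K_d^{\,n} + C^{n}},$$

by unweighted nonlinear least squares on replicate-level observations
(Levenberg–Marquardt, `minpack.lm`). Replicates are deliberately not
averaged before fitting: averaging discards the information needed for
honest standard errors, and the unweighted choice reflects that the assay
noise is approximately homoscedastic on the rate scale. When per-point
SEMs are available, `fit_hill(weights = 1/sem^2)` provides inverse-variance
weighting.

`fit_hill` treats the Hill coefficient as free by default, with `fix_n`
available because published apparent-$K_d$ tables for PMCA do not always
report $n$; fixing $n$ trades bias for variance on sparse titrations.
Starting values come from the data (max activity; abscissa of half-max;
$n = 1$), with five jittered restarts under a fixed internal seed if the
first start fails. A fit is flagged `converged = FALSE` when the optimizer
fails or when the $K_d$ standard error exceeds ten times the estimate —
the signature of a titration with no usable curvature (e.g. constant
activity), where $K_d$ is not identifiable. Flagging rather than erroring
keeps batch pipelines running while making the failure visible.

### Non-essential activation by aSN

aSN is a *non-essential* activator of PMCA: the pump turns over without
it, and activation saturates. In the general modifier mechanism the
activator binds the enzyme and enzyme–substrate complex and rescales both
the apparent $V_{max}$ and $K_m$. At the fixed substrate concentration of
a titration assay, that mechanism is not identifiable beyond two
parameters, and the predicted fold activation collapses to

$$FA(A) = \frac{1 + \beta A / K_{1/2}}{1 + A / K_{1/2}},$$

which is exactly 1 at $A = 0$ (no intercept is estimated — the constraint
is structural) and saturates at the maximal fold activation $\beta$. The
lumped $K_{1/2}$ is the activator concentration of half-maximal effect.
This reduced form is the package's design choice for `fit_activation`; a
global fit of the full modifier mechanism across substrate concentrations
is out of scope, because the data the model is meant for are collected at
one fixed free-Ca set-point.

Flat fold curves ($\beta \approx 1$) leave $K_{1/2}$ unidentifiable and
are flagged; negative fold values are rejected as physically meaningless.

## Free calcium in chelatored buffers

Activity assays set free Ca²⁺ with EGTA in the presence of Mg²⁺ and ATP.
Writing apparent association constants $K'$ for CaEGTA, MgEGTA, CaATP and
MgATP, conservation of each total gives a coupled system in the free
species. The key structural fact the solver exploits: *given* the two
free metals, each free ligand is explicit,

$$[EGTA]_f = \frac{[EGTA]_t}{1 + K'_{CaE}[Ca]_f + K'_{MgE}[Mg]_f},$$

and likewise for ATP. The problem therefore reduces to nested
one-dimensional root searches — an outer search on free Ca, an inner one
on free Mg — each monotone, solved with Brent's method on a logarithmic
scale (bracket: 15 decades below the total). Monotonicity makes the
solution global and unique; after solving, all four mass balances are
rechecked and the function errors if any relative residual exceeds 1e-9.
The inverse problem (`invert_free_ca`, "how much CaCl₂ to pipette") is an
outer Brent search on total Ca, bounded above by the target plus the full
chelator capacity, verified to reproduce the target to 0.1 %.

The shipped constants (`inst/extdata/chelator_constants.csv`) are apparent
log₁₀ association constants at pH 7.2 and 37 °C, the assay condition, of
the magnitudes used by Maxchelator-style calculators (CaEGTA 6.91, MgEGTA
2.38, CaATP 3.79, MgATP 4.10). They are data, not code: conditions other
than pH 7.2/37 °C require supplying a different table, since protonation
corrections are deliberately not computed inside the package.

## The presynaptic model

### Structure

The terminal is a point compartment. Membrane potential follows the
classical squid-axon Hodgkin–Huxley equations (capacitance 1 µF/cm²;
$g_{Na} = 120$, $g_K = 36$, $g_{leak} = 0.3$ mS/cm²; reversals +50, −77,
−54.4 mV), stimulated by square current pulses — the model describes a
point terminal, so action potentials are evoked, not propagated. A
voltage-gated Ca²⁺ channel adds one activation gate with Boltzmann steady
state (half-activation −17 mV, slope 8 mV, time constant 1 ms — a
P/Q-type-like high-voltage-activated profile) and, by default, an ohmic
driving force with $E_{Ca} = 125$ mV. A GHK current is available behind
`vgcc$driving = "ghk"`; the selector records the convention, since both
appear in the presynaptic modelling literature and the downstream
conclusions do not hinge on the choice.

Cytosolic Ca²⁺ obeys

$$\frac{d[Ca]}{dt} = f\,(-I_{Ca}) + J_{leak}
  - FA(A)\,V_p\,\frac{[Ca]^h}{[Ca]^h + K(A)^h}
  - V_{ncx}\frac{[Ca]}{[Ca] + K_{ncx}},$$

with $f$ = `flux_scale` (0.15 µM·cm²/µA/ms) lumping surface-to-volume
ratio, Faraday conversion and the fast-buffer fraction into one factor —
the model does not resolve an explicit buffering variable, so $f$ is the
only place buffering enters. NCX is given the Michaelis form with
$K_{ncx} = 1.8$ µM and $V_{ncx} = 0.4$ µM/ms: a low-affinity,
high-capacity extruder that dominates clearance at transient peaks, while
the high-affinity, low-capacity PMCA shapes the resting state and the
transient tail. NCX voltage dependence is omitted; the analysis is
rest-dominated and the simplification keeps the Ca balance autonomous in
V except through the VGCC.

### aSN action on the pump

aSN enters twice, matching the enzymology: $V_{max}$ is multiplied by the
fitted fold activation $FA(A)$ (default $\beta = 5$, $K_{1/2} = 1$ µM),
and the apparent $K_d$ interpolates between its basal (0.56 µM) and
aSN-saturated (0.082 µM) values — the measured pair for the full-length
pump in brain lipid extract — through the activation occupancy
$\theta(A) = (A/K_{1/2})/(1 + A/K_{1/2})$. The pump Hill coefficient is 2,
the conventional value for PMCA Ca²⁺ dependence. With $K_{1/2}$ of order
1 µM, the steady-state dose response is steepest below 10 µM aSN and
essentially saturated above it, so physiological fluctuations at high aSN
leave resting Ca²⁺ unchanged.

### Calibration

Two flux magnitudes cannot be taken from titration assays: the absolute
PMCA capacity $V_p$ in the terminal and the lumped leak influx. They are
fixed by requiring the unstimulated fixed point to sit at 0.25 µM Ca²⁺
without aSN and 0.1 µM at saturating aSN — the two resting endpoints the
model is meant to connect. Imposing the resting balance at both
endpoints gives two equations *linear* in $(V_p, J_{leak})$, solved in
closed form by `calibrate_ca_fluxes()` at construction. Calibration is a
property of the parameter object, not a hidden fitting step: pass
`calibrate = FALSE` to use explicit values.

### Numerics

- Integration: `deSolve::lsoda`, rtol 1e-8 / atol 1e-10. Square pulses
  are discontinuous, so the trajectory is integrated piecewise between
  pulse edges; the solver never steps across a discontinuity.
  Output is sampled at 0.02 ms.
- Initial state: the resting fixed point (membrane at its resting
  potential from a bracketed root of the total ionic current on
  [−90, −40] mV; gates at steady state; Ca at the aSN-dependent steady
  state), so a no-stimulus protocol stays flat to solver tolerance.
- Steady states: algebraic Brent root of the net Ca flux. Because efflux
  is strictly increasing in Ca and the resting influx is constant, the
  positive root is unique; the bracket ceiling is grown by decades until
  the net flux changes sign. `verify = TRUE` cross-checks by a 5 s
  integration to 0.1 %. Systems with no effective influx at rest (the
  fixed point collapses to Ca = 0) are reported as degenerate errors.
- Positivity: integration aborts with an error if Ca becomes
  nonpositive, rather than continuing on an unphysical trajectory.

### Transient metrics

`peak_metrics` defines baseline as the pre-stimulus mean, peak height as
the maximum, and the pre-/post-peak widths as the times from the upward
half-maximum crossing (above baseline) to the peak and from the peak to
the downward crossing, with linear interpolation between samples. On a
Gaussian bump both widths are $\sigma\sqrt{2\ln 2}$; on a step-rise /
exponential-decay transient the post width is $\tau\ln 2$ — both are used
as closed-form test oracles.

For spike trains, the moving-average maximum uses a centered window of
one inter-spike interval (50 ms at 20 Hz): a whole-period average removes
the within-train oscillation and leaves the accumulating mean, which is
the quantity of interest. Centered (not trailing) keeps the summary
phase-neutral. `compute_auc` is a trapezoidal integral with linear
interpolation at window edges, defaulting to the 2–12 min window used for
slow indicator recordings; no baseline subtraction is applied by default
(`baseline_subtract = TRUE` subtracts the pre-window mean), since the raw
area is the conventional summary for such recordings.

## PSI binning

Tissues are assigned to expression intervals of the binning gene —
left-closed, right-open $[a, a+10)$ from 0 to 190 cRPKM by default — and
each event's non-missing PSI values are averaged per interval. Two edge
conventions had to be decided: tissues at or beyond the last edge go to a
separately flagged overflow bin rather than being silently dropped or
merged, and missing PSI is excluded per event (not per tissue), because
tissue-by-event coverage in VastDB-style exports is event-specific. Both
conventions are checked by exact-conservation tests: the count-weighted
mean of bin means must equal the global mean over included tissues
exactly. Where a splice variant is defined by several exons jointly, the
module reports each exon separately and leaves any composition to the
caller. The trend summary is a Spearman rank correlation of bin midpoint
against mean PSI over populated non-overflow bins, requiring at least 3
populated bins and returning 0 for all-tied means.

## Synthetic data

The generators are pure functions of their specification (seed included,
run in a private RNG stream) and attach their generating parameters to
the output for round-trip tests.

- `gen_hill_curve`: Hill activities over log-spaced concentrations
  (titrations span nM–µM, so log spacing is the realistic design) with
  additive Gaussian noise, SD = `noise_sd` × $V_{max}$ — mimicking
  roughly constant absolute scatter across a titration. Default 8 points
  over 0.01–10 µM, the span of a free-Ca titration around a sub-µM $K_d$.
- `gen_activation_curve`: the $FA$ hyperbola over a zero point plus
  log-spaced aSN concentrations with multiplicative noise
  (SD = `noise_sd` × value), since fold-activation scatter grows with the
  fold.
- `gen_psi_tables`: 60 tissues (a VastDB-scale panel), uniform expression
  over 0–190 cRPKM, logistic PSI trend between the `psi_range`
  asymptotes plus 5-point Gaussian noise, and a 5 % fraction of
  off-trend outlier tissues with uniform PSI — emulating the few tissues
  (e.g. high-expressing non-neural ones) that sit off the main trend.
- `gen_ca_trace`: flat baseline, linear evoked rise at 2 min, exponential
  clearance (τ = 2 min), sampled at 0.005 min — the shape of a
  depolarization-evoked indicator recording. The exact integral of the
  continuous trace is available in closed form
  (`analytic_trace_auc`) as the AUC oracle.

What the generators do *not* emulate: correlated replicate errors,
concentration-dependent assay artefacts (substrate depletion, protein
adsorption at low concentration), indicator saturation and bleaching,
tissue phylogenetic correlation in the PSI tables, and any spatial
structure in the Ca signal. Passing recovery tests on these generators
therefore demonstrates correctness of the estimators under the stated
noise model, not robustness to real-data pathologies.

## Problem sizes

The test-suite simulations use single action potentials (~0.5 s trace
each at 0.02 ms sampling) and 20 Hz / 400 ms trains; Monte-Carlo recovery
studies use 200 seeded Hill replicates and 100 activation replicates,
with the grid-search and bisection oracles run at reduced grid sizes.
These sizes were chosen so that the full suite documents the statistical
claims (median-within-SE, ≤10 % median error, ≥95 % sign agreement) at
conventional Monte-Carlo precision while remaining a routine desk-scale
run.

## Known limitations

- The point-compartment model has no Ca²⁺ nanodomains, diffusion, ER/
  mitochondrial exchange, or vesicle-release coupling; SERCA is treated
  as an inhibited background, and proton countertransport by the pump is
  ignored.
- The reduced activation form is exact only at fixed substrate; data
  collected across substrate concentrations need the full modifier
  mechanism, which this package deliberately does not fit.
- Chelator constants are table lookups at one condition; no ionic-
  strength or temperature corrections are computed.
- The calibration ties two flux magnitudes to the two resting endpoints;
  transient amplitudes therefore inherit any error in those endpoints.
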