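---
title: "Models and methods behind hexakin"
author: "hexakin maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hexakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hexakin` converts TIRF movies of surface-immobilized fluorescent insulin
into per-transition assembly/disassembly rate constants, equilibrium
constants and extrapolated oligomer populations. This vignette records the
models behind each stage, the parameters that matter, the numerical choices,
what the synthetic-data generator does and does not emulate, and the known
limitations. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement model

A particle immobilized on the coverslip is a single growing/shrinking
oligomer: monomers (S1) through hexamers (S6). Species from solution bind
and unbind stochastically, so the particle's emitted photon count moves
between discrete levels, one level per oligomeric state. Three physical
layers sit between the state path and the recorded counts:

1. **Emission.** Each labeled monomer contributes on average 46 photons per
   50 ms exposure; a state of size m emits `m × 46`. The per-fluorophore
   brightness width is 16 photons; independent fluorophores add in variance,
   so the state-level width scales with `sqrt(m)` by default (a constant-σ
   option exists).
2. **Acquisition.** Frames are 50 ms exposures separated by 100 ms dead
   time (0.15 s/frame, 6.7 frames/s). Only the exposure window is observed:
   the generator averages state occupancy over the exposure alone, which
   reproduces the missed-event behavior of the real acquisition; a jump
   inside an exposure yields one occupancy-weighted intermediate frame.
3. **Camera.** An EMCCD reports `s = s0 + Gamma(shape = N, rate = γ)`
   counts, `N ~ Poisson(E)` photons, which is exactly the
   Poisson⊛Erlang density used in calibration; a zero draw collapses to
   the offset `s0`. Counts are rounded to the 16-bit integer grid.

The synthetic module (`simulate_state_path()`, `render_photon_trace()`,
`render_movie()`) implements these layers generatively, plus a 2-D Gaussian
PSF integrated per pixel, a Gaussian illumination profile, optional
per-particle bleaching (single exponential) and telegraph blinking, and
constant free-solution concentrations (open system — the surface particle
does not deplete the solution; whether the real experiment's solution
composition drifts over ten minutes is unknown, and constancy is the
simplest defensible choice). Every stochastic operation takes an explicit
seed and restores the ambient RNG state.

What the generator does **not** emulate: diffusing (non-immobilized)
particles, 3-D/astigmatic PSFs, irreversible amyloid-type aggregation,
spectral crosstalk, drift, and per-fluorophore photophysics inside a
multi-fluorophore oligomer (bleach/blink modulation is applied per
particle, which is exact for the monomeric control that motivates it).
Passing the recovery tests therefore demonstrates correctness of the
analysis chain under this measurement model, not robustness to artifacts
the model excludes.

## EMCCD calibration

`fit_emccd_pixel()` fits the three parameters `(s0, γ, E)` to one pixel's
count histogram across frames by minimum χ². Numerical choices:

- Integer-count bins are merged until each expected count is at least 5
  (χ² validity), with the expectation evaluated at a moment-based starting
  point (`mean = s0 + E/γ`, `var = 2E/γ²`, `third central = 6E/γ³`).
- The zero-photon spike is a separate bin (the one containing `s0`), never
  a narrow Gaussian.
- Bin probabilities use the integer-shape incomplete-gamma recurrence
  `P_{n+1}(x) = P_n(x) − e^{−x} x^n/n!`, making each objective evaluation a
  handful of vectorized arithmetic passes.
- Two starting points are tried (cumulants; the modal count as a spike
  guess) and the lower χ² wins. The p-value uses `bins − 3 − 1` degrees of
  freedom.
- The continuous density is evaluated on the offset-corrected argument
  `s − s0`: only under that convention does the density integrate to one
  and have mean `s0 + E/γ`, i.e. match the generative model it is fitted
  against.

`calibrate_camera()` fits 400 random pixels (without replacement, capped at
the pixel count), averages `s0` and `γ` over fits with p > 1%, and fails
loudly below 10 accepted fits. Per-pixel `E` is diagnostic only. Minimum-χ²
estimation carries a small finite-sample bias that grows with the
background level; at the particle-free background used in the tests
(2 photons/pixel/exposure) the averaged parameters recover the generative
truth within 1–2%, which the acceptance suite asserts.

## Illumination correction and photometry

The excitation profile is estimated as the σ = 30 px Gaussian blur
(reflective boundaries) of the time-average image. Frames are divided by
the profile **normalized to its maximum**: the raw division would cancel
the photon units, while max-normalization preserves the photon scale of a
particle under peak illumination — the same scale as the 46
photons/monomer calibration. Temporal smoothing (σ = 3 frames) is applied
to a *detection copy* only; photometry uses unsmoothed frames, because
smoothing along time would blur state transitions at the 0.15 s frame
interval and distort dwell statistics.

Detection follows the band-pass / local-maximum / integrated-mass recipe
(diameter 11 px, separation 6 px, minmass = 0.4 × mean of the averaged
movie) with two additions: a floor on the band-passed peak height (5 robust
noise units) that suppresses spurious maxima on near-empty synthetic
backgrounds, and a roundness acceptance window (default [1, 1.6]) that
drops merged spots while keeping shot-noise-distorted singles. Sub-pixel
positions come from least-squares 2-D Gaussian fits; coordinates are
0-based with pixel centers at integers, origin top-left.

Photometry integrates the discrete circular ROI of diameter 9 px (69
pixels) centered on the rounded centroid and subtracts the per-particle
Gaussian-fit baseline times the pixel count. The baseline comes from the
time-average fit and is reused for all frames (per-frame refits are not
attempted: at 46 photons/monomer a per-frame baseline would be noise-
dominated). With a σ = 1.5 px PSF, the ROI captures
`1 − exp(−4.5²/(2·1.5²)) ≈ 98.9%` of the spot mass; the recovery tests
divide by this factor when comparing to the generator truth.

One geometric caveat: the profile estimate is only meaningful on fields
large relative to the 30 px smoothing scale (real acquisitions are
hundreds of pixels on a side). On small synthetic fields, reflective
smoothing flattens the profile and bright spots near a boundary fold back
into their own background estimate; the tests therefore use fields of 96 px
and larger with slowly varying profiles, which is the regime the published
parameters were designed for.

## Trace QC

Traces with any frame above 500 photons are discarded as higher-order
aggregates (strictly above: a 499-photon peak survives). An optional
σ = 5 frame Gaussian smoothing supports low-SNR variants. The monomeric
control QC flags 400-frame blocks with mean ≤ 30 photons as bleached, and
frames in the 100–1000 window deviating from the trace mean by ≥ 3 trace
SDs as blinking; because the sign convention is not fixed by the rule's
plain reading, both the sign-free count and the dark-only (negative
deviation) count are reported.

## Seven-state HMM

Photon traces are idealized with a Gaussian-emission HMM whose seven state
levels are frozen: 20/50/100/150/200/250/300 photons with SDs
25/25/35/35/35/35/35. Freezing is forced by the data: the higher oligomers
are too rarely occupied for stable per-trace emission estimates. SDs are
frozen along with the means (freeing them is config-selectable but off by
default). Each trace gets its own transition matrix and initial
distribution via Baum–Welch (uniform initialization, ≤ 500 iterations,
absolute log-likelihood tolerance 1e−6), and the state path by Viterbi,
which yields a self-consistent path for dwell analysis (per-frame posterior
argmax does not). The recursions are compiled (Rcpp); a pure-R
implementation of the same forward–backward pass is kept in the package and
the tests assert the two agree to machine precision. No minimum dwell is
imposed; the prevalence of single-frame states is reported as a diagnostic.

**Known limitation — minimum resolvable dwell.** Viterbi decoding under the
frozen (wide) emission SDs suppresses state visits whose cumulative
emission evidence cannot beat the transition penalty. For adjacent levels
separated by 50 photons this makes dwells shorter than roughly 1 s (≈ 7
frames) invisible; for 100-photon separations the threshold is ~0.3–0.45 s.
Because the per-cluster rate estimator is 1/mean(dwell), missing short
dwells biases rates downward by roughly `d/(mean dwell + d)` plus a merge
term — measured at −12…−15% for monomer-spaced two-state kinetics at
0.1 s⁻¹. The package reports what the published estimator produces;
recovery is quantitatively within 10% in the estimator's validity regime
(transitions between levels ≥ 100 photons apart, dwells well above the
frame time and well below the 75 s cutoff), which is where the acceptance
suite pins it. The 75 s cutoff itself (simple exclusion, no truncated-
likelihood correction, exactly as published) adds an upward bias of
`≈ (75/τ)·e^(−75/τ)` relative for mean dwell τ — under 2% for τ ≤ 13 s.

Residual QC pools `trace − idealized` over an ensemble and reports the
Gaussian (μ, σ) plus an Anderson–Darling normality p-value; a centered,
normal residual distribution is the evidence that seven frozen levels
describe the data without systematic error. Monomer calibration pools
per-frame photons from anchored monomeric controls (pre-bleach frames
only when a bleach report is supplied), with a two-component-mixture BIC
screen that warns on aggregate contamination and reports the dominant mode.

State occupancies are mixture weights of a seven-Gaussian fit with frozen
means and SDs; the uncertainty comes from ten parametric-bootstrap refits
(resample from the fitted mixture, refit, report mean and SD), mirroring
the reinitialization scheme used for the published occupancy fits.

## Dwell kinetics and the CHESS table

Transitions are enumerated from the Viterbi path: every change between
non-background states is an event keyed by (state before, state after) —
the transition-density-plot grid aligned with the frozen levels, 42
possible clusters once S0-involving events are excluded. Dwells used for
rate fitting are interior (entry and exit both observed); a trace's first
segment is entry-censored and counts toward densities only. This censoring
rule avoids length bias while keeping the density bookkeeping complete —
the CHESS densities sum exactly to the number of enumerated events.

Per cluster, the exponential MLE is `rate = 1/mean(dwells ≤ 75 s)`, with a
nonparametric bootstrap SE (1000 resamples) and, when traces carry video
ids, the per-video refit spread as the published error variant. Clusters
with fewer than 10 events carry a low-n flag (the "triangle" annotation).
Association clusters are converted to bimolecular constants by dividing
with the solution concentration of the added species.

That concentration comes from the assembly step sizes themselves: the
photon increments of all assembly events are fitted with a five-Gaussian
mixture anchored at `m × μ` (μ from the monomer calibration, SDs
`sqrt(m) × σ`, weights free). Anchoring the means is a deliberate
identifiability choice at low weights. The weights are number fractions of
the free species; molar concentrations follow from monomer-equivalent
conservation, `c_m = w_m · C_N` with `C_N = C_total / Σ m·w_m`. The
conversion from weights to concentrations is not uniquely dictated by the
measurement — conservation of monomer equivalents is the convention used
here and results that depend on it inherit that caveat.

A competing-risks subtlety is documented rather than hidden: when a state
has several exit channels, the dwells ending in *any* one channel are
distributed with the *total* exit rate, so the published per-cluster fit
reports the total exit rate in every cluster of that state. The CHESS
table carries this convention (it is what the reported rate constants
mean), and additionally exposes `rate_corrected` — channel share × pooled
total exit rate — whose rows sum to the state's total exit rate.

## Thermodynamics and statistics

`K_eq = k_ij/k_ji`, `ΔG = −RT ln K_eq` and `ΔG‡ = −RT ln(h·k/(k_B·T))`
with R = 8.314 J/(mol K), T = 298 K and CODATA `k_B`, `h`. Condition
comparisons use Welch's unequal-variance t-test from summary statistics
(n = number of videos), with stars at p < 0.05/0.01/0.001, and rate-constant
ratios propagate first-order errors.

## Mass-action extrapolation

The solution network couples S1+S1⇌S2, S2+S1⇌S3, S3+S1⇌S4, S4+S1⇌S5,
S5+S1⇌S6, S2+S2⇌S4 and S2+S4⇌S6. Conventions that are easy to get wrong,
and are therefore unit-tested through mass conservation:

- `d[S1]/dt` contains `−2k12[S1]²` and `+2k21[S2]` (two monomers per
  dimerization event); likewise `−2k24[S2]²`, `+2k42[S4]`.
- The reverse of S2+S4⇌S6 is two parallel first-order channels `k62` and
  `k64` summing in the equations: experimentally distinct observations of
  the same net reaction. `k64` defaults to 0.01 s⁻¹, an upper bound an
  order of magnitude below hexamer monomer loss, because the transition is
  too rare to quantify directly.
- `k46` (dimer addition seen from the tetramer side) is not an input of
  the network; the S2+S4 forward flux uses `k26` alone, with a config
  switch to use `max(k26, k46)` for sensitivity analysis.
- `k42` is measurable only under phenol-containing conditions and is
  propagated unchanged to the others.

Integration uses `deSolve::lsoda` with rtol 1e−8, an absolute floor of
`C0 × 1e−12`, 200 output steps over 300 s, and a step-size cap of
`t_end/20` (without the cap, lsoda's step inflates without bound once the
fast reactions equilibrate and its interpolation fails). Monomer-
equivalent mass is conserved to better than 1e−9 relative, and the
default schemes reach `|d[S]/dt|/C0 < 1e−6` well before 300 s.

Endpoint fractions are particle-number normalized, `f_m = [S_m]/Σ[S_j]`
(a monomer-equivalent weighting is config-selectable), the mean oligomeric
state is `μ = Σ m·f_m`, and the hexamer fraction across a 1 nM–1 mM sweep
(the figure-style range; a 10 nM–100 mM methods-style sweep is one
argument away) is fitted with the Hill form to give the apparent affinity
K (half-maximal concentration), `n_h` and `B_max`. A Hill coefficient
below one is the expected signature of an assembly ladder with
heterogeneous stepwise affinities.

A particle-number Gillespie simulator of the same network (propensities
`k·nA·nB/(N_A·V)`, `k·n·(n−1)/(N_A·V)` for identical pairs) cross-checks
the deterministic integration; at ~1e5 particles the endpoint agrees with
the ODE within a fraction of a percent.

**Example schemes.** The shipped `example_scheme()` tables combine the
measured main-line constants with representative completions for constants
that were never printed (k12, k21, k32, k43, k54). The completions were
chosen once against published constraints — a weak, literature-scale dimer
(Kd ≈ 20 μM), dissociation rising with oligomer order up to a stable
hexamer, a micromolar apparent hexamer affinity and `n_h < 1` — not fitted
to data. Quantities that depend on the full measured tables (the 14-fold
affinity shift under both additives, the 1%/13% hexamer abundances at
10 nM, the ~40% effective-monomer reduction) are supported as workflow but
deliberately not asserted anywhere.

## Problem sizes used in validation

The test and acceptance suites choose sizes where the statistical error of
the check sits well inside the asserted band: 400 pixels × 4000 frames for
calibration recovery; 50 monomer spots × 250 frames for end-to-end
photometry; 200 traces × 500 frames (dwells ≥ 5 frames by construction)
for decode accuracy; 90 traces × 4000 frames (≥ 2000 events per transition)
for full-pipeline rate recovery; 1e4-sample oracles for dwell MLE
consistency; ~1e5 particles for the stochastic/deterministic cross-check.

## Known limitations

- Rates for transitions between adjacent 50-photon levels inherit the
  minimum-dwell bias described above; fast monomer exchange (≳ 0.1 s⁻¹) is
  systematically underestimated by ~10–15% by the published estimator.
- The weights → concentration conversion assumes monomer-equivalent
  conservation in solution.
- The per-particle bleach/blink model is exact only for monomeric
  controls.
- The example solution schemes are semi-synthetic (see above); quantitative
  condition comparisons require the user's own measured tables.
- Illumination correction presumes fields much larger than the 30 px
  smoothing kernel and backgrounds bright enough that spots do not
  dominate their own profile estimate.
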