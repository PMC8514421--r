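---
title: "Strike kinematics and energetics: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strike kinematics and energetics: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strikekin)
```

# The measurement problem

Trap-jaw spiders hold their chelicerae (jaw-like mouthparts) open at a wide
gape and snap them shut on prey. Whether that snap is driven by muscle alone
or by stored elastic energy released through a latch (latch-mediated spring
actuation, LaMSA) is conventionally tested by an energetic criterion: if the
strike's mass-specific power output exceeds the ~400 W/kg ceiling of
conventional muscle, muscle alone cannot explain it and "power
amplification" by a spring is inferred.

The raw data are high-speed videos (1,000–10,000 frames per second). After
image stabilization removes the whole-body lunge, the distal edge of each
chelicera is digitized manually, frame by frame (or every few frames), as a
planar point track. `strikekin` takes those tracks to the energetic verdict:

1. **Calibration** — pixels to millimetres (`calibrate()`), with optional
   drift subtraction against a tracked body point (`remove_drift()`).
2. **Displacement** — cumulative arc length of the tracked point
   (`cumulative_arc_length()`): the running sum of unsigned chord lengths,
   divided by the cheliceral length \(L\) to give angular displacement
   \(\theta(t) = s(t)/L\).
3. **Smoothing and differentiation** — a penalized quintic smoothing spline
   fit to \(\theta(t)\) (`fit_quintic_spline()`); angular velocity
   \(\omega\) and acceleration \(\alpha\) are the analytic first and second
   derivatives of the fitted spline (`differentiate()`), and linear
   kinematics follow as \(v = \omega L\), \(a = \alpha L\).
4. **Energetics** — the chelicera is a uniform thin rod pivoting at its
   base: \(I = \tfrac13 M L^2\); kinetic energy \(E = \tfrac12 I \omega^2\);
   strike power \(P = E_{max}/t_{E,max}\) with time measured from the first
   digitized frame; mass-specific power output \(O = P/m\) with \(m\) the
   adductor muscle mass (`strike_energetics()`).
5. **Aggregation** — left and right chelicerae strike synchronously and are
   averaged per strike; strikes are then averaged with equal weight into a
   species summary (`summarize_strikes()`, `report()`).

A synthetic strike generator with closed-form ground truth
(`simulate_strike()`) makes every stage testable by parameter recovery, and
a morphometrics module reproduces the micro-CT measurement post-processing
(left/right averaging, carapace-width size correction, clypeus ratio).

# The smoothing spline

Displacement is fit with a degree-5 (quintic) penalized B-spline: the basis
sits on equally spaced knots across the digitized window (basis dimension
`nseg + 5`, capped at the number of observations), and a third-order
difference penalty on the coefficients controls roughness. Quintic degree
gives a twice-continuously-differentiable acceleration estimate; the
third-order penalty leaves constants, lines and parabolas unshrunk, so
uniform rotation is reproduced exactly at any smoothing level.

The smoothing parameter is selected by generalized cross-validation (GCV),
\(n\,\mathrm{RSS}/(n - \mathrm{edf})^2\), minimized on a log-spaced grid and
refined with golden-section search. GCV is the sensible default when the
digitization error model is unknown, but it assumes roughly independent
errors; cumulative displacement has random-walk (integrated) noise, so GCV
can undersmooth dense, noisy tracks. For that reason `fit_quintic_spline()`
accepts an effective-degrees-of-freedom override, and every result carries
the `edf` actually used — reported results should quote it.

Two implementation contracts are enforced by tests: derivatives are the
analytic derivatives of the fitted basis (verified against central finite
differences of the fitted curve), and the fitted displacement agrees with an
independently implemented penalized B-spline smoother (mgcv) on the same
data. Peaks are extracted on a dense evaluation grid (10× the digitized
sampling) rather than at sample times, avoiding grid bias at 1 kHz; ties
take the earliest time.

# The synthetic strike generator

The generator's defaults are the study conditions for *Pararchaea alba*: a
gape (total angular sweep per chelicera) of 172.4°, closure in 12 ms,
cheliceral length 0.46 mm, 10,000 frames per second, 0.005 mm/px
calibration, digitization every 4th frame, and 0.5 px isotropic Gaussian
noise per coordinate. The angular profile is the quintic smoothstep
\[
\theta(t) = \Theta\,(10\tau^3 - 15\tau^4 + 6\tau^5),\qquad \tau = t/T,
\]
chosen because it is C², starts and ends at rest, matches the degree of the
analysis spline, and has closed-form extrema — peak velocity
\(1.875\,\Theta/T\) at \(\tau = 1/2\) and peak acceleration
\((10/\sqrt3)\,\Theta/T^2\) — which makes recovery errors exactly
computable. The pivot sits at the origin with the midline along +y; the two
chelicerae are mirrored and perfectly synchronous. An optional
constant-velocity translation of pivot and point emulates the lunge that
image stabilization removes in real footage; the tracked body reference
point is simulated alongside with the same noise model so drift removal can
be tested.

What the generator deliberately does **not** emulate: out-of-plane motion
and camera-angle foreshortening (real left/right curves can differ for this
reason), profile asymmetry or multi-phase closure, autocorrelated human
digitization error, and rolling-shutter or motion-blur artifacts. Passing
recovery tests therefore show the numerics are sound under the stated noise
model, not that any real strike follows a smoothstep.

The noise model (isotropic Gaussian in pixel space, default 0.5 px) stands
in for manual point-tool placement error, for which no published error model
exists. One integer seed drives all draws through R's default
Mersenne-Twister generator, in a fixed order, so simulations are exactly
reproducible.

# Known limitation: path-length inflation at high frame rates

Because cumulative displacement sums *unsigned* chord lengths, digitization
noise is rectified: once the true per-frame displacement approaches the
noise floor, each step contributes a positive bias of order
\(\sigma\sqrt{\pi/2}\), and the recovered sweep and peak velocity inflate.
At the default conditions this is why digitizing every frame at 10 kHz is
*worse* than digitizing every 4th frame — the same reason manual protocols
digitize "at set intervals". The package keeps the unsigned-chord
convention (it is the field's definition of cumulative displacement) and
treats stride selection as the mitigation: choose a stride such that the
per-step displacement comfortably exceeds the pixel noise times the scale.
The test suite measures this effect directly; it is a property of the
method, not a removable implementation artifact, and it breaks the naive
expectation that recovery error always falls as the frame rate rises.

# Conventions and tunable parameters

- **Angular-first fitting.** The spline is fit to \(\theta(t) = s(t)/L\);
  since \(L\) is constant, fitting \(s(t)\) instead would give identical
  peaks after unit conversion.
- **Strike duration** is the span from first to last digitized frame — the
  digitization protocol runs from open to closed position, so the digitized
  span is the strike. A thresholded alternative
  (`strike_window(threshold_frac=)`, window where \(\omega\) exceeds a
  fraction of its peak) is provided for sensitivity analysis only.
- **Strike onset** for the power calculation is the first digitized frame;
  \(t_{E,max}\) is measured from it, and a kinetic-energy peak at onset is a
  degenerate division and an error.
- **Chelicerae averaging** takes arithmetic means of the scalar summaries
  and pointwise means of the series on the common time support; a missing
  chelicera passes through flagged `averaged_n = 1`.
- **Species summaries** weight strikes (not individuals) equally and use the
  sample (n−1) standard deviation; with a single strike the SD is reported
  as 0 with `n = 1`.
- **Allometric masses.** Chelicera and adductor muscle masses are usually
  not weighable at this body size; they are estimated as \(m = cL^3\)
  (geometric similarity; exponent overridable). The coefficients must come
  from the user — e.g. a regression on related species — and are *never*
  defaulted, because any default would silently set the energetic verdict's
  scale. Where this package's own examples and tests need coefficients,
  they use a transparent geometric stand-in: a chelicera modelled as a
  cylinder of diameter \(0.2L\) at ~1080 kg/m³ (giving
  \(c_{chelicera} = 3.4\times10^{-8}\) kg/mm³) with the adductor at ~60% of
  chelicera mass (\(c_{muscle} = 2\times10^{-8}\) kg/mm³), which puts a
  0.46 mm chelicera at ~3 µg — the right order of magnitude for a spider of
  under 3 mm body length.
- **Digitization stride** defaults to 4 frames, the worked example of the
  manual protocol; it is a free per-video parameter, not a constant.

# Morphometrics conventions

Micro-CT muscle measurements (tendon length, shortest and longest fiber
length, microns) are taken per side and averaged left/right; measurements
extrapolated to the carapace's interior surface (detached muscles in the
open-chelicerae specimen) carry flags that propagate through averaging by
OR and render as asterisks. Size correction divides by the carapace width
of the matching specimen/state; the raw ratio is kept at full precision and
rounded half-even to two decimals only for table rendering, with a
documented ±0.01 tolerance against published tables (published rounding is
not perfectly consistent — three cells in the reference table differ from
recomputed two-decimal rounding by ≤0.01). The clypeus trait is stored both
as raw thickness and as the ratio to carapace thickness between the
anterior median eyes, because published summaries mix the two conventions.

# Degenerate inputs and tie rules

Tracks need at least 6 digitized points (quintic degree + 1); times must be
strictly increasing and consistent with `frame_index/fps` to 1e-9 s;
duplicate frames, unknown side codes and missing columns are hard errors
naming the row. Evaluating a spline outside its fitted interval is an
error. Peak ties resolve to the earliest time. Calibration refuses to run
twice. All validation is total: malformed input raises a classified error,
never a silent pass.

# Problem sizes used in the tests

The bundled verification uses a noise-free strike at the species-mean
parameterization (121 digitized frames) for closed-form recovery; 100
seeded noisy simulations at the default conditions for the robustness
median; 40 seeds per frame rate for the resolution ordering; a 16-strike
simulated study for aggregation; a 10⁶-segment discretized rod and a
1°-sampled quarter circle as brute-force oracles. These sizes keep the full
suite to well under a minute while leaving the statistical assertions
stable across seeds.
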