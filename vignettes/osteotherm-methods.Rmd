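---
title: "Modelling HIFU mild hyperthermia in osteolytic bone lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HIFU mild hyperthermia in osteolytic bone lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Osteolytic bone metastases destroy a sector of cortical bone and replace it
with soft tumour tissue. This *cortical breakthrough* is an acoustic window:
a focused ultrasound (HIFU) beam aimed through it can heat the medullar
cavity directly, which is otherwise inaccessible because intact cortical
bone absorbs and reflects ultrasound almost completely. Mild hyperthermia —
holding the lesion a few degrees above baseline (here +6&nbsp;°C, i.e.
~43&nbsp;°C) for tens of minutes — is a radio- and chemo-sensitizer, so a
stable, spatially uniform, automatically controlled elevation is the
clinical goal.

`osteotherm` is a desk-scale simulator of this system: a voxel phantom of
the drilled ex vivo lesion model, linear focused-beam acoustics, a
semi-empirical dual heat source, a Gaussian-kernel bioheat solver, PRFS
(proton-resonance-frequency-shift) MR thermometry emulation, and the
predictive duty-cycle controller that closes the loop. It exists so the
study's numerical findings — the optimal focal position, the time-lag
surface, the controller's stability envelope — can be reproduced and probed
without hardware.

## Phantom geometry

The bone is a finite cylinder along *x* (outer radius `cortical_radius_mm`,
default 6&nbsp;mm; shell thickness 3&nbsp;mm — the source model states only
"a few millimeters"). The breakthrough is the intersection of the cylinder
with a cone of full aperture 72°, apex on the cylinder axis, axis along the
beam (+*z*), opening toward the transducer; its voxels are tumour-mimicking
gel. Remaining interior is medulla, exterior defaults to muscle. Voxels are
isotropic (1&nbsp;mm default) on a centred, odd-count grid so the cylinder
axis, cone apex and breakthrough plane all fall on voxel centres.

One naming subtlety matters when comparing with the source study: its lag
analysis parameterizes bone size by the radius *R* of the *bone section*,
which its own sample table identifies with the medullar (internal) radius
(cavity long axes 10–16&nbsp;mm, "average radius 6&nbsp;mm"; a 14&nbsp;mm
*internal* diameter paired with ±7&nbsp;mm offsets). `geometry_params()`
keeps the outer-radius convention; `lag_table()` sweeps the section radius
and adds the shell on the outside. Under this reading the simulated lag at
(R = 6&nbsp;mm, H = 0) is 125.5&nbsp;s against the study's 126&nbsp;s; under
the outer-radius reading it would be ~55&nbsp;s.

## Acoustics

The transducer is a spherical cap (radius of curvature 130&nbsp;mm, aperture
120&nbsp;mm, f-number 1.08, 1&nbsp;MHz) discretized quasi-uniformly
(Fibonacci spiral) and evaluated with the Rayleigh–Sommerfeld integral in a
homogeneous medium, with the 0.5&nbsp;dB&nbsp;cm⁻¹&nbsp;MHz⁻¹ attenuation of
the tissue-mimicking gel folded into a complex wavenumber. The surface
velocity comes from the radiated power via the plane-wave relation
`P = ρc u₀²/2 · A_cap`. An exact closed form exists on the axis and serves
as the oracle for the numerical integral (agreement <&nbsp;2%, in practice
~10⁻⁶).

Two deliberate numerical choices:

* **Element size.** Arbitrary-point evaluation uses λ/3 elements. Grid
  fields use 2λ elements: every voxel of the desk-scale domain is
  ≥100&nbsp;mm from the cap, where the quasi-uniform cap at 2λ matches the
  closed form to ~10⁻⁶ relative; λ/3 on the full grid would cost ~14
  minutes per field for no measurable gain. A convergence test (halving the
  element size changes the focal pressure by <1%) guards this.
* **Grid spacing.** 1&nbsp;mm exceeds λ/2 = 0.77&nbsp;mm, so the focal peak
  is undersampled by design; `rayleigh_pressure()` warns unless the caller
  opts out, which the session constructor does knowingly. All
  peak-sensitive quantities go through the 13-pixel ROI average, which is
  insensitive to this.

Because the transducer is rigidly translated along the beam axis to set the
focal offset *H*, all offsets are integer-voxel shifts of one cached base
field: a full offset study or lag sweep costs a single surface-integral
evaluation.

Cortical bone is essentially opaque at 1&nbsp;MHz. Rather than solving the
solid-mechanics problem, the free-field intensity is masked by a **shadow
model**: every ray of a focused beam passes (approximately) through the
focus, so a voxel is dark when the focus-to-voxel segment crosses cortex.
Without this mask the beam would heat tissue through and behind the bone.

## The dual heat source and its calibration

Two mechanisms heat the cavity:

* **Direct absorption**: `q = 2βI` in soft tissue, with β = 5.756 Np/m
  derived from the gel attenuation at 1 MHz.
* **The acoustic oven effect**: the intensity incident on the exposed inner
  cortical facet is *averaged* over that surface, and a fraction α of the
  power crossing it is deposited uniformly in the cortical shell behind it
  (the facet grown through the 3 mm thickness — bone attenuation at 1 MHz,
  ~10 dB/cm, absorbs through the shell, not in a 1 mm sheet). This
  uniformization stands in for the reflection/refraction/evanescent-wave
  physics at the bone boundary and is what produces the near-circumferential
  isotherms around the cavity.

Both terms are scaled by an in-situ thermalization `efficiency` η: the
fraction of free-field beam intensity that actually becomes heat. It lumps
together the absorbed (vs scattered) share of attenuation, the water path
and transducer-drive losses relative to an ideal bowl, and heat lost to the
finite, bath-cooled specimen.

(η, α) are the model's only free constants, and they are **identified, not
tuned**: the plant is linear in its sources, so two noise-free open-loop
runs (direct-only and oven-only at unit constants) give component gains at
the focal ROI and at the intracortical sensor locus, and two printed
operating-point anchors close the system —

1. the controller converged to δ ≈ 0.18 at 60 W while holding +6 °C, i.e. a
   quasi-steady ROI gain of 6/0.18 = 33.3 °C at δ = 1;
2. the intracortical sensor read at most ~5.4 °C while the cavity held
   6 °C at the optimal focus, fixing the wall-to-cavity split.

`calibrate_sources()` solves the 2×2 system; its output (η = 0.291,
α = 0.253) is frozen as the package default. Both magnitudes are physically
plausible: ~30% of beam power thermalizing, and ~25% of post-focal power
depositing locally in the wall with the rest reflected or guided away along
the bone.

A consequence worth stating plainly: under these anchors the focal ROI is
direct-dominated (~84:16). The model then reproduces the converged duty
cycle, mean power (~10 W), delivered energy (~9 kJ), sensor ceiling and
overshoot envelope — but *not* the claim that the ring-uniformity CV is
minimized at H = 0 among {−7, 0, +7} mm: the in-front focus, illuminating
the cavity diffusely through the wide 72° window, gives the flattest ring,
while the H = 0 map carries the post-focal axial "bridge" bump (which the
study's own experimental maps show). The corresponding acceptance assertion
is left failing rather than papered over; the H = 0 vs +7 ordering, the
sensor-depth ordering and the in-cavity thermal-risk hot spot all hold.

## Thermal solver

Heat diffusion is the exact Green's-function update: each step convolves the
temperature-elevation field with a separable Gaussian of
σ = √(2DΔt) and injects `q·Δt/C`. Defaults D = 1.4×10⁻⁷ m²/s,
C = 3.8×10⁶ J/(m³K); no perfusion (ex vivo). The kernel must satisfy
σ ≥ 0.5 voxel (enforced), kernels are truncated at 4σ and renormalized,
and the boundary is absorbing with the bone centred in a 48 mm domain, so
that over a 12-minute session edge effects at the ROI stay negligible
(mass conservation over 100 source-free steps tests at <0.5%). Against the
analytic 3-D heat kernel the discrete step is accurate to <1% L2 after 10
steps. Cooling "nulls α and β": the source is simply withheld.

The pulse period (0.5 s) is two orders of magnitude below the conduction
timescale, so within a step the duty cycle is applied as average power.

## Time-lag analysis

The controller's central difficulty is the lag ε between the sonication
command and the focal-point temperature maximum, caused by centripetal
conduction from the wall. `impulse_response()` uses a 10 s pulse
(short against the ≥100 s lags) with the cortical source only, and
`time_lag()` refines the discrete peak with a parabolic vertex.
`lag_table()` sweeps section radii 6–10 mm and relative offsets
(−0.7R, 0.7R) on a 6×6 grid; `fit_lag_surface()` fits the six-term
quadratic in (H, R) by least squares. For this sweep the oven deposition
averages over the *full* internal facet: restricting it to a sharp beam
cone makes the uniform deposition set — and hence ε — jump discontinuously
as the focus shifts (fit residual 15.5 s instead of 9.2 s), and the
near-isotropic redistribution premise justifies whole-surface averaging.
The printed quadratic coefficients of the source study are not asserted:
evaluated at (R = 6, H = 0) they give ≈912 s, contradicting the study's own
126 s anchor, so the anchor and the monotonicity of ε(R) carry the
comparison instead.

## Thermometry emulation

Frames are single axial slices: 4 mm slab average along the bone, 1 mm
in-plane, 1.6 s cadence, i.i.d. Gaussian pixel noise of 0.2 °C, a global
drift (linear 0.3 °C over 12 min plus a 0.1 °C slow sinusoid — magnitudes
chosen since the study states only that correction is mandatory), and NaN
in cortical bone and medulla (no PRFS signal in short-T2* bone; fat
suppressed). Drift correction subtracts the mean of a 3×3 unheated muscle
patch. The focal ROI is the 13-pixel disc (centre + 12 nearest in-plane
neighbours). The fluoroptic sensor is emulated as the truth elevation at a
locus two-thirds into the distal cortical wall, quantized to 0.1 °C. PRFS
phase math is not simulated; the emulation operates at the temperature
level, which is where all downstream analysis lives.

## The predictive controller

Energy per frame is E = δ·P·Δt. The loop activates when the ROI elevation
crosses 1.5 °C, then every dwell time (64 s) projects the asymptote
T∞ from the trailing 32 s observation window and applies the multiplicative
update δ ← min(δ·T_target/T∞, 1), clamped to [0.1, 0.9]. The window
restarts at every δ change so no fit spans a transient.

The asymptote estimator is the one genuinely under-determined component
(the source study's appendix describing it is not available), so two
realizations live behind one interface:

* `"regression"` — smooth, differentiate, regress dT/dt on T; recovers both
  T∞ and τ, exact on noise-free exponentials. But the curvature of a 32 s
  window is barely above the noise floor: the Cramér–Rao bound for T∞ at
  σ = 0.2 °C is ~10 °C, so single-window estimates scatter wildly — no
  estimator realization can beat this, it is a property of the data.
* `"slope"` — the exact mono-exponential identity
  T∞ = mean(T) + τ·mean(dT/dt) with a *configured* τ (default 120 s, the
  order of the simulated intra-cavitary response lag) and the OLS slope as
  the mean derivative. It estimates only a first moment, so it is
  well-conditioned at the ROI noise level, and any τ mismatch biases the
  projection only while the temperature still moves: at steady state the
  slope vanishes and the fixed point T∞ = T_target is exact regardless
  of τ.

The closed loop uses `"slope"`; the controller's stability then does not
hinge on extracting curvature that the data does not contain. One stability
caveat is inherent to this choice: if `tau_model_s` greatly exceeds the
plant's true response time, the projection over-amplifies post-update
transients and the loop can limit-cycle (observable on a first-order test
plant with τ = 30 s and τ_model = 240 s). Underestimating τ is always safe
(sluggish but stable), and the thermal plant's intra-cavitary response
(≥100 s) sits above the 120 s default, so the default loop operates in the
stable regime. On the full
simulated plant this yields ~0.3 °C overshoot, ~0.13 °C steady-state
ripple, and convergence to δ ≈ 0.17 (10.4 W) — against the study's
<1 °C, 0.23 °C average precision and 0.18 (11 W).

## What the synthetic world does and does not establish

The generator emulates: the drilled-lesion geometry at its printed
dimensions, the printed acquisition parameters (1×1×4 mm, 1.6 s, 0.2 °C),
the printed controller settings (δ₀ = 0.3, range 0.1–0.9, 64/32 s,
1.5 °C threshold, 0.5 s pulses, 60 W), and a plant calibrated to two
printed operating points. It does not emulate: nonlinear acoustics or
cavitation, shear waves and true bone acoustics (replaced by the averaging
operator plus shadowing), perfusion, tissue motion, spatially correlated
MR noise, or k-space/phase-reconstruction artifacts. A green closed-loop
test therefore establishes the controller's behaviour on a physically
plausible, operating-point-faithful plant — not the acoustic physics of
bone, which the source study itself treats semi-empirically.

## Numerical details and degenerate inputs

Tissue maps reject grids that cannot resolve the shell (<2 voxels across).
The diffusion step rejects σ < 0.5 voxel. `time_lag()` errors when the
maximum sits at the last sample (run too short) and returns 0 for monotone
decay. The lag fit errors on rank-deficient designs. An empty facet warns
and returns a zero source (the cooling configuration α = 0 is exact). ROI
means exclude NaN and error above 50% masking. All randomness flows from
one seed recorded in the outputs; identical seed and config give
byte-identical logs.
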