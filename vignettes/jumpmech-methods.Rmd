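---
title: "Models and methods behind jumpmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind jumpmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumpmech)
```

jumpmech implements the kinetic and kinematic analysis chain used to
compare long jumpers with a unilateral below-knee amputation (BKA), who
sprint and take off from a carbon-fibre running-specific prosthesis (RSP),
against non-amputee athletes. This vignette documents the models, the
conventions and the numerical choices, in the spirit of a lab methods
section: everything a reader needs to judge what the numbers mean and
where their limits are.

Throughout: SI units; x is anteroposterior (positive in the running
direction), y mediolateral, z vertical (up); forces are ground-on-athlete;
g = 9.81 m/s².

## Signals and events

Raw channels live in `sampled_signal` containers (values, rate, start
time). Filtering uses a recursive digital Butterworth low-pass design.
The default is zero-phase application: a filter of half the stated order
run forward and backward, so a "4th-order, 50 Hz" setting means a
2nd-order design applied twice. Zero phase matters because inverse
dynamics requires forces and kinematics filtered identically and without
lag; a single-pass variant (`zero_phase = FALSE`) is kept for
reproducing phase-lagged processing, since either reading of "recursive
Butterworth" is plausible in older lab pipelines. The end conditions use
odd (point-symmetric) reflection padding sized at ~12 filter time
constants, which preserves DC to ~1e-12; unpadded forward-backward
filtering corrupts signal edges badly enough to bias stance averages.

Typical cut-offs: 50 Hz for force plates (1000 Hz) and marker/CoM
trajectories (250 Hz), 1 Hz for laser-gun speed (100 Hz). These are the
defaults in `lowpass_filter()` callers, not hard-coded.

Stance phases are the maximal intervals where the resultant GRF exceeds
20 N. Two refinements:

* **Sub-sample crossing times.** At 1 kHz one sample is ~1% of a sprint
  contact. The crossing is refined by extrapolating the secant through
  the two nearest *above-threshold* samples to the 20 N level (clamped to
  the bracketing sample interval). Interpolating against the neighbouring
  below-threshold sample instead biases the crossing by up to half a
  sample whenever the plate reads exactly zero outside the contact, which
  is enough to distort between-leg asymmetry by ~0.5 percentage points.
* **Debouncing.** Sub-threshold dips shorter than 5 ms are merged into
  the surrounding contact, so sensor noise chattering at the 20 N line
  cannot split a stance.

Event detection should run on the *unfiltered* resultant: the low-pass
filter's edge ringing (a percent of a multi-kilonewton peak easily exceeds
20 N) dilates detected stances on filtered records. `run_pipeline()` does
this automatically; `takeoff_summary()` exposes `detection_grf` for the
same purpose.

Stance-averaged vertical force (ASF) is the trapezoidal time-average of
the vertical GRF over the refined stance, in bodyweights; impulses are
trapezoidal time-integrals including the partial edge trapezoids between
the refined crossing times and the first/last above-threshold samples.
Note one intrinsic property, not a bug: a 20 N threshold trims the force
tails, so thresholded ASF sits a fraction of a percent above the
full-contact mean, and the trim scales with 1/peak. This is why the
doubled-body-mass invariance of normalized outputs holds only to O(20 N /
peak force).

Laser speed is the central difference of the raw distance trace, smoothed
at 1 Hz. The reported maximum excludes one filter time constant at each
end of the record, where the one-sided difference and the filter end
conditions make the estimate unreliable on noisy data.

## GRF descriptors and asymmetry

Directional asymmetry compares take-off vs non-take-off leg ASF:
`100 (F_to − F_nto) / F_nto`; negative values mean the non-take-off leg
carries more. It is *not* antisymmetric under swapping legs — the
denominator changes, and the property tests document the exact relation
`d(b,a) = −d(a,b)·b/a` rather than pretending otherwise. Fluctuating
asymmetry is the mean absolute directional asymmetry across athletes,
which bounds the absolute directional mean from above.

Stride definitions: stride time is the interval between successive
ipsilateral touchdowns; stride frequency its reciprocal; step frequency
twice that. Contact length is not standardized in the field: jumpmech
defines it as the CoM horizontal displacement during stance when
kinematics are available, with speed × contact time as the documented
fallback (`contact_length_source` records which was used), because
maximum-speed × contact-time is inconsistent with typical printed values
at these speeds.

`spring_mass_reference()` builds the ideal spring-mass half-sine whose
stance impulse balances bodyweight over the full step
(peak = BW·(π/2)·t_step/t_contact), the reference waveform against which
impact-peaked sprint GRFs are compared qualitatively.

## CoM energetics

Energies are `E_pot = mgh`, `E_kin = mv²/2` per axis, summed into total
CoM energy. CoM power is `F_grf · v_com / m`. The gravity convention was
a genuinely open choice and is switchable:

* default (`include_gravity = FALSE`): net CoM work over an interval
  equals the change in *total* CoM energy (gravity's power is exactly
  −dE_pot/dt), which is the bookkeeping the net gain/loss statistics rely
  on and what the work–energy property test asserts;
* `include_gravity = TRUE`: net work equals the kinetic-energy change
  alone. This is the right convention when asking what the contact force
  plus gravity do to the CoM state.

Negative/positive work are sign-split time integrals of the power curve;
the generation/absorption ratio is `100 · W_pos / |W_neg|`, reported `NA`
when there is no absorption.

Collision angles measure how far the GRF deviates from perpendicular to
the CoM velocity: 0° is a smooth redirection, 90° a head-on collision.
Per-sample angles are weighted by `|F||v|` and averaged over the energy
absorption phase (samples with negative GRF power when auto-detected; all
samples of an explicitly supplied absorption interval). The exact
weighting in the original collision literature is not reproduced in the
source material for this pipeline; the `|F||v|`-weighted
deviation-from-perpendicular is adopted and flagged as such.

## Inverse dynamics and the prosthesis model

The link-segment pass is standard bottom-up Newton–Euler: starting at the
segment loaded by the measured GRF at the centre of pressure, each
segment's balance `F_p = m a − m g − F_d` and the moment balance about
the segment CoM (including `I α + ω × I ω`, inertia rotated to world)
yields the proximal joint load, whose negation loads the next segment.
Joint moments are reported in world coordinates and in the distal
segment's frame. Segment angular velocity comes from `skew(ω) = Ṙ Rᵀ`
with central differences on the (identically filtered) rotations;
accelerations are second central differences. The implementation is
validated against an independent free-body oracle (direct per-segment
summation, no recursion) to 1e-6 relative on random 2–4 segment chains —
the two solutions share only the kinematic inputs.

The prosthesis inertia model divides the blade into 9 measured cuboids.
Homogeneous density = measured total mass / summed volume assigns each
cuboid its mass; standard cuboid principal moments `m(a²+b²)/12` plus
rotation and parallel-axis transport assemble the two rigid bodies on
either side of the prosthetic joint (placed between two named cuboids at
the blade's point of highest curvature, from the two edge markers). A
Monte-Carlo mass-cloud oracle (uniform samples in the cuboid union)
confirms composite tensors to 0.5%.

Joint centres: knee and ankle are midpoints of the medial/lateral
condyle/malleolus markers; MTP is the midpoint of the 1st/5th metatarsal
heads. The hip centre regression of the original full-body modelling
software is not recoverable, so a Bell-style inter-ASIS regression
(0.36 d medial, 0.22 d posterior, 0.30 d inferior of the ipsilateral
ASIS) is the documented, configurable default — reports should flag that
hip-level quantities depend on this choice. Anthropometric segment
parameters are likewise supplied by configuration (`read_model()`), with
de-Leva-style proportions recommended, rather than hard-coding any one
table.

Joint power is `P_j = M_j · ω_j` summed over the three planes; joint work
is its sign-split time integral per kilogram of body mass. MTP work
counts only sagittal-plane power and only while the CoP is anterior to
the MTP centre (`mtp_work_filter()`). "Below-knee" work aggregates
ankle + MTP for biological legs and the prosthetic joint for the affected
leg (`below_knee_work()`), an exact bookkeeping identity.

Energy closure is tested on a prescribed-motion single-link stance (a
rigid body pivoting on a fixed contact, GRF constructed as `m a − m g`):
there the joint moment is the only actuator, so its work must equal the
total CoM energy change, and the gravity-inclusive CoM work must equal
the kinetic-energy change. A multi-segment closure *band* (soft-tissue
and model-defect terms) is deliberately not asserted: it would require
forward-dynamics trial generation, and the free-body oracle already pins
the mechanics.

## Take-off state and jump distance

The take-off state is measured from the first 25 ms of flight. The
take-off angle is the angle of the raw CoM displacement vector over that
window — the field's operational definition, which differs from
`atan(v_vert/v_hor)` by the gravity droop of the window (~0.8° at these
speeds). For the *velocities* that propagate the flight parabola, the
vertical component is recovered with the exact parabola inversion
`v₀ = Δz/t + g t/2` rather than the raw `Δz/t`: the raw quotient
underestimates v_vert by g·t/2 ≈ 0.12 m/s, which would bias every jump
distance low by ~0.15 m and is inconsistent with reproducing measured
flight times. The horizontal component is `Δx/t` (exact under drag-free
flight, which is assumed throughout; air drag on a jumper over ~0.9 s is
negligible at the reported precision).

Flight time is the positive root of `h₀ + v_vert t − g t²/2 = 0` and jump
distance is `(CoM_AP − toe_tip) + v_AP · t_flight`, measured from the
most anterior point of the foot or prosthesis during the take-off
contact. Landing technique is outside the model by construction — no
post-flight input exists in the API. Distance is strictly increasing in
v_AP, v_vert and take-off height (property-tested), and matches dense
numerical integration of the flight curve to 1e-9 m.

## The advantage framework

Horizontal velocity loss during the take-off step (signed, negative)
is regressed on touchdown velocity and take-off angle over a non-amputee
reference population by ordinary least squares. Residual SD uses the
n − 3 denominator (three estimated coefficients) — standard unbiased
practice; the alternative n-denominator would shrink the band and
overstate excesses. The natural-variation band is residual mean ± k·SD
with k = 3 (99.7% coverage under normality); a Gaussian-kernel density
with rule-of-thumb bandwidth is returned alongside the fitted normal so
the normality assumption can be inspected. The band boundary is
*inclusive*: an athlete exactly on it has zero excess, the conservative
reading. `residual_excess()` is positive when the athlete's loss is
reduced beyond the band (residual above the upper boundary under the
signed-loss convention) and negative for excessive loss.

Two ΔV routes are exposed because both are legitimate: the direct
reference difference (reference mean loss − athlete loss) and the
residual-threshold excess. `estimate_advantage()` is the exact bilinear
product `t_flight · ΔV` and records which route produced its input. The
reference ΔV is an explicit input rather than recomputed from rounded
summary tables, because differences of independently rounded means do not
reproduce the unrounded difference.

## What the generators emulate — and what they do not

`make_sprint_trial()` builds alternating-leg half-sine vertical GRFs whose
per-step impulse satisfies impulse–momentum exactly: given per-leg ASF,
the aerial time after each step is `t_contact (ASF − 1)`, so mean force
over any full stride is 1 BW by construction (property-tested to 0.5%).
The non-amputee early impact transient is approximated by a Gaussian bump
(centre 15% of contact, width 4%) with the main half-sine rescaled to
preserve the stance impulse — a shape approximation, adequate for testing
detection and averaging, not a validated two-mass model. The AP channel
is a zero-net braking/propulsion full sine (amplitude 0.3 BW). Plate
noise defaults to 2 N white; laser distance noise to 3 mm white at
100 Hz, with the speed profile a tanh ramp (τ = 2 s) saturating at the
requested top speed over a 12 s record — values chosen once as realistic
for piezoelectric plates and sports laser guns.

`make_jump_trial()` scales half-sine vertical and (pure braking) AP
forces so their impulses produce exactly the requested velocity changes,
integrates them in closed form for the stance CoM path, and appends the
exact flight parabola; the ground-truth distance follows in closed form.
Defaults mirror the best BKA athlete's take-off step; presets cover the
three BKA athletes and the non-amputee mean.

`make_reference_population()` draws touchdown velocity and angle
uniformly (defaults 8.8–10.8 m/s, 16–22°, spanning laboratory and
championship-level approaches) and losses from
`1.22 − 0.15 v_td − 0.05 α + N(0, 0.1)` m/s — coefficients chosen once so
the population centres near a −1.1 m/s loss at 9.4 m/s / 18°, with loss
growing with speed and angle as the field reports.

Passing round-trip tests on these trials demonstrates that the pipeline
recovers what it is pointed at, with documented tolerances (distance
0.02 m, velocity loss 0.01 m/s, ASF 1%, step frequency 0.01 Hz, top
speed 1% under default noise). It does **not** demonstrate robustness to
what real data add: marker soft-tissue artefact and gaps, plate drift and
cross-talk, imperfect CoM models, impact transients that are not Gaussian
bumps, or athletes whose GRF shapes depart from half-sines. Problem sizes
in the shipped tests (6-step sprints, ≤4-segment chains, 1e5-point
residual samples, 1e6-point Monte-Carlo clouds) were chosen as the
smallest that pin each property to its stated tolerance.

## Degenerate inputs and tie-breaks

* All-zero GRF: no stances, an empty list, not an error.
* Zero braking impulse: the vertical/braking impulse ratio is reported
  `NA` with `ratio_flag = "no_braking"` rather than infinity.
* No absorption phase: collision angle and work ratio are `NA`.
* `flight_time(0, v ≤ 0)` is 0; negative heights are rejected.
* Perfect regression fits (zero residual SD) collapse the band to a
  point and skip the density diagnostics.
* Missing files, channels, markers and rate mismatches raise classed
  errors (`missing_channel`, `missing_marker`, `rate_mismatch`, …) naming
  the offending item.

## Known limitations

* The pipeline analyzes *given* CoM and marker trajectories; inverse
  kinematics, marker labelling and gap-filling are upstream of its scope.
* Hip-level joint kinetics inherit the configurable hip-centre
  regression; prosthesis power inherits the two-rigid-body blade model
  (a unified deformable-segment treatment would differ).
* Collision-angle magnitudes depend on the adopted weighting; only the
  formula's self-consistency is testable without raw trial data.
* The advantage framework conditions on touchdown velocity and take-off
  angle only, and assumes BKA and non-amputee athletes share the
  loss-vs-approach relationship; that assumption is an open scientific
  question, not something this package can settle.
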