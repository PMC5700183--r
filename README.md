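# jumpmech

Biomechanics of maximum-speed sprinting and the long-jump take-off, for
comparing athletes with a unilateral below-knee amputation (BKA) who jump
from a running-specific prosthesis (RSP) against non-amputee long jumpers.
The package is aimed at sports-biomechanics researchers and movement
scientists who work from force-plate records, motion-capture CoM
trajectories and laser-gun position traces, and who need a tested,
scriptable pipeline rather than one-off lab code.

## What it computes

**Ground reaction forces and asymmetry.** Stance phases are detected with a
20 N threshold on the resultant GRF (sub-sample refined), and each stance
yields the stance-averaged vertical support force (ASF, in bodyweights),
vertical and net horizontal impulses (BW·s), contact time and peak force.
Between-leg asymmetry of ASF is

    Asymmetry (%) = 100 · (F_takeoff − F_non_takeoff) / F_non_takeoff

with the signed (directional) version and its absolute (fluctuating)
version across athletes.

**CoM energetics.** Potential energy `m g h`, kinetic energies
`m v²/2` per axis, CoM work from the GRF power `F · v / m` split into
absorption (negative) and generation (positive), and magnitude-weighted
collision angles between the GRF and CoM-velocity vectors during energy
absorption.

**Inverse dynamics.** A bottom-up Newton–Euler pass over a configurable
link-segment chain, with joint moments expressed in the distal segment
frame, joint power `P_j = M_j · ω_j` summed over the three planes, and
mass-normalized joint work. The prosthesis is modelled as two rigid bodies
assembled from 9 measured cuboids of homogeneous density (parallel-axis
composite inertia), joined at the blade's point of highest curvature. The
metatarsophalangeal joint contributes sagittal-plane power only while the
centre of pressure is anterior to its joint centre.

**Jump distance.** Drag-free ballistic flight from the take-off state:

    d = (CoM_AP − toe_tip) + v_AP · t_flight,
    t_flight = (v_vert + sqrt(v_vert² + 2 g h₀)) / g

with the take-off angle measured from the CoM displacement over the first
25 ms of flight.

**Take-off performance advantage.** Horizontal velocity loss during the
take-off step is regressed on touchdown velocity and take-off angle over a
non-amputee reference population; residuals beyond the inclusive
mean ± 3 SD band count as artificially induced, and a velocity-loss
difference ΔV converts to a distance advantage via
`advantage = t_flight · ΔV` (0.884 s flight time for the reference
take-off conditions).

**Synthetic trials.** `make_sprint_trial()`, `make_jump_trial()` and
`make_reference_population()` generate GRF records, CoM trajectories,
laser traces and regression populations with closed-form ground truth, so
the whole pipeline is testable without laboratory data; presets mirror the
per-athlete study conditions.

## Worked example

```r
library(jumpmech)

# best-BKA-athlete take-off step, regenerated synthetically
j <- do.call(make_jump_trial, c(jump_presets()$P1, list(seed = 1)))
s <- takeoff_summary(j$grf, j$com_ap, j$com_vert, j$bodyweight,
                     j$body_mass, j$toe_tip_ap)
round(c(distance = s$distance, v_loss = s$v_loss_hor,
        angle = s$takeoff_angle, contact_ms = 1000 * s$contact_time), 3)
#>   distance     v_loss      angle contact_ms
#>      7.971     -0.639     18.347    117.716

# the advantage of losing 0.55 m/s less than the reference at this take-off
estimate_advantage(0.55, flight_time(1.18, 3.00))
#> <advantage_estimate> 0.49 m (= 0.884 s x 0.55 m/s, direct_reference)

# sprint asymmetry of the same athlete
sp <- do.call(make_sprint_trial, c(sprint_presets()$P1, list(seed = 1)))
asf <- sapply(names(sp$forces), function(l) {
  sig <- sp$forces[[l]]
  mean(sapply(detect_stances(sig, 20), stance_average_force,
              grf_vertical = sig, bodyweight = sp$bodyweight))
})
directional_asymmetry(asf[["takeoff"]], asf[["non_takeoff"]])
#> [1] -9.159595
```

The jump distance (7.97 m) is the ballistic-flight distance from toe tip
to the CoM's ground intersection; the negative velocity loss (−0.64 m/s)
is the horizontal CoM velocity change over the stance; the negative
asymmetry (−9.2%) means the take-off (affected) leg applies less support
force than the unaffected leg.

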