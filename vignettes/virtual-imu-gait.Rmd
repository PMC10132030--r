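---
title: "Virtual IMU synthesis and threshold-based gait event detection"
author: "imugait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual IMU synthesis and threshold-based gait event detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

## The problem

Wearable inertial measurement units (IMUs) are routinely used to segment
walking into gait phases — stance and swing, delimited by initial contact
(IC), mid stance (MSt), toe off (TO) and mid swing (MSw).  How well a
rule-based detector performs depends on where the sensor sits on the limb,
how its thresholds are parameterised, and which signals it consumes.
Measuring hundreds of candidate positions on real patients is infeasible;
`imugait` instead *simulates* the sensors: given rigid-body pose
trajectories of the lower-limb segments (from optical motion capture and
inverse kinematics, or from the bundled synthetic generator), it
synthesises the accelerometer and gyroscope signal every candidate sensor
would have measured, runs the detectors, and maps the timing error over
the whole placement grid.

## The sensor model

Each virtual sensor is welded to a segment at offset $\vec{o}$ (segment
frame) with a mount rotation $M$.  With the segment's global-to-local
rotation $Q(t)$ and origin $\vec{p}(t)$, the sensor's world position is
$\vec{k}(t) = \vec{p}(t) + Q^{\mathsf T}(t)\,\vec{o}$ and its
global-to-sensor rotation is $Q_s(t) = M\,Q(t)$.  The accelerometer is
additive:

$$\vec{a}(t) \;=\; \vec{a}_d(t) + \vec{a}_g(t), \qquad
\vec{a}_d(t) = Q_s(t)\,\frac{d^2 \vec{k}}{dt^2}, \qquad
\vec{a}_g(t) = Q_s(t)\,\vec{\jmath}\; g,$$

with $\vec{\jmath} = (0,1,0)$ the global vertical and $g = 9.81$ m/s².
$\lVert \vec{a}_g \rVert = g$ at every sample, which the tests assert to
numerical precision.  The second derivative is a central difference
(order 2; one-sided at the edges); its truncation error contracts by a
factor ≈ 4 when the rate doubles, which is also asserted.  The gyroscope
is obtained from the skew-symmetric matrix
$S(t) = Q_s \,\dot{Q}_s^{\mathsf T}$, whose off-diagonal entries are the
sensor-frame angular-velocity components.  (A naive "derivative of the
orientation" is not a vector; the skew extraction is the standard
rigid-body construction and reduces to the signed sagittal rate for
planar motion.)

Signals are conditioned the way the detectors expect: a zero-phase
second-order Butterworth low-pass (17 Hz acceleration, 15 Hz gyroscope)
followed by a Savitzky–Golay smoother (order 5, window 35 samples at
100 Hz).  Zero-phase (forward–backward) filtering is the default because
the entire analysis is offline and compares event *times*; a causal mode
exists behind `filter_spec(zero_phase = FALSE)`.  Filtering applies to
the summed acceleration, not its components — the gravity share is always
computed from unfiltered orientations.

## Placement grids

Leg segments carry a cylindrical surrogate with 12 rings × 16 slots
(192 sensors per segment; S1 is ventral, azimuth 0, numbering increasing
laterally; R1 is proximal).  Each shoe carries 96 sensors on three
outline rings.  The printed per-ring shoe sizes in the source material
(36 + 36 + 25 = 97) contradict the stated totals of 96 per shoe and 960
overall; the default profile here is (36, 35, 25), honouring the totals,
and is configurable.  Mount convention: sensor x = outward surface
normal, y = limb axis (proximal), z completes the right-handed triad.  A
direct consequence is that a 180° azimuth shift inverts the sensor z axis
— dorsal sensors measure the *negated* sagittal angular velocity.

## Detection rules

All rules share one peak detector: local extrema gated by a minimum
height $\theta_h$ and a minimum inter-peak distance $\theta_d$ (conflicts
keep the more extreme peak; ties the earlier).  $\theta_h$ is trained,
not hand-set: candidate peaks are collected without a height gate and
$\theta_h = \bar h - |\bar h|\cdot f$ (positive polarity) or
$\bar h + |\bar h|\cdot f$ (negative), with fraction $f = 0.15$ for
acceleration and $0.25$ for gyroscope signals.  Wait times between
events: 600 ms (1-phase), 300 ms (2-phase), 150 ms (4-phase).

* **A1 (acceleration only, 1-phase):** IC at qualifying positive
  $a_y$ peaks, $\theta_d = 600$ ms.
* **A2 IC:** a strict positive-to-negative sign change of $\omega_z$
  followed by a qualifying $a_y$ peak within [0, 50] ms; the event
  timestamp is the accelerometer peak.
* **A2 TO:** a negative $a_y$ peak followed by a negative $\omega_z$ peak
  within 50 ms; timestamp = gyro trough.
* **A2 MSw:** a positive ipsilateral $\omega_z$ peak while the
  contralateral $a_y$ is locally quiet; **A2 MSt:** mirrored (positive
  contralateral gyro peak, ipsilateral quiet gate), assigned to the
  ipsilateral timeline.

"Locally quiet" is operationalised as: the maximum absolute second-order
central difference inside the 50 ms window centred on the candidate must
not exceed the 75th quantile of that statistic over consecutive 50 ms
segments of the training data.  A cyclic state machine (IC → MSt → TO →
MSw) enforces event order with event-specific wait anchors (IC waits on
the previous event, MSw on the last IC, MSt on the last TO); out-of-order
candidates are skipped, not reordered, so missing peaks surface as
missing events and can push nMAE beyond 100 % — a failure mode the
evaluation deliberately preserves.

**Gyro-sign calibration.** Because dorsal placements invert $\omega_z$,
every *position-dependent* parameterisation (A1, A2a, A2b) trains one
extra per-sensor parameter: the sign making the dominant angular-velocity
extremum positive.  This is treated as part of "position-adapted
parameters"; the position-independent variant A2c keeps a fixed +1 sign,
which is exactly why its rotatory error spread is large — medial/lateral
and dorsal placements degrade when the parameterisation may not depend on
position.  This was a genuinely open design point: without it, no
fixed-sign rule set can work on both the ventral and dorsal meridians.

## Evaluation

Reference ICs and TOs come from the vertical GRF: stance is the set of
strictly loaded samples, IC the first loaded sample of each rising edge,
TO the first unloaded one.  Mid-phase references (MSt, MSw) are not
derivable from a vertical GRF and are taken from scenario ground truth
(standing in for manual labels).  Timing error matches each reference
event to the nearest detected event of its kind (reuse permitted — an
order-free rule that preserves the >100 % nMAE behaviour under missed or
spurious peaks), averages the absolute differences (MAE), and normalises
by the mean reference stride duration (nMAE, %).

Cross-validation strategies:

* **A2a / A1** — per participant *and* per sensor, 5-fold over contiguous
  stride blocks (80/20), fold results averaged.
* **A2b** — leave-one-participant-out; per-sensor thresholds averaged over
  the training participants.  The held-out participant is evaluated on
  interior strides (first/last stride carry boundary transients).
* **A2c** — as A2a, but thresholds averaged across all sensors of a
  segment instance before testing.

The rotatory/translatory decomposition summarises an A2c report over one
ring (all 16 slots; a uniaxial rotation around the limb) and one slot
(all 12 rings; a uniaxial translation along the limb).  On a rigid
segment the gyroscope is *exactly* invariant under axial translation, so
the translatory nMAE spread is zero to numerical precision — asserted at
1e-10 in the acceptance suite.

Agreement metrics for measured-versus-synthesised series pool
per-participant Pearson correlations through Fisher's z (mean and 95 %
normal-theory CI on the z scale, back-transformed).  MAD is the median
absolute deviation *between* the two series (`median(|x_m - x_s|)`; the
centred variant is an option), and nMAD normalises by the peak-to-peak
range of the measured series — the normaliser was unspecified in the
source material, so it is a documented, configurable choice.

## The synthetic gait generator

`gait_scenario()` / `generate_scenario()` define the package's stated
world: planar sagittal kinematics of six segments over `n_strides`
strides at 100 Hz, with exact ground-truth events and a synthetic GRF.

* **Anchored angular-rate profile.** The canonical sagittal rate profile
  is built from shape knots in stride phase — zero crossing (+→−) at IC,
  dominant trough at TO, dominant positive peak at mid swing — balanced
  to zero mean (so the integrated angle is periodic) and projected onto
  14 Fourier harmonics (smooth, analytically integrable).  Segment angles
  are scaled copies of the integrated profile (defaults: 0.32 / 0.55 /
  0.75 rad peak-to-peak for upper leg / lower leg / shoe).  Anchoring the
  *segment rate* rather than joint angles is deliberate: the detectors
  consume exactly this morphology, so ground-truth events are correct by
  construction rather than by calibration.
* **Impact and push-off transients.** Each IC adds a Gaussian hip dip
  (depth 8.5 cm, width 55 ms, centred 20 ms after IC) and each TO a
  matching rise 20 ms before TO.  The second derivative of a Gaussian dip
  is a low-frequency Ricker wavelet — a positive accelerometer peak that
  survives the 17 Hz + Savitzky–Golay chain (a narrow pulse would not:
  the smoother's effective cut-off is ≈ 5 Hz) while velocity and position
  stay bounded per event.
* **Phase-locked jitter.** Stride boundaries are a per-side metronome
  plus independent boundary noise (sd `jitter_sd/√2`, giving
  stride-duration sd ≈ `jitter_sd`), not a random walk: treadmill gait is
  belt-locked, and a random walk would let the two sides drift apart and
  defeat the bipedal MSt/MSw gates late in long trials.  A per-side
  asymmetry multiplier emulates hemiparetic timing.
* **Noise.** `noise_sd` adds 6 Hz low-passed Gaussian angle noise (rad)
  to every segment.  Under the default world, held-out nMAE rises
  monotonically over noise sd {0, 0.005, 0.02}.

What the generator does *not* emulate: soft-tissue artefact, sensor
noise/bias/saturation, deformable shoe mechanics, out-of-plane rotation,
and the inter-subject variability of real patients.  A green test
therefore establishes that the algorithms and metrics are implemented
correctly and behave as documented on controllable kinematics — not that
any particular clinical error level is reproduced.

## Numerical choices and degenerate inputs

Rotation matrices off orthonormality by less than 1e-4 are re-projected
onto SO(3) (SVD polar factor); worse violations and improper matrices are
rejected.  Resampling interpolates positions linearly and rotations
geodesically.  The stance fraction must lie in [0.2, 0.8] for the
profile anchors to stay ordered.  Pairing windows are closed at zero
("followed by within 50 ms" admits simultaneity).  Every error is a
classed condition; the CLI maps each family to a distinct exit code.

## Worked example

```{r example, eval = FALSE}
scn <- generate_scenario(gait_scenario(n_strides = 20, seed = 11))
pl <- Filter(function(p) p$ring == 6 && p$slot == 1,
             build_leg_grid("lower_leg", 0.43, 0.055)$placements)[[1]]
imu_l <- scenario_imu(scn, pl, "left")
imu_r <- scenario_imu(scn, pl, "right")
prm <- detection_params(4)
tr <- function(i, c) train_detection_params(i$a[, 2], i$omega[, 3], i$t, prm,
                                            a_y_contra = c$a[, 2],
                                            omega_z_contra = c$omega[, 3])
ev <- run_phase_model(imu_l, imu_r, "A2", tr(imu_l, imu_r), tr(imu_r, imu_l))
ref <- extract_reference_events(scn$grf$left,
                                ground_truth = scn$ground_truth$left)
timing_error(ev$left, ref, "IC",
             window = c(1.2, 22.8))[c("MAE", "nMAE")]
```

On the default noise-free world this reports an IC MAE of ~0.02 s
(nMAE ≈ 1.7 %): the impact peak sits 20 ms after the ground-truth contact
by construction, so the detector is expected to land there.

## Known limitations

Detection quality on medial/lateral meridians is intrinsically poor (the
sagittal rate projects onto the sensor z axis with cos ψ); this is a
property of the physics, not a defect, and mirrors the error patterns the
evaluation is designed to expose.  The A2b strategy assumes exchangeable
participants; with strongly heterogeneous scenarios its averaged
thresholds can miss events entirely, surfacing as `undefined` rows in
the report rather than being dropped.
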