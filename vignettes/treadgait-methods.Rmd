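---
title: "Simulating treadmill versus overground gait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating treadmill versus overground gait: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

treadgait asks a narrow physical question: when the same walker, driven by
the same gait controller, walks overground and on a treadmill, which purely
mechanical properties of the treadmill — the maximum force its belt drive
can exert, and how often its speed controller updates — change the joint
kinematics, and by how much?  The package answers it with a fully
deterministic simulation pipeline: a planar biped, a belt with a realistic
speed-control loop, a reference-tracking walking controller, and an
analysis stage that measures per-joint differences over the normalized
gait cycle.

## The biped

The body is a sagittal-plane, seven-segment rigid-body chain: a combined
head-arms-trunk (HAT) segment and two legs of thigh, shank and foot, all
hinged at a common pelvis point (the root).  The generalized coordinates
are the root position (x forward, z up), trunk pitch, and hip, knee and
ankle flexion per leg — 9 degrees of freedom, with the root unactuated: no
external agent can push the model forward or hold it upright except
through joint torques, contact and the explicitly declared stabilizer
wrench described below.

Segment masses are fixed fractions of body mass (HAT 0.678, thigh 0.100,
shank 0.0465, foot 0.0145 per side) and lengths fixed fractions of
standing height (thigh 0.245 H, shank 0.246 H, foot 0.152 H, ankle height
0.039 H), in the style of Winter's anthropometric tables; inertias use
slender-rod formulas (box for the foot).  Scaling `total_mass` scales every
segment proportionally, which is how the 47/63/79/95 kg subject family is
produced from one geometry.

The equations of motion `M(q) q̈ = Q` are assembled from point Jacobians
(mass matrix from segment CoM Jacobians plus rotational inertias;
velocity-product and gravity terms likewise) and integrated with
semi-implicit Euler at `dt = 5e-4 s`.  The compiled core (RcppArmadillo)
runs the whole closed-loop trial; the exported R functions
(`step_dynamics()`, `mass_matrix()`, `contact_forces()`, `total_energy()`)
call the same kernels one step at a time.  Integrator quality is bounded
empirically by the conservation checks in the test suite: a pinned passive
leg swing at `dt = 1e-4` drifts less than 1% in total energy over 2 s.

### Contact

Each foot carries a heel and a toe point.  Penetration `δ` below the
surface produces a Hunt-Crossley-style normal force
`fN = kn δ (1 + cn δ̇)` clipped at zero, and regularized Coulomb friction
`fT = -μ fN tanh(v_rel / v_ε)` with `v_rel` the point's horizontal
velocity relative to the surface material.  Defaults: `cn = 0.5 s/m`,
`v_ε = 0.05 m/s`, `μ = 0.9`.

The normal stiffness default scales with subject weight
(`kn = 3e4 N/m × mass/63`), keeping the static two-point penetration depth
near 1 cm for every subject.  This is penalty-contact conditioning, not
shoe physics: with a fixed `kn`, light and heavy subjects bounce on
different contact resonances and their gaits differ for reasons unrelated
to the treadmill, which is exactly the confound the mass sweep must avoid.
An explicit `contact_kn` overrides the scaling.

Joint ranges are enforced by stiff one-sided torsional springs
(500 N·m/rad plus light damping beyond the limit) rather than hard
constraints, keeping the integrator simple and smooth.

## The treadmill

The belt is a single translating body (`m_belt = 10 kg` by default) on a
prismatic joint.  A PD controller regulates its speed: at every update
instant (period `1/f_ctrl`) it recomputes
`F = clip(Kp (v* - v_belt) - Kd a_belt, ±Fmax)` and holds that force until
the next update (zero-order hold) — the two experimental knobs are
exactly `Fmax`, the proxy for drive power, and `f_ctrl`, the control
frequency.  The belt acceleration estimate uses the last two
controller-update speed samples, so the controller is causal with no extra
state.  Deck friction `μ_deck (m_belt g + N_load) tanh(v_belt / v_ε)`
opposes belt motion (`μ_deck = 0.05`).

Gains are auto-tuned as `Kp = m_belt f_ctrl` — half the discrete stability
bound `Kp < 2 m_belt f_ctrl` for ZOH proportional control of a pure
inertia — and `Kd = 0.1 Kp / f_ctrl`.  The tuning deliberately scales with
the control frequency: a slow controller must be soft to remain stable,
which is precisely why low control frequencies cannot hold belt speed
against foot loads.  `belt_response_oracle()` provides an exact discrete
recursion of this loop, independent of the physics engine, against which
the integrator is verified to ~1e-13 m/s.

The *ideal* treadmill is a kinematic body: its speed is exactly `v*`
regardless of load.  Its co-moving frame is inertial, so walking on it is
physically identical to overground walking — the pipeline's central
sanity property.  The implementation simulates it honestly as a moving
surface (the surface velocity enters only the friction law), so the
identity is a genuine numerical outcome, not a change of variables.

The belt speed is measured along the running direction; a walker facing +x
stands on surface material moving at `-v_belt`.  Tangential foot reactions
load the belt with braking loads negative, so early-stance braking slows
the belt and push-off speeds it up.

## The controller

The paper-scale controller here is deliberately not learned.  A
reference-tracking policy returns the reference joint angles at the
current gait phase (clock-driven, `φ = t/T mod 1`), a per-joint PD law
turns targets into torques (`τ = kp e - kd θ̇`, clipped at `τ_max`), and a
root stabilizer applies a restoring pitch torque and vertical force toward
the reference root trajectory.  The stabilizer never applies horizontal
force: belt-induced horizontal perturbations must propagate to the
kinematics through the legs, preserving the causal path the experiment
studies.  The policy sits behind a small interface (phase in, targets
out), so a learned policy could be substituted without touching the
pipeline.

Three controller design choices deserve explanation:

* **Gains.** Defaults are hip/knee 5000/60, ankle 800/15 N·m/rad,
  `τ_max = 800 N·m`, pitch 8000/800, height 2000/2500, specified for the
  63 kg reference subject.  They are deliberately stiff: a pure PD tracker
  has no feedforward and no learned anticipation, so softer gains lag the
  moving reference by tens of degrees and fall within seconds.  The height
  stabilizer is the opposite — weak stiffness, strong damping — because
  damping contributes no mean force over a periodic cycle: the legs, not
  the stabilizer, carry body weight (the test suite checks that the
  cycle-averaged vertical ground reaction force equals body weight within
  5%).
* **Phase lead.** Joint targets are taken 0.03 s ahead of the current
  phase.  This is classical lag compensation for PD tracking of a moving
  target; a trained policy learns the equivalent anticipation implicitly.
* **Mass scaling.** All gains and the torque limit scale with body mass.
  The study's experimental logic trains one controller per subject mass so
  that every subject is equally competent; fixed gains would make the
  light subject the most perturbed one for reasons of controller tuning,
  not treadmill physics.

Controller quality is gated, not assumed: the default configuration must
hold a mean motion-imitation reward above 0.9 over a ten-cycle overground
trial.

### Imitation rewards

Tracking quality is scored by the standard motion-imitation terms:
pose `rp = exp[-2 Σ (θ̂ - θ)²]`, velocity `rv = exp[-0.04 Σ (θ̂̇ - θ̇)²]`,
end-effector `re = exp[-40 Σ ||p̂e - pe||²]` over the two foot centres, and
centre of mass `rc = exp[-30 ||p̂c - pc||²]`, all positions relative to the
root in a non-rotating frame, combined as
`r = 0.65 rp + 0.1 rv + 0.15 re + 0.1 rc`.  Each term lies in (0, 1] and
is 1 only at an exact match.  In the planar model, angle differences are
plain scalars (the 3-D analogue uses quaternion differences) and the
end-effectors are the feet only.

## The synthetic reference gait

Measured motion capture is replaced by a generator that produces one
canonical, periodic, kinematically consistent gait cycle per speed.

* Hip and knee flexion come from a compact Fourier description
  (harmonics 0–5) of normative sagittal gait: a first-harmonic-dominated
  hip, a knee with stance-loading and swing-flexion bumps.
* The cadence model `T(v) = clamp(1.12 - 0.25 (v - 1.05), 0.75, 1.45) s`
  reproduces normative stride lengths (0.77 m at 0.63 m/s, 1.18 m at
  1.05 m/s, 1.40 m at 1.33 m/s); running uses a constant `T = 0.70 s`.
  The hip amplitude is solved (by root finding) so the stride implied by
  the stance-foot geometry equals `v·T` exactly.
* The ankle is *scheduled* from foot attitude rather than tracked
  directly: flat foot during stance (`ankle = knee - hip`), 10° toe-up
  through terminal swing for heel-first contact, and the template's own
  plantarflexion bump at push-off in between.  A strike-preparation knee
  term (+22° bump at 91% cycle) keeps the reaching leg short through
  terminal swing — a straight reaching leg is geometrically longer than
  the stance support and would strike early.  Both scheduled curves are
  band-limited (8 harmonics, raised-cosine taper) so the stored angles are
  analytic Fourier series and the stored velocities are their exact
  derivatives.
* The pelvis trajectory is derived from the joint curves: height from a
  smooth soft-minimum over the four heel/toe points (lowered by the 1 cm
  static contact penetration, then band-limited to 4 harmonics so weight
  transfer descends gently), and forward velocity from phase-scheduled
  stance weights (right stance 0–60%, left 50–110%, smootherstep
  hand-over) cancelling the stance foot's velocity relative to the
  pelvis.  A uniform correction enforces the mean forward speed exactly.

The phase grid spans [0, 1] *inclusive*, the last row duplicating phase 0
by periodicity; this makes the periodicity diagnostic directly computable
on stored CSV files and linear interpolation near phase 1 exact.
`check_motion()` verifies the three contract properties of any motion —
finite-difference consistency of the stored velocities (< 1e-3 rad/s at
1000 samples), mean forward speed within 1%, periodicity gap < 1e-9 rad.

What the generator does *not* emulate: subject-specific asymmetries and
variability (cycles are exactly periodic and left-right symmetric), pelvic
list and transverse-plane motion (the model is planar), arm swing, and
running flight-phase dynamics (the running template reuses the stance-led
construction; running trials are included for completeness, not fidelity).
Passing tests therefore demonstrate the *mechanism* — belt-speed
fluctuation reshaping ground reaction forces and kinematics — under a
clean, repeatable gait, not the reproduction of any specific subject's
angles.

## Trials and analysis

`run_trial()` initializes the model in the reference pose at phase 0, with
the root velocity matched to the environment: walking forward at the
reference speed overground, stationary over a belt already running at its
target on a treadmill.  Default duration is `transient + 6.6` gait cycles;
the first 3 cycles are discarded and at least five steady cycles retained.

Heel strikes are rising 20 N crossings of the right foot's vertical GRF.
Trial segmentation additionally requires 90% loading over the following
quarter cycle (`min_stance`) and spaces events by at least half a cycle
(`debounce = 0.5 T`, since same-foot strikes are one cycle apart): penalty
contact produces brief unloads at weight transfer and occasional pre-strike
grazes that the bare threshold rule would count as strikes, splitting
cycles.  Each inter-strike interval is resampled to 101 points (0–100% of
the gait cycle), retained cycles are averaged pointwise, and treadmill
minus overground mean curves give the per-joint maximum and RMS
differences in degrees.  A fall — root below half standing hip height or
trunk pitch beyond 60° — propagates as a categorical outcome with the
post-fall cycles excluded.

`run_sweep()` runs the factorial of belt force, control frequency, mass
and speed against shared overground baselines, one deterministic trial per
condition, and returns a long tibble (`mass_kg, speed_mps, fmax_N,
fctrl_Hz, joint, max_diff_deg, rms_diff_deg, fell`); `Fmax = Inf` denotes
the ideal belt.

### Numerical behaviour of the frame identity

Overground and ideal-treadmill trials agree per step to better than
1e-6 rad over the first three-quarters of a second.  Beyond the first heel
strike, machine-rounding differences between the two frames (the surface
speed enters the friction arithmetic) are amplified by the stiff contact
events into a small bounded discrepancy (~1e-3 rad) that does not grow —
the closed loop is contracting — so the scientific identity, the
cycle-mean curves, agrees to well inside the 0.1° acceptance band over
full trials at every speed and mass.  The same consideration shapes the
low-level Galilean invariance test: it stays in the sliding-friction
regime, because across a stick transition the steep `tanh` regularization
chatters at machine precision and per-step comparisons lose meaning.

## Problem sizes

Default analyses use 12–15 s trials (about 9–10 gait cycles at walking
speeds) at `dt = 5e-4 s`, 1001-sample reference grids, and the 5 × 5 belt
condition grid at 63 kg and 1.05 m/s; the conservation checks run 2 s at
`dt = 1e-4` and the belt oracle comparison 2 s at `dt = 1e-5`.  The full
default sweep completes in well under a minute on one core.

## Known limitations

* Planar dynamics: no pelvic list/rotation, no arms, no mediolateral
  balance; the belt acts along the direction of travel only.
* The deterministic tracker is more compliant than a trained policy at
  perturbation rejection; absolute difference magnitudes are therefore
  smaller than what a learned controller exhibits, and condition trends
  (directions), not absolute degrees, are the meaningful output.
* Falls are rarer than with a learned policy for the same reason: the
  stabilizer cannot be knocked over by moderate belt excursions, and the
  fall pathway is exercised by disabling it (`stabilizer = FALSE`).
* Belt elasticity, deck vibration and motor electrical dynamics are
  deliberately out of scope.
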