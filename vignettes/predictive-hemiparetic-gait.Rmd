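---
title: "Predictive simulation of hemiparetic gait: model, transcription, and solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive simulation of hemiparetic gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Hemiparesis — unilateral muscle weakness, common after stroke and in
cerebral palsy — presents clinically together with many other impairments,
which makes it hard to attribute any particular gait deviation to the
weakness itself. Predictive musculoskeletal simulation isolates the effect:
one builds a musculoskeletal model, reduces the peak isometric strength of
every muscle on one limb by a fixed fraction, and solves for the periodic
gait that minimizes an assumed neural objective at a prescribed speed. The
emergent step-length and step-time asymmetries and the metabolic cost of
transport (COT) are then properties of the *optimal* adaptation to weakness,
not of confounded co-impairments.

`hemigait` implements this analysis end to end in R: a sagittal-plane
musculoskeletal model, direct-collocation transcription of the periodic
optimal-control problem, a solver for the resulting nonlinear program,
smooth step-length/step-time symmetry objectives for the symmetry-enforcement
experiment, and the post-hoc spatiotemporal and energetic analyses.

# The musculoskeletal model

The skeleton is planar with 11 degrees of freedom: pelvis translation (x
forward, y up) and tilt, and pin joints at each hip, knee, ankle, and toe
(metatarsophalangeal) joint. The torso (head–arms–trunk) is rigidly fused to
the pelvis — there is no lumbar joint — so the model cannot hyperextend the
hip the way humans do; the pelvis/trunk segment rides tilted slightly
forward instead. Hip and knee flexion, ankle dorsiflexion, and toe extension
are positive.

Anthropometry is a package-owned standard adult set (~75 kg, ~1.75 m) stored
in `inst/extdata/planar_walker.yaml`; segment masses follow conventional
proportional tables, with the toe segments given a slightly generous
rotational inertia (1e-3 kg m^2) because the toe joint is otherwise the
stiffest mode of the system by far and dominates the conditioning of the
transcribed problem. Every acceptance property of the package is stated
relative to this parameter set, not to any external model.

Each limb is actuated by 12 Hill-type muscle–tendon units (24 total):
hamstrings (long/short head), gluteus maximus, psoas, rectus femoris, vastus
intermedius, gastrocnemius, soleus, tibialis anterior, extensor hallucis
longus, flexor digitorum longus, and flexor digitorum brevis. Peak isometric
strengths are the published 12-muscle table; optimal fiber lengths, tendon
slack lengths, and pennation angles are plausible published-range values
stored in the same config. Muscle geometry uses **constant moment arms** per
muscle–joint pair — the simplest choice that keeps the muscle-tendon length
an exact affine function of the joint angles (so the moment arm equals minus
the length derivative by construction). This is a deliberate simplification
relative to path-based geometry; the moment-arm table in the config is the
place to refine it.

The muscle model is the smooth Hill-type formulation used throughout
gradient-based gait optimization: a sum-of-Gaussians active force–length
curve peaking at optimal fiber length, an exponential passive curve, a
logarithmic force–velocity curve (~1 at zero velocity), and an exponential
tendon force–strain curve crossing zero just above slack length. Tendon
compliance is handled in **implicit form**: the normalized tendon force is a
state, its time derivative a control, and the fiber–tendon force balance is
enforced as an algebraic residual at every collocation node. Activation
follows first-order dynamics with activation/deactivation time constants of
15/60 ms, blended smoothly (tanh) so the rate is differentiable.

Unilateral weakness is applied with `apply_weakness(model, fraction)`:
every left-limb muscle's peak isometric strength is scaled by `1 - fraction`
while muscle masses — used by the energetics models — stay fixed (weakness
without atrophy).

## Foot–ground contact

Five contact spheres per foot (four on the hindfoot segment, one on the
toes) interact with the ground through a smoothed Hunt–Crossley normal force
`F = k d^{3/2} (1 + 1.5 c v)` with tanh-smoothed Coulomb friction. The
penetration depth is smoothed with a softplus of width 4 mm: near the ground
this behaves like the usual smoothing, but the force tail decays
*exponentially* with clearance, so a sphere 10 cm above the ground feels
essentially nothing while a sphere within a centimetre or two feels a small,
smoothly growing attraction gradient. That tail is what lets a
gradient-based solver find its way back into contact instead of stalling in
the "airborne dead zone" where contact forces and all their derivatives
vanish. Stiffness (3e5 N/m^1.5), dissipation (2 s/m), and friction (0.8)
were chosen once so that the tracked symmetric gait produces vertical GRF
peaks near 1.1 body weight with sub-centimetre penetration, and then frozen
in the config. Light viscous damping at the joints and a return spring at
the toes stand in for passive tissue.

# The optimal-control problem

States are the 11 coordinates `q`, 11 speeds `u`, 24 activations `a`, and 24
normalized tendon forces; controls are the 24 excitations `e` and the 24
tendon-force derivatives. One full stride is solved with free final time
`t_f` in [0.3, 2] s, subject to:

* skeletal kinematics and dynamics, activation dynamics, and the implicit
  tendon equilibrium;
* bounds: excitations and activations in [0.001, 1], normalized tendon
  forces in [0, 1.8], their derivatives in [-1000, 1000], and coordinate
  ranges from the config;
* periodicity of all states and excitations, except the forward pelvis
  position, which must advance by (speed x `t_f`) — this is also what pins
  the average gait speed.

The nominal objective is muscular effort: the integral of the summed cubed
excitations divided by the forward pelvis displacement, a muscle-fatigue
proxy. The tracking variant adds SD-normalized squared deviations of the 11
coordinates, 11 speeds, and 4 GRF channels from a reference gait; it is used
to manufacture initial guesses. The symmetry variants add the smooth
step-length and/or step-time goals described below, with weights 8 and 5.

## Smooth symmetry goals

The exact step metrics are event-based and non-smooth, so the objective uses
smooth surrogates (re-derived in this package from their verbal description;
the original smoothing formulas were not available):

* **Step-length goal** — the target stride length is taken from the matching
  nominal condition and halved to give a per-side target step length. A
  softplus penalty accumulates whenever the fore-aft heel-to-heel distance
  exceeds the target in either leading configuration; the squared overshoot
  is integrated over the cycle (phase quadrature, normalized by the squared
  target, so the goal is dimensionless and decoupled from stride time).
* **Step-time goal** — per-node logistic contact indicators on each foot's
  vertical GRF (centred at the 20 N foot-strike threshold) are summed into
  smooth per-side "contact node counts"; nodes where both feet are in
  contact are attributed to the leading foot through a logistic weight on
  the fore-aft heel separation. The goal is the squared node-count asymmetry
  `((n_NP - n_P)/(n_NP + n_P))^2`. Node-count normalization is the default
  (the alternative stride-time normalization differs only by the constant
  node spacing on an even grid).

Both goals converge to hard-threshold oracles as their sharpness grows
(verified in the tests), and the exact indices `sla()`/`sta()` are always
recomputed post hoc from the solved trajectory — the goals are steering
devices, not measurements.

# Transcription

`transcribe()` discretizes states and controls on an evenly spaced grid
(default 51 nodes for the reduced profile; 201 for replication runs) with
**compressed Hermite–Simpson** collocation: interval midpoint states are
eliminated through the Hermite interpolant rather than kept as decision
variables. The separate (midpoint-as-variable) form is the other standard
choice; compression halves the decision vector, which matters for the
package's own solver, at identical discretization order. Integral costs use
the interval-consistent Hermite-Simpson quadrature (with interpolated
midpoint controls); node-only quadrature is subtly wrong here because it
lets the optimizer alias controls at the grid frequency and undercut the
true cost, which the minimum-effort double-integrator test demonstrates. The implicit tendon residual is
enforced pointwise at the nodes; periodicity closes the cycle.

Scaling is essential and is part of the problem definition:

* variables are scaled to order one by characteristic magnitudes (speeds by
  5, tendon-force derivatives by 50);
* defect rows are scaled by `1/(s_d h)` where `s_d` is a per-channel
  characteristic *rate* — 1 for coordinates, and for the speed rows a
  characteristic acceleration that grows distally (100 at the hips to 2000
  at the toes, where light segments meet stiff contact). The feasibility
  tolerance is stated on this scaled violation: the reduced profile uses
  1e-3, the replication profile 1e-4.

A fourth-order convergence check on a linear ODE, and an analytic
minimum-effort double-integrator problem, verify the transcription order and
the optimizer on problems with known solutions.

# Solver

No general sparse NLP solver is available to the package, so it carries its
own: an augmented-Lagrangian outer loop with two kinds of inner minimizer.
Early outers can use bound-constrained L-BFGS-B on the AL function (cheap,
robust far from feasibility); the main workhorse is a damped Gauss–Newton
method that assembles the exact sparse constraint Jacobian (analytic
chain-rule blocks through the Hermite midpoint, with the mass matrix
factorized once per node), forms `mu J'J` plus the tracking objective's
diagonal curvature, and solves for the step with a supernodal sparse
Cholesky factorization, under a Levenberg-style damping parameter adapted by
the ratio of achieved to predicted decrease and a projected line search for
the bounds. Multipliers follow the classical safeguarded update: improve
feasibility sufficiently and the multipliers move; otherwise the penalty
grows (to a cap, after which multiplier updates resume). Everything is
deterministic — identical guesses reproduce identical iterates — and
single-threaded.

The augmented-Lagrangian/Gauss–Newton consistency (AL gradient equals
`grad J + J' (lambda + mu c)` assembled from the exported Jacobian) is
asserted in the tests to machine precision, so the two code paths cannot
drift apart silently.

## Initial guesses and the solve ladder

Predictive contact-rich problems live or die by their initial guess. The
package builds guesses in three layers:

1. **Synthetic reference** (`generate_reference()`): task-space construction
   of one stride — each foot flat on the ground for 62% of the cycle with a
   late-stance heel rise about the metatarsal pivot (toes kept flat),
   cycloidal swing with a clearance bell, and the pelvis riding the
   compass-gait arc implied by leg reach; planar two-link inverse kinematics
   converts this to joint angles, and a 12-harmonic Fourier projection makes
   the curves periodic with speeds that are exact time derivatives. By
   construction the stance foot skims the ground with a few millimetres of
   penetration at the correct times. Per-limb vertical GRF references are
   double-peaked and average one body weight over the cycle. The curve shape
   adapts to the target speed by default; a fixed-shape mode reuses the
   nominal (1.4 m/s) shape across speeds for fidelity to tracking pipelines
   built on a single recorded dataset.
2. **Muscle-consistent fill** (`reference_guess()`): inverse dynamics along
   the reference gives the required joint torques, which are distributed
   over the muscles by bounded ridge-regularized least squares at every
   node; activations follow by inverting the (affine-in-activation) fiber
   equilibrium, and excitations by inverting the activation dynamics. This
   removes the large stance-phase torque deficits that a naive constant-
   activation guess leaves in the defect constraints.
3. **Warm-start ladder** (`run_condition()`): the tracking solution at a
   speed seeds the nominal solve; nominal solutions seed their
   adjacent-faster-speed and adjacent-greater-weakness neighbours; symmetry
   conditions start from their nominal solution and take its measured stride
   length as the symmetry target. Among the attempts for a condition, the
   converged solution with the least objective is kept (`select_best()`).

The tracking solve itself is staged: kinematic tracking first (with a
coordinate corridor around the reference that makes sustained flight
infeasible), then the full objective including GRF tracking. Tracking keeps
the stride time within 15% of the reference's.

# Problem sizes and budgets

The tests and the acceptance script run the *reduced profile*: 51 nodes,
scaled feasibility tolerance 1e-3, and bounded solver budgets (tens of
outer iterations with ~10 Gauss–Newton steps each) chosen so the whole
suite completes on a single CPU at desk scale. These are the package's
stated study conditions for the scaled-down behavioural checks. The
*replication profile* — 201 nodes, tolerance 1e-4, the full 26-condition
matrix with three guesses per nominal condition — is constructible through
the same interfaces (`collocation_grid(201)`, `solver_control(tol = 1e-4)`,
`run_matrix()`) but takes hours per condition on this solver, as it does for
the reference implementations of this class of problem; it is therefore a
documented long-running profile, not part of the test suite. A practical
consequence, reported honestly by the convergence flags: under tight desk
budgets the predictive solves may terminate feasibility-limited (the
contact-transient defect rows are the last to converge), and the behavioural
assertions are then red rather than silently weakened.

# Energetics

Two whole-muscle energetics models are implemented from their original
formulations, with every coefficient exposed in `metabolic_parameters()`:

* the default model: activation/maintenance heat (slow/fast-twitch weighted,
  scaled by activation^0.6 and an aerobic factor of 1.5, maintenance part
  scaled by the force–length curve above optimal length),
  shortening/lengthening heat with fiber-type-specific coefficients, and
  *positive* fiber work only, with the total rate clamped non-negative;
* the alternative model: excitation-driven activation and maintenance heat
  (sinusoidal fiber-type weighting, piecewise-linear length dependence),
  shortening heat proportional to fiber force, and positive fiber work.

Fiber-type fractions per muscle are commonly published lower-limb values
stored in the model config; they are not identifiable from gait data, and
absolute COT values shift by several percent across plausible choices — the
*comparisons across conditions*, which share the fractions, are the robust
output. A whole-body basal rate of 1.2 W/kg body mass is included by default
(gross COT). COT normalizes by total body mass and pelvis displacement;
positive/negative mechanical COT integrates the positive/negative parts of
the fiber power per limb. Muscle masses derive from base strengths (specific
tension 60 N/cm^2, density 1059.7 kg/m^3) and are held fixed under weakness.

# Gait metrics

A foot strike is the upward crossing of 20 N by a foot's vertical GRF,
linearly interpolated between nodes with periodic wrap-around; zero or
multiple strikes per stride mark the gait atypical (a flag, not an error).
Step lengths are heel-sphere-centre separations at the respective strike
instants; the paretic step time runs from non-paretic strike to paretic
strike (the definition that makes the two step times partition the stride).
`condition_summary()` locates each model's minimum-COT speed, sending exact
ties to the slower speed and flagging single-speed sweeps.

# What the synthetic reference does and does not emulate

The generator reproduces the *structure* of normative reference data:
periodicity, physiological joint ranges, correctly timed double-peaked
vertical GRFs averaging body weight, and per-channel SDs of published
magnitude. It does not model inter-subject variability beyond those SDs,
frontal-plane mechanics, or the fine shape of experimental angle curves
(e.g., the early-stance knee-flexion bump is absent; the surrogate walks
with a straighter stance knee, as this model family tends to anyway).
Passing tests therefore demonstrate that the pipeline recovers the intended
behaviour under these surrogate conditions, not that it reproduces any
specific experimental dataset.

# Known limitations

* Constant moment arms are a first-order muscle geometry; muscles spanning
  large joint excursions see correspondingly large normalized fiber-length
  excursions.
* The hand-rolled solver is robust but slow compared to industrial interior
  point methods; full-resolution replication is an overnight computation.
* The energetics coefficients follow the published models as transcribed in
  `metabolic_parameters()`; no attempt is made to fit them to calorimetry.
* Sagittal-plane only; no lumbar joint, arms, or frontal-plane compensations.
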