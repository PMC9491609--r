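# hemigait

Predictive simulation of hemiparetic gait in R: periodic optimal-control
walking for a sagittal-plane musculoskeletal model with graded unilateral
muscle weakness, and the spatiotemporal-asymmetry and energetic analyses
that go with it.

## The problem

Hemiparesis — one-sided muscle weakness after stroke or in cerebral palsy —
occurs together with many other impairments, so observational data cannot
say which gait deviations weakness *itself* would cause. Predictive
simulation can: build a musculoskeletal model, scale down the peak isometric
strength of every muscle on one limb, and solve for the gait that minimizes
an assumed neural objective at a prescribed speed. The emergent step-length
asymmetry (SLA), step-time asymmetry (STA), and metabolic cost of transport
(COT) then quantify the *optimal adaptation* to weakness alone.

`hemigait` implements the full pipeline:

* an 11-degree-of-freedom planar skeleton (pelvis x/y/tilt plus hip, knee,
  ankle, and toe pin joints per leg; torso fused to the pelvis) driven by 24
  Hill-type muscle–tendon units with implicit tendon compliance, and five
  smooth contact spheres per foot;
* `apply_weakness()` scales the paretic (left) limb's peak isometric
  strengths by `1 - fraction` (20/40/60% in the standard matrix), holding
  muscle mass fixed (weakness without atrophy);
* `transcribe()` + `solve_nlp()` — Hermite–Simpson direct collocation of the
  periodic stride (free stride time, average speed pinned through the
  pelvis-translation periodicity constraint), solved by an augmented
  Lagrangian with sparse Gauss–Newton inner steps;
* `fit_gait()` — the one-call fitting interface returning a classed
  `gait_solution` with `print()`, `summary()`, `coef()`, `plot()`, and
  `residuals()` methods;
* smooth step-length/step-time symmetry objectives for the
  symmetry-enforcement experiment, and exact post-hoc indices;
* Umberger- and Bhargava-family muscle energetics, mechanical work
  partitioning, and cost of transport;
* `generate_reference()` — a synthetic normative reference gait
  (task-space-constructed, inverse-kinematics-consistent) that seeds the
  tracking solves used as initial guesses.

The core quantities, in the field's notation: the nominal objective is the
muscular-effort (fatigue proxy) functional

    J1 = ( sum_i  ∫ e_i(t)^3 dt ) / ( q_pelvis_x(t_f) - q_pelvis_x(0) )

over the 24 excitations `e_i`, and the asymmetry indices are

    SLA = 100 (SL_NP - SL_P) / (SL_NP + SL_P)
    STA = 100 (ST_NP - ST_P) / (ST_NP + ST_P)

with NP/P the non-paretic/paretic sides; positive values mean the
non-paretic step is longer/slower.

## A worked example

```r
library(hemigait)

model <- load_gait_model()          # packaged planar walker, ~75 kg
model
#> Sagittal-plane gait model: 11 coordinates, 24 muscle-tendon units
#>   body mass 75.01 kg, gravity 9.8066 m/s^2
#>   symmetric strength (base model)

weak <- apply_weakness(model, 0.40) # 40% weaker left (paretic) limb
head(muscle_strengths(weak), 4)
#>              muscle right   left
#> 1  biceps_long_head  4105 2463.0
#> 2 biceps_short_head   557  334.2
#> 3   gluteus_maximus  4450 2670.0
#> 4             psoas  2448 1468.8

# asymmetry indices (signed percent, non-paretic minus paretic)
sla(0.6, 0.4)
#> [1] 20
sta(0.40, 0.50)
#> [1] -11.11111

# a predictive solve on the reduced profile (51 nodes): the tracking stage
# manufactures a warm start from the synthetic reference, then the nominal
# (pure-effort) problem is solved from it
ctl <- solver_control(outer_max = 16L, newton_maxit = 10L)
track <- fit_gait(model, speed = 0.75, objective = "tracking", n_nodes = 51L,
                  control = ctl)
sol <- fit_gait(model, speed = 0.75, objective = "nominal", n_nodes = 51L,
                guess = track$trajectory, control = ctl,
                guess_label = "tracking")
sol
#> gait solution: nominal objective, 0.75 m/s, weakness L 0%/R 0%
#>   NOT converged; objective 2.27826; max constraint violation 1.02e-01; 482 inner iterations (82 s)
#>   SLA -3.46%, STA -3.39%, stride 1.037 m / 1.385 s

summary(sol)$energy
#> energetics (umberger model): COT 14.830 J/kg/m (NP 7.522, P 7.308)
#>   mechanical COT +6.155 / -4.526 J/kg/m; integrated activation 7.097
```

The step metrics here come out near-symmetric, as they should for a
symmetric model. The convergence flag and the maximum constraint violation
are part of the result and are reported honestly: under desk-scale solver
budgets the contact-transient defect rows typically remain above the 1e-3
reduced-profile feasibility tolerance (see the methods vignette for the
analysis), so a solution is labelled not converged even when it walks —
treat the reported energetics of such iterates as provisional. `run_condition()` / `run_matrix()`
orchestrate the full condition matrix with the warm-start ladder
(tracking solution, neighbouring speed, neighbouring weakness) and
`select_best()` keeps the least-objective converged attempt per cell.

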