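# Default sagittal-plane walker: 11 coordinates, 9 bodies (torso rigidly fused
# to the pelvis), 24 muscle-tendon units (12 per limb), 5 contact spheres per
# foot. Anthropometry is a package-owned standard adult set (~75 kg, ~1.75 m);
# peak isometric strengths are the published 12-muscle table.
# Conventions: x forward, y up, ground at y = 0; hip/knee flexion positive,
# ankle dorsiflexion positive, toe extension positive; pelvis_tx positive
# forward. Left limb is the paretic (weakened) side.
gravity: 9.80665
segments:
  hat:        {mass: 50.85, com: [0.0, 0.32], inertia_zz: 4.00, length: 0.80}
  thigh:      {mass: 7.50,  com: [0.0, -0.186], inertia_zz: 0.145, length: 0.430}
  shank:      {mass: 3.49,  com: [0.0, -0.186], inertia_zz: 0.059, length: 0.430}
  foot:       {mass: 0.94,  com: [0.05, -0.030], inertia_zz: 0.0040, length: 0.160}
  toes:       {mass: 0.15,  com: [0.03, -0.010], inertia_zz: 0.0010, length: 0.070}
# metatarsophalangeal joint location in the foot (ankle) frame
mtp_location: [0.160, -0.045]
coordinates:
  # name: [lower, upper, speed_lower, speed_upper]  (m, m/s or rad, rad/s)
  pelvis_tx:   [-0.5, 5.0, -1.0, 3.0]
  pelvis_ty:   [0.60, 1.10, -2.0, 2.0]
  pelvis_tilt: [-0.9, 0.9, -8.0, 8.0]
  hip_r:       [-0.7, 1.5, -13.0, 13.0]
  knee_r:      [-0.12, 2.2, -16.0, 16.0]
  ankle_r:     [-1.0, 0.8, -16.0, 16.0]
  toe_r:       [-0.6, 1.3, -16.0, 16.0]
  hip_l:       [-0.7, 1.5, -13.0, 13.0]
  knee_l:      [-0.12, 2.2, -16.0, 16.0]
  ankle_l:     [-1.0, 0.8, -16.0, 16.0]
  toe_l:       [-0.6, 1.3, -16.0, 16.0]
contact:
  stiffness: 3.0e+05        # N/m^(3/2), Hunt-Crossley-type normal law
  dissipation: 2.0        # s/m
  friction: 0.8           # Coulomb coefficient, tanh-smoothed
  velocity_smoothing: 0.05  # m/s, friction transition velocity
  depth_smoothing: 4.0e-03   # m, smooth-penetration epsilon
  spheres:
    # foot-frame (ankle) coordinates; heel sphere first: it is the marker
    # used for step-length measurement. segment: foot or toes.
    - {segment: foot, location: [-0.055, -0.045], radius: 0.040, heel: true}
    - {segment: foot, location: [0.010, -0.055], radius: 0.030}
    - {segment: foot, location: [0.070, -0.060], radius: 0.025}
    - {segment: foot, location: [0.130, -0.063], radius: 0.022}
    - {segment: toes, location: [0.045, -0.018], radius: 0.022}
passive:
  # passive tissue at the joints: light viscous damping plus a return spring
  # at the toes (N.m.s/rad, N.m/rad)
  joint_damping: {hip: 0.8, knee: 0.8, ankle: 0.8, toe: 0.2}
  toe_stiffness: 15.0
# pose (rad) at which each muscle-tendon unit is calibrated: fiber at
# optimal length, tendon at slack. A mid-gait flexed pose keeps operating
# fiber lengths near optimal across the stride (with constant moment arms).
calibration_pose: {hip: 0.20, knee: 0.35, ankle: -0.05, toe: 0.10}
muscle_defaults:
  max_contraction_velocity: 10.0   # optimal fiber lengths / s
  activation_tau: 0.015            # s
  deactivation_tau: 0.060          # s
  tendon_strain_at_fmax: 0.049     # nominal tendon strain at peak isometric force
  fiber_damping: 0.01
  specific_tension: 6.0e+05          # N/m^2, used to derive muscle mass
  density: 1059.7                  # kg/m^3
muscles:
  # f_iso_max: published peak isometric strengths (N).
  # moment arms (m) are constant, signed in the flexion/dorsiflexion/toe-
  # extension-positive convention: positive arm means the muscle shortens as
  # the coordinate increases.
  biceps_long_head:
    f_iso_max: 4105
    optimal_fiber_length: 0.109
    tendon_slack_length: 0.341
    pennation_at_optimal: 0.0
    moment_arms: {hip: -0.060, knee: 0.035}
    fast_twitch_fraction: 0.35
  biceps_short_head:
    f_iso_max: 557
    optimal_fiber_length: 0.173
    tendon_slack_length: 0.089
    pennation_at_optimal: 0.40
    moment_arms: {knee: 0.040}
    fast_twitch_fraction: 0.45
  gluteus_maximus:
    f_iso_max: 4450
    optimal_fiber_length: 0.147
    tendon_slack_length: 0.127
    pennation_at_optimal: 0.38
    moment_arms: {hip: -0.062}
    fast_twitch_fraction: 0.45
  psoas:
    f_iso_max: 2448
    optimal_fiber_length: 0.104
    tendon_slack_length: 0.113
    pennation_at_optimal: 0.14
    moment_arms: {hip: 0.045}
    fast_twitch_fraction: 0.50
  rectus_femoris:
    f_iso_max: 2192
    optimal_fiber_length: 0.084
    tendon_slack_length: 0.346
    pennation_at_optimal: 0.09
    moment_arms: {hip: 0.040, knee: -0.045}
    fast_twitch_fraction: 0.55
  vastus_intermedius:
    f_iso_max: 9593
    optimal_fiber_length: 0.087
    tendon_slack_length: 0.136
    pennation_at_optimal: 0.06
    moment_arms: {knee: -0.045}
    fast_twitch_fraction: 0.50
  gastrocnemius:
    f_iso_max: 4691
    optimal_fiber_length: 0.060
    tendon_slack_length: 0.380
    pennation_at_optimal: 0.30
    moment_arms: {knee: 0.020, ankle: -0.048}
    fast_twitch_fraction: 0.45
  soleus:
    f_iso_max: 6194
    optimal_fiber_length: 0.050
    tendon_slack_length: 0.250
    pennation_at_optimal: 0.44
    moment_arms: {ankle: -0.048}
    fast_twitch_fraction: 0.20
  tibialis_anterior:
    f_iso_max: 1227
    optimal_fiber_length: 0.098
    tendon_slack_length: 0.223
    pennation_at_optimal: 0.09
    moment_arms: {ankle: 0.040}
    fast_twitch_fraction: 0.30
  extensor_hallucis_longus:
    f_iso_max: 889
    optimal_fiber_length: 0.111
    tendon_slack_length: 0.305
    pennation_at_optimal: 0.16
    moment_arms: {ankle: 0.030, toe: 0.012}
    fast_twitch_fraction: 0.45
  flexor_digitorum_longus:
    f_iso_max: 1331
    optimal_fiber_length: 0.034
    tendon_slack_length: 0.400
    pennation_at_optimal: 0.21
    moment_arms: {ankle: -0.030, toe: -0.015}
    fast_twitch_fraction: 0.45
  flexor_digitorum_brevis:
    f_iso_max: 938
    optimal_fiber_length: 0.051
    tendon_slack_length: 0.065
    pennation_at_optimal: 0.44
    moment_arms: {toe: -0.012}
    fast_twitch_fraction: 0.45
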