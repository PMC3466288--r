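# impedadapt default configuration
# Matrix-valued entries are flattened column-major.

arm:
  L: [0.30, 0.33]            # link lengths (m): upper arm, forearm+hand
  m: [1.40, 1.10]            # link masses (kg)
  lc: [0.11, 0.16]           # center-of-mass distances from proximal joint (m)
  I: [0.025, 0.045]          # link moments of inertia (kg m^2)
  B: [0.8, 0.2, 0.2, 0.8]    # joint viscosity matrix (N m s/rad)
  q_lim: [-1.5707963, 0.01, 3.1415927, 3.1101767]  # joint limits (rad), lower then upper

geometry:
  # moment arms (m), 2x6: rows shoulder/elbow; columns sh-flex, sh-ext,
  # el-flex, el-ext, bi-flex, bi-ext
  A: [0.040, 0.000, -0.040, 0.000, 0.000, 0.025, 0.000, -0.025,
      0.040, 0.025, -0.040, -0.025]
  l0: [0.15, 0.15, 0.15, 0.15, 0.15, 0.15]   # reference muscle lengths (m)
  q_ref: [0.7853982, 1.5707963]              # reference posture (rad)

muscle:
  T0: 400        # active tension per unit activation (N)
  k0: 100        # intrinsic stiffness intercept (N/m)
  k1: 30000      # intrinsic stiffness slope (N/m per unit activation)
  b0: 10         # intrinsic viscosity intercept (N s/m)
  b1: 2000       # intrinsic viscosity slope (N s/m per unit activation)
  rho: 0.015     # rest-length shortening per unit activation (m)

gains:
  stretch_slope: 30     # feedback V-shape slope, stretch side (1/m)
  shorten_slope: 15     # feedback V-shape slope, shortening side (1/m)
  kappa: 0.05           # velocity weighting in the sliding error (s)
  delay: 0.06           # neural feedback delay (s)

learning:
  eta: 2                # learning rate
  Q: 1                  # error-cost weight
  R: 0.001              # activation-cost weight
  gamma: 0.002          # uniform decay per trial
  stretch_slope: 30     # learning-drive slope, stretch side (1/m)
  shorten_slope: 15     # learning-drive slope, shortening side (1/m)
  decay: uniform        # uniform | proportional

noise:
  coef: 0.02            # signal-dependent noise sd per unit activation
  cutoff_hz: 10         # low-pass cutoff of the noise process (Hz)

simulation:
  dt: 0.001             # integration step (s)
  speed_limit: 8        # divergence guard on hand speed (m/s)
  success_radius: 0.0125  # terminal accuracy for a successful trial (m)

network:
  K_min: 3
  K_max: 80
  K_init: 20
  coverage: 0.85        # target 95th-percentile state-to-center distance (z units)
  scale_factor: [1.5, 1.5, 2.5, 2.5]  # width scaling per state dimension
  iter_budget: 2000     # total Lloyd-iteration budget of the selection stage
  n_restarts: 3         # K-means restarts per candidate K

fields:
  # velocity-dependent field gain matrix (N s/m), column-major
  vf_B: [-10.1, -11.2, -11.2, 11.1]
  vfk_amplitude: 70     # direction-variant curl amplitude (N s/m)
  df_gain: 600          # divergent-field lateral stiffness (N/m)
  df_barrier: 0.05      # safety-barrier threshold (m)
  df_barrier_damping: 50  # barrier damping (N s/m)
  df_circle_diameter: 0.025  # start/end circle diameter (m)

workspace:
  center: [0.0, 0.40]   # workspace center for reach/circle protocols (m)
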