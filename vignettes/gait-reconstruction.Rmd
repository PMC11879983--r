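---
title: "Reconstructing gait from sparse IMU data: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gait from sparse IMU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the musculoskeletal
model and its assumptions, the optimal control formulation, the numerical
machinery, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the problem was genuinely open.

## The musculoskeletal model

The skeleton is a planar seven-segment chain: a combined head-arms-trunk
(HAT) segment and, per leg, thigh, shank and a rigid foot. Its configuration
is nine generalized coordinates `q`: pelvis (hip-point) position (m), trunk
orientation (rad, counter-clockwise from upright), and hip, knee and ankle
angles of both legs. The sign conventions are anatomical: hip flexion, knee
flexion and ankle dorsiflexion positive; +x is the direction of progression,
+y is up, gravity is (0, -9.81) m/s², and the ground is the line y = 0.

Anthropometry is personalized from body height and mass alone through
Winter's regression fractions (`extdata/params/segment_fractions.csv`):
segment masses as fractions of body mass, lengths as fractions of height,
center-of-mass offsets and radii of gyration as fractions of segment length.
The HAT absorbs the mass remainder, so segment masses sum to body mass
exactly, and all lengths scale linearly with height. The foot is rigid with
heel and toe contact offsets at the tabulated ankle height below the ankle
joint; the heel sits a quarter of the foot length behind the ankle, the toe
three quarters ahead.

Sixteen Hill-type muscles (eight per leg: iliopsoas, glutei, hamstrings,
rectus femoris, vasti, gastrocnemius, soleus, tibialis anterior) actuate the
joints. Their parameters (`extdata/params/muscles.csv`) follow the
established planar 9-DOF/16-muscle gait model parameterization; the original
study cites but does not print its muscle table, so these values are
documented substitutes in the same family. Muscle paths use constant moment
arms, making the musculotendon length affine in the joint angles,
`lMT(q) = slack + lceopt - sum_j d_j q_j`, with `d_j = -dlMT/dq_j` exact. An
angle-dependent arm model was considered and rejected: nothing in the
formulation needs it, and constant arms keep every derivative analytic.

The Hill curves are chosen to be infinitely differentiable, because the
collocation solver consumes exact first *and second* derivatives:

* force-length: Gaussian `exp(-((l/lceopt - 1)/width)^2)`, width 0.56;
* force-velocity: the logistic `1.5 / (1 + 0.5 exp(-12 vnorm))` — zero force
  at rapid shortening, slope 4 at isometric, eccentric plateau at 1.5 times
  isometric, strictly monotone;
* series-elastic and parallel-elastic elements: smoothed quadratics in
  tendon strain (reference strain 4% at maximal force) and normalized CE
  length, with `softplus(x) = (x + sqrt(x^2 + e^2))/2` replacing the hard
  positive part;
* a small damping term (0.01 of maximal force per normalized velocity) keeps
  the implicit contraction equation solvable for the CE velocity at zero
  activation.

Activation dynamics are first order, `da/dt = (u - a) r(u, a)`, with the
rate blending smoothly (tanh switch) between 1/10 ms (activation) and
1/40 ms (deactivation).

Passive joint-limit moments — smooth exponential springs outside anatomical
ranges, plus light viscous damping (1 N m s/rad) — are included in the joint
moments. They are an addition beyond the source formulation's printed text:
without them an effort-minimal gait hyperextends the knee into the bound
box, and some joint damping is standard in planar gait models of this class.

Foot-ground contact acts at four points (heel/toe, both feet). The vertical
force is `clamp(k * softplus(-py) * (1 - c * vy))` — penetration-based with
velocity damping, clamped smooth-nonnegative — and the horizontal force is
`-fy * mu * tanh(vx / vslip)`, a smoothed friction law opposing slip.
Defaults (`extdata/params/contact.csv`): stiffness 75 kN/m per point,
damping 0.85 s/m, friction 1.0, slip smoothing 0.1 m/s, penetration
smoothing 1 mm, force floor 0.5 N. The exact published contact constants
live in a methods-paper citation chain; these are tuned defaults of the same
penetration/friction family, flagged as configuration.

## Virtual sensors

A virtual IMU fixed to a segment measures the planar angular velocity of its
host segment (gyroscope) and the *specific force* at its mounting point: the
point acceleration minus gravity, expressed in the segment-aligned sensor
frame. Including the gravity reaction is a deliberate, testable convention —
a physical accelerometer at rest reads +1 g — and the unit tests pin it.
Default placements put sensors on the instep of each foot, anterior mid
thigh and shank, and the posterior pelvis; positions scale with the subject
and can be overridden per sensor.

## The optimal control problem and its transcription

A reconstruction minimizes `J_track + 300 J_effort + 1e-5 J_reg` subject to
the implicit system dynamics, bounds, and periodicity over one gait cycle,
where `J_track` is the variance-weighted squared deviation between virtual
and measured accelerometer/gyroscope channels (averaged over duration,
channels and sensors) and `J_effort` is the squared excitation mean
normalized by the squared speed. Tracking by inverse variance lets noisy
parts of the cycle (large across-cycle variance) count less and
automatically balances accelerometer against gyroscope units.

Direct collocation with a backward-Euler discretization turns this into a
sparse NLP: per node, 18 skeletal states, 32 muscle states, 16 excitations
and 16 contact values (global positions and forces of the four contact
points, the forces stored in bodyweights); globally, the speed and the cycle
duration. An extra node N+1 carries the periodicity constraint: every
per-node quantity equals its node-1 value, with the horizontal shift
`speed * T` applied to the pelvis x and the four contact-point x positions.
At N = 100 this is 8,284 variables and 6,682 constraints (100 x 66 dynamics/
contact rows + 82 periodicity rows). Contact positions/forces are decision
variables bound to the model by consistency rows — redundant in exact
arithmetic but markedly better conditioned, since the stiff contact law then
enters through 16 decoupled rows instead of through the mass-matrix rows.

Open points resolved as package design choices:

* **`J_reg`** is named but never defined in the source formulation. It is
  implemented as the mean squared first difference of the excitations and of
  the generalized velocities across nodes, scaled by 1/T — a roughness
  penalty, the standard reading; at weight 1e-5 the results are insensitive
  to the exact form.
* **Quadrature**: rectangle rule on the N right-hand nodes, consistent with
  backward Euler.
* **Variance floor**: measured variances are clamped below at
  `1e-4 * mean(mu^2) + 1e-6` per channel, so zero-variance nodes cannot
  blow up the tracking weights.
* **Bounds** (not printed in the source): excitations/activations in [0,1],
  joint angles within generous anatomical ranges, pelvis height within
  (0.5, 1.5) leg lengths, speed in (0.2, 6) m/s, duration in (0.2, 2) s,
  normalized CE lengths in (0.3, 1.9), contact forces in (-3, 3)/(-0.05, 5)
  bodyweights.
* **Gauge terms**: accelerometers observe the pelvis x position only up to a
  constant, and a predictive (no-data) problem is additionally invariant
  under cyclic time shifts. Two small quadratic anchors — on the first-node
  pelvis x, and (predictive only) on the first-node right hip angle pinning
  the cycle to start near right heel strike — remove these null directions.
  They are numerical gauge fixing, orders of magnitude below the physical
  objective terms.

## The solver

No interior-point NLP library is part of the package's dependency footprint,
so `gaitrec` carries its own: a sparse primal-dual interior-point method in
the IPOPT mold. The constraint Jacobian and the exact Hessian of the
Lagrangian are assembled analytically — the multibody, contact-kinematic and
virtual-sensor kernels (with their first and multiplier-weighted second
derivatives) are generated symbolically once by `tools/generate_dynamics.py`
and shipped as vectorized R source; muscle, activation and contact-law
curvature is chained by hand. The KKT systems are symmetric quasidefinite
and are factorized by CHOLMOD's simplicial LDL' with iterative refinement
(sparse-LU fallback); inertia is read off the D factor and corrected by a
primal diagonal shift. Globalization is an l1 exact-penalty line search with
fraction-to-boundary steps, a monotone barrier schedule, multiplier
safeguards (the equality multipliers are reset to their least-squares
estimate when primal regularization inflates them), and a final feasibility
polish — Newton least-norm steps onto the constraint manifold — that drives
the constraint violation to ~1e-10.

Two continuations make the nonconvex problems tractable from generic
starts:

* **Tracking-weight tempering** (reconstructions): solve with the tracking
  term scaled by 1e-3 — equivalent to inflated measurement variance — then
  at full weight, warm-starting primal and dual variables.
* **Mesh continuation**: reconstructions above N = 16 are first solved on
  coarse track grids (the cycle-phase-interpolated tracks at roughly N/4 and
  N/2), each solution interpolated up as the next warm start; the predictive
  generator does the same with its own grids. The stiff fine-grid problem
  then starts near-feasible and near-optimal.

Termination: "converged" means the scaled KKT error met the tolerance or the
objective stalled at a feasible, centered point; "acceptable" means the
iteration/time budget ran out at a feasible (post-polish, ~1e-10), centered
point. On this problem family the objective creeps along nearly flat valleys
long after the trajectory has stopped changing materially, so budgeted
near-optimality is the practical stopping rule; both statuses guarantee the
dynamics and periodicity hold to far better than 1e-6. Restoration failure
(step computation stalls) and plain iteration exhaustion at infeasible
points are reported distinctly and treated as failures.

## The synthetic-data generator

`predictive_gait()` produces ground truth by solving the same collocation
problem with no data: effort plus regularization only, speed fixed at the
target. Two further design choices shape it:

* **Cycle duration is prescribed**, not optimized, from a nominal
  speed-stride relationship (stride = 0.75 v + 0.40 m walking, 0.62 v +
  0.42 m running). Effort-per-distance alone under-determines cadence — left
  free, the optimizer drifts toward extreme stride lengths — and published
  predictive simulations that recover human-like cadence rely on richer
  objectives (metabolic cost, joint accelerations). The duration remains a
  decision variable structurally (held by equal bounds), and is free in all
  data reconstructions.
* **Initialization** is a nominal-gait template: joint-angle harmonics
  shaped like normal walking or running, backward-Euler-consistent
  velocities, contact forces from per-node inverse dynamics (the
  least-squares forces zeroing the equations of motion). A kinematic-pull
  continuation (quadratic attraction to the template, then released) guides
  the first solve. The plain standing guess of `initial_guess(.., "static")`
  remains available.

The resulting walking truth at 1.3 m/s is periodic, dynamically consistent
to ~1e-14, and walking-like: alternating single-leg stance with stance
fraction around 0.5 and vertical GRF peaks of 1.2-1.8 BW. Compared to human
walking it is stiff-kneed in swing and spends almost no time in double
support — known traits of pure squared-excitation objectives on planar
models — so the stance-fraction sanity band asserted in the tests is the
broad (0.40, 0.80).

`synthesize_tracks()` renders the truth's virtual signals for a sensor
setup, adds i.i.d. Gaussian noise per node and channel independently to each
of (default) 10 synthetic cycles, and stores per-node mean and floored
sample variance — the same reduction a measured multi-cycle recording
undergoes. Defaults: accelerometer sd 0.5 m/s², gyroscope sd 0.05 rad/s,
realistic across-cycle magnitudes for walking. The generator deliberately
does *not* emulate soft-tissue artifact spectra, sensor bias/misalignment,
or calibration error; passing recovery tests therefore demonstrate that the
estimator inverts its own forward model under additive noise — a necessary
condition — not that it is robust to every artifact of real recordings.

## Evaluation metrics

Stride length is the right-heel horizontal translation over the cycle
(equal to `speed * duration` by periodicity), speed is stride over duration,
and stance is the maximal circular run of nodes whose vertical GRF exceeds
0.05 BW (a configurable threshold; detection conventions window walking
cycles heel-strike to heel-strike and running cycles toe-off to toe-off).
Waveform agreement uses RMSD and the linear-fit-method coefficient of
determination — the R² of the least-squares affine map from the reference
waveform to the estimate (reference as regressor, estimate as response);
R² values are averaged through Fisher's Z-transform of their square roots,
values at 1 clamped just below (atanh(1) is infinite). Relationship
categories: strong > 0.7, moderate > 0.5, weak > 0.3, else none; boundaries
fall to the lower category. Joint moments are reported in bodyweight ×
bodyheight percent, GRFs in bodyweights.

## Problem sizes and budgets used in the shipped tests

The test-suite recovery study uses N = 50 for the zero-noise full-setup
recovery (the scale at which the recovery claims are made) and N = 10 for
the 3-noise-level × 3-seed monotonicity sweep; the acceptance script uses
N = 30 with mild noise. These sizes are the package's own evaluation
choices: they keep a complete truth-synthesis-reconstruction study on a
single CPU while leaving the transcription identical in structure to the
N = 100 reference problem, whose dimensions are verified separately.

## Known limitations

* Sagittal plane only; no frontal/transverse motion, by construction.
* The rigid two-point foot simplifies rolling contact; ankle kinetics are
  the least faithful quantity, as expected for this model family.
* Effort-minimal synthetic gait is not human gait: stiff-knee swing, minimal
  double support, prescribed cadence. It is dynamically consistent ground
  truth, not a normative dataset.
* The interior-point method, while exact in its derivatives, is a compact
  implementation: hard problems can end "acceptable" (feasible,
  budget-limited) rather than fully KKT-converged, and cold starts far from
  a gait-like state may fail; the shipped continuations are the supported
  path.
* Muscle parameters are population defaults; no subject-specific strength
  calibration.
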