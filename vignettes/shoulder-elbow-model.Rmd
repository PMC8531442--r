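---
title: "Methods: the scaled-generic shoulder-elbow model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the scaled-generic shoulder-elbow model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the model it implements: the
mechanical formulation and its assumptions, the tunable parameters and their
defaults, what the synthetic anatomy does and does not emulate, and the
numerical choices made where the design was genuinely open.

## Kinematic formulation

The upper limb is a thorax-clavicle-scapula-humerus-ulna-radius chain.  The
thorax is the inertial frame, oriented x anterior, y toward the subject's
left, z superior; gravity acts along $-\hat z$ with $g = 9.81\,$m/s$^2$.
The modeled side is the right.

Eleven generalized coordinates parameterize the chain: three intrinsic Euler
angles at each of the sternoclavicular (SC), acromioclavicular (AC) and
glenohumeral (GH) ball joints, elbow flexion/extension $q_{10}$ about the
epicondylar axis of the ulna frame, and forearm pronation/supination
$q_{11}$ about the longitudinal axis of the radius frame.  The two elbow
hinges are deliberately non-perpendicular, which is why the ulna and radius
bone-fixed frames are constructed directly from bony landmarks: the ulna
frame from the epicondyles (EL, EM), their midpoint (HU) and the ulnar
styloid (US); the radius frame from EL, US and the radial styloid (RS).

Two features deserve comment:

* **Alignment rotations.**  The rotations that align the ulna frame to the
  humerus and the radius frame to the ulna are evaluated once, in the stored
  reference pose, and kept fixed.  All coordinates are therefore zero at the
  reference pose, which is reproduced exactly.  This deviates from a strict
  ISB frame alignment on purpose: inherent alignment produces
  non-physiological forearm configurations, and a fixed alignment also
  absorbs the (fixed) elbow carrying angle.  A varying carrying angle is a
  known limitation.
* **Euler sequences.**  The default sequences are z-y-x at SC and AC and
  z-x-y at GH, all configurable per model.  Sequences are an implementation
  basis, not physics: the load-sharing problem is invariant to the choice
  because the equality rows transform by an invertible matrix.  z-x-y was
  chosen for GH after checking gimbal margins: over a full $20-150^\circ$
  scapular-plane abduction the middle angle stays below $12^\circ$ (the
  common y-x-y shoulder sequence is singular at the reference pose itself,
  and z-y-x passes within $8^\circ$ of its singularity near $100^\circ$
  elevation, which degraded finite-difference dynamics there).

The scapula is constrained to glide on the ribcage: the trigonum spinae
(TS) and angulus acromialis (AI) landmarks must remain on two ellipsoids,
$\Phi(\boldsymbol q) = (p - e_0)^T E (p - e_0) - 1 = 0$, leaving $11 - 2 =
9$ degrees of freedom.

## Dynamics

Each segment contributes a Lagrangian
$\mathscr L = \tfrac12 (m\,\dot{CG}^T\dot{CG} + \omega^T I \omega) - m g
[0\,0\,1]\,CG$; the forearm centers of mass are the landmark midpoints
($CG_u$ halfway from HU to US, $CG_r$ halfway from EL to RS).  The hand is
a point-mass block rigidly tied to the radius (default mass 0.6% of body
mass, a conventional hand fraction) and merged by the parallel-axis theorem
in diagonal form before any dynamic computation.

Generalized loads are
$\tau_k = \frac{d}{dt}\partial\mathscr L/\partial\dot q_k -
\partial\mathscr L/\partial q_k$.  The velocity gradient is computed
exactly as the generalized momentum $M(q)\dot q$ (the mass matrix is
assembled from the instantaneous joint axes, which give exact point
Jacobians $\partial p/\partial q_k = a_k \times (p - c_k)$); the
configuration gradient uses central differences with step $10^{-6}$ rad,
and the momentum rate central differences on the time grid.  This keeps
the implementation robust to model edits at the cost of a grid-resolution
requirement: the energy identity $\dot E = \sum_k \tau_k \dot q_k$ holds
to about $10^{-4}$ relative at 200 frames over a 3.25 s motion, and
degrades quadratically on coarser grids.

## Muscle paths and moment arms

Muscles are massless strings routed origin - via points - insertion, with
at most one analytic wrapping obstacle (sphere or cylinder) per polyline
gap.  Sphere wrapping solves the planar taut-string problem in the plane
through the endpoints and the center; cylinder wrapping solves it in the
transverse projection with the axial coordinate interpolated linearly in
developed length, producing a C1 helical arc.  Engagement is purely
geometric - a wrap is active exactly when the chord intersects the
obstacle - so paths are hysteresis-free.  The wrapping side is fixed per
muscle (never inferred per frame): cylinders carry a traversal sense, and
sphere wraps may carry a preferred bulge direction (used to keep the
deltoid lateral and the cuff on its anatomical side of the humeral head).

Moment arms come in two independent implementations used to cross-check
each other: the tendon-excursion definition $W_{kj} = -\partial L_j /
\partial q_k$ (central differences, step $10^{-5}$ rad) and a geometric
virtual-work evaluation that distributes unit-tension node forces along
the discretized path and contracts them with the exact rigid-body point
Jacobians.  The two agree to far better than 1% RMS; coordinates a muscle
does not span are exactly zero by construction.

## Load sharing and the stability cone

For each frame the muscle-force vector solves

$$\min_{\tilde f}\ \tilde f^T P \tilde f \quad\text{s.t.}\quad
\big[\,W\ \ \partial\Phi_{TS}/\partial q\ \ \partial\Phi_{AI}/\partial q\,\big]
\tilde f = \tau,\qquad 0 \le \tilde f \le \tilde f_{max},\qquad
\psi(\mathrm{JRF}(\tilde f)) \le 0 .$$

$P$ is diagonal with the inverse squared PCSAs on the muscle block; the
two ribcage multipliers $\lambda_{TS}, \lambda_{AI}$ (and the passive
ligaments, below) receive a tiny weight $10^{-9}$ to keep the objective
strictly convex while leaving them effectively free.  The multipliers are
bounded below by zero - the ribcage can push but not pull.  Force bounds
follow Fick's law $f_{max} = \sigma \cdot \mathrm{PCSA}$ with
$\sigma = 25\,$N/cm$^2$ by default.

The JRF is assembled as the force balance of the humerus+forearm(+hand)
subsystem: the sum of all muscle point loads applied to the arm segments,
plus the arm's weight, minus its linear inertial loads.  Segment angular
accelerations are neglected in this balance (their contribution is a
moment, not a force, and the net force balance is exact for the linear
part); constraint multipliers act on the scapula and do not appear.  The
JRF is affine in $\tilde f$, so the stability constraint - the JRF must
point into a cone that replicates the glenoid fossa - stays linear after
the cone is replaced by 8 half-spaces
$n_i = \cos\theta\, u_i - \sin\theta\, \hat d$.  The cone apex is the
humeral-head center, its axis points toward the (possibly re-inclined)
glenoid center, and the aperture is the maximum angular extent of the four
rim points seen from the apex (the full extent, rather than the mean, also
credits the labrum's effective deepening; the aperture is configurable).
Eight facets circumscribe the true cone; more facets approximate it more
tightly from outside and therefore tighten the feasible set.

The QP is solved by `pracma::quadprog`; solutions are certified in the
test suite by a stationarity (KKT) residual reconstructed via nonnegative
least squares and, on small instances, by brute-force active-set
enumeration.

## Subject scaling

`scale_subject()` composes, in order: (1) gender/weight/height predictive
equations for segment masses (percent of body mass), lengths (fractions of
stature) and transverse/lateral inertias ((gyration coefficient x
length)$^2$ x mass), with the forearm mass split 62%/38% between ulna and
radius; (2) anisotropic morphology scaling by $S =
\mathrm{diag}(l_W/l_{W_g},\, l_W/l_{W_g},\, l_H/l_{H_g})$ applied to every
reference landmark, muscle point, wrap center and joint center (wrapping
radii scale by the mean in-plane factor, since an anisotropic $S$ has no
single radius factor); (3) ribcage-ellipsoid dilation - the base-ellipsoid
center is scaled by $S$ while its semi-axes are isotropically dilated by
the smallest positive real root of the resulting 6th-degree polynomial so
that the scaled TS/AI landmarks lie exactly on their ellipsoids (roots via
the companion-matrix method, real-root filter at $10^{-9}$, verified by
direct substitution to $10^{-10}$); (4) optional glenoid
inclination/version adaptation with Rodrigues operators about the scapular
y and z axes - applied iteratively, because the two plane projections
interact and a single pass cannot hit both targets to the enforced
$10^{-6}$ degree round-trip; the rim points rotate together with the
glenoid center so that re-measurement stays consistent with the adapted
cone; (5) PCSA scaling by the ratio of the subject's BMI-based muscle
percentage to the generic model's, with subject-specific overrides taking
precedence.  Clavicle and scapula gyration radii are not covered by the
predictive equations and come from schema defaults (0.12/0.28 of clavicle
length; 0.22/0.30/0.22 of scapula length).

For the generic subject (male, 1.86 m, 85.5 kg) these equations give an
arm mass of 3.5055 kg (2.9925 kg for a female of identical size), an
arm-mass sensitivity of 100/85.5 = 1.17% per kg, and muscle percentages of
77.67% (male) and 67.36% (female) at BMI 24.71 - the generic muscle
percentage is itself taken from the male equation at the generic BMI.
After scaling, the model's stored anthropometry becomes the subject's, so
body-weight-normalized outputs use the subject's weight.

## The synthetic anatomy

The generator emits a deterministic, anatomically plausible right upper
limb: skeleton landmarks proportioned from standard anthropometric ratios
at the requested stature (default 1.86 m), 42 muscle groups of which 14
span the elbow, two wrapping obstacles (humeral-head sphere, radius
2.7 cm; elbow-condyle cylinder, radius 2.2 cm), a glenoid built at exactly
the requested inclination (default $7^\circ$, version 0), and a deep
thoracic-core base ellipsoid whose TS/AI dilations remain positive for any
scaling in $[0.5, 2]$.  Rotator-cuff PCSAs default to 20.84 / 33.32 /
35.68 / 6.80 cm$^2$ (supraspinatus / infraspinatus / subscapularis /
teres minor) so that a 50% degeneration scenario lands on 10.42 / 16.66 /
17.84 / 3.40 cm$^2$.

Three passive ligaments (coracoclavicular, acromioclavicular capsule,
costoclavicular) are included as tension-only strings with negligible
objective weight.  They are not an optional nicety: the muscle set alone
cannot equilibrate the acromioclavicular torques at extreme elevation, and
ligament elements are standard in shoulder models for exactly this role.

The built-in abduction generator produces a scapular-plane elevation
(plane $30^\circ$ anterior of frontal) with a minimum-jerk profile,
a linear 2:1 glenohumeral:scapulothoracic rhythm (clavicle carrying 0.7 of
the scapulothoracic share), a humeral external-rotation schedule of 0.17
times elevation (about $26^\circ$ at $150^\circ$, inside the reported
physiological range - elevation beyond $\sim 120^\circ$ is impossible
without external rotation), and a least-change Gauss-Newton projection of
the clavicle/scapula coordinates onto the two ellipsoid constraints at
every frame (residuals $< 10^{-12}$).  The rhythm parameters were fixed on
plausibility grounds: JRF onset around 270 N at $20^\circ$, a smooth rise
to a peak near 80% body weight around $110^\circ$, and feasible load
sharing over the whole $20-150^\circ$ range.

What the generator does **not** emulate: real bone surfaces (landmarks and
analytic obstacles only), measured scapulohumeral rhythms, soft-tissue
artifact in the exported marker motions (noise is isotropic Gaussian),
muscle force-length/velocity properties, co-contraction beyond what the
stability cone induces, and translation of the humeral head.  Passing
tests therefore demonstrate internal consistency of the machinery and
trend-level physiological plausibility - not fidelity to any individual's
anatomy or to in vivo recordings.

## Numerical choices and degenerate inputs

* Finite-difference steps: $10^{-6}$ rad (Lagrangian gradient),
  $10^{-5}$ rad (tendon excursion); trajectory derivatives by central
  differences with one-sided second-order stencils at the ends.
* Frame constructions fail loudly on collinear or coincident landmarks;
  wrap solvers reject endpoints inside the obstacle, naming the muscle.
* The landmark fitter (Levenberg-Marquardt on all 11 coordinates with the
  constraints in penalty form, weight $10^4$) warm-starts each frame from
  the previous solution and skips frames with fewer than four finite
  landmarks, with a warning.  A mid-clavicle marker is included in the
  synthetic marker set because two collinear clavicle markers leave the
  clavicle roll unobservable.
* Simulation sizes used by the test suite: 131-frame abduction sweeps for
  six subject scenarios in the acceptance battery, 201 frames for the
  energy-consistency check, 15-frame trajectories for per-frame unit
  tests.  These sizes make the whole suite run in well under a minute
  while keeping finite-difference errors at the documented levels.

## Known limitations

Fixed carrying angle; ideal ball/hinge joints with no translations; a
single-obstacle-per-gap wrapping algorithm (no ellipsoid or multi-obstacle
wrapping); equal splitting of PCSA across strings of a group; diagonal
inertia blocks (parallel-axis terms drop off-diagonal components); the
standard load-sharing objective underestimates co-contraction, and the
EMG-assisted variant is out of scope.
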