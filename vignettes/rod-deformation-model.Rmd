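---
title: "An elastic-rod model of sagittal spinal shape and 3D scoliotic deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An elastic-rod model of sagittal spinal shape and 3D scoliotic deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinerod)
```

## The question and the model

Adolescent idiopathic scoliosis (AIS) is a three-dimensional deformity of a
spine that, seen from the side, started as a planar S-shaped curve.  A
long-standing biomechanical hypothesis holds that the *shape of the sagittal
profile itself* — how the kyphotic (thoracic, posteriorly convex) and
lordotic (lumbar, anteriorly convex) segments divide the spine, and where
the inflection between them sits — predisposes some spines to twist out of
their plane under ordinary upright loading.

`spinerod` tests this hypothesis *in silico* with a deliberately reduced
mechanical model.  The spine is a slender, initially curved, linearly
elastic rod: no vertebrae, discs, ribs or muscles, just a centerline with
bending, torsional and axial stiffness.  The rod is given the sagittal
geometry of a spinal subtype, loaded with the gravitational force carried
at each vertebral level, perturbed with a small axial torque representing
the slight asymmetry of trunk-weight distribution, and brought to static
equilibrium with a geometrically nonlinear finite-element solver.  The
three-dimensional shape that equilibrium takes — how far and in which
direction the rod leaves its sagittal plane — is then quantified and
compared across subtypes.

Everything is dimensionless: lengths in units of spine height, with the
elastic and load parameters forming a consistent model-unit system.

## Synthetic sagittal profiles

No patient geometry ships with the package; a generator produces the study
conditions.  A profile is a planar curve in the sagittal (Y–Z) plane through
17 vertebral centroids (T1–L5), isotropically normalized to unit height with
L5 at the origin, built from two arcs of opposite curvature:

* curvature is a positive sine bump over the lordotic (caudal) span and a
  negative sine bump over the kyphotic (cranial) span, vanishing at the
  join, so the curve has **exactly one inflection**, placed midway between
  the last kyphotic and first lordotic vertebra;
* the tangent at L5 is vertical (zero sacral slope — a stated
  simplification of the modelled system);
* the lordotic apex reaches `lordosis_amplitude` anterior of the L5 plumb
  line at the inflection, and T1 ends `kyphosis_amplitude` *posterior* of
  that plumb line.  The posterior inclination matters mechanically: it
  tilts the T1–L5 support line, which is what lets gravity react the
  applied axial torque (below).

The six default archetypes encode the clinically described subtype
structure: a short-kyphosis group (kyphotic segments of 6 and 8 vertebrae,
mid-thoracic inflection — the subtypes whose axial projection is
loop-shaped), a long-kyphosis group (kyphotic segments of 12, 10 and 13
vertebrae, thoraco-lumbar inflection — the lemniscate-projection subtypes),
and a non-scoliotic profile with the lowest inflection (13 vs 4 vertebrae)
and smaller amplitudes.  Amplitudes (0.025–0.055 of height) were fixed once
at values typical of unit-height spine curves, with 10–25% within-group
spread; they are configuration entries, not fitted quantities.

Noise-free generation is deterministic, and the inflection detector
recovers the generator's segment split exactly over the whole parameter
sweep (kyphotic length 4–13) — this generator/detector round trip is a
tested invariant.

## Loads

Gravity acts as concentrated nodal forces at the 17 vertebral nodes,
pointing down (−Z).  The per-level magnitudes follow a superincumbent
trunk-weight fraction profile rising monotonically from about 9% of body
weight at T1 to about 47% at L5 (a smooth fit to published trunk-segment
data of the kind used to load spine finite-element models); uniform and
linear-ramp schemes exist for sensitivity checks.  The total load is a
configuration scalar.

Its default, `8e-9` model units, was calibrated once against the elastic
constants of the rod: it is of the order of the pinned-column Euler load
`pi^2 EI ≈ 7.75e-9`, produces maximum displacements of 1–8% of the height
across the archetypes (moderate deformation — the regime where patterns,
not magnitudes, carry the information), and leaves the factor-two load
sweep used in the robustness analysis below the in-plane limit point near
`2e-8`, beyond which a load-controlled static solve has no equilibrium to
find.

The axial torque is specified as a peak torsional shear stress of
magnitude `1e-4` (pressure units) and converted through the section modulus
of the circular cross-section, `M = tau * pi * r^3 / 2 ≈ 1.57e-13`.  Reading
the perturbation as a stress is the only dimensionally consistent
interpretation that keeps it *small*: taken as a moment, `1e-4` against a
torsional rigidity `GJ ≈ 6e-10` would wind the rod by ~1.6e5 radians, and
no static equilibrium of that kind exists.  The sign convention is fixed
package-wide: the anatomical frame has X to the subject's left, Y anterior,
Z up, and the torque handedness in this frame is negative about +Z,
matching a right-thoracic cohort.  Flipping the sign mirrors every
out-of-plane result exactly (a tested solver property).

## The finite-element core

Each rod is meshed into 2-node corotational beam elements (4 per vertebral
interval by default), with cubic-spline interpolation of the centroid
polyline.  Each element carries a local linear Euler–Bernoulli bending
stiffness about both section axes, Saint-Venant torsion and engineering
axial stretch, all measured in a corotated frame that follows the element
chord and the mean of the two nodal rotation triads.  Nodal rotations are
stored as full rotation matrices updated multiplicatively, so large
rotations are represented without approximation; initial curvature lives in
the per-element reference frames, making the undeformed state exactly
stress-free.

The tangent stiffness is the exact Jacobian of the discrete internal force,
obtained per element by central finite differences consistent with the
multiplicative rotation update.  Newton's method therefore converges
quadratically on the discrete equations.  Three closed-form validations pin
the element down (all tested at the default mesh): axial settlement
`F L / EA` (to 0.5%), cantilever tip deflection `P L^3 / 3EI` (to 1%), and
Saint-Venant end twist `T L / GJ` (to 1%, and linear in length).

Boundary conditions follow the modelled load case literally: all three
translations fixed at L5, the two horizontal translations fixed at T1
(which may settle vertically), and **every rotation free**.  A rod held at
two points can always rotate rigidly about the line through them; here that
mode is stabilized by gravity, because the support line is tilted (T1 is
posterior to L5) so rotating the hanging rod about it raises its weight.
This stiffness exists only once gravity is applied, which dictates the load
schedule: the solver ramps the gravitational system to full over the first
half of the increments with the torque off, then ramps the torque with
gravity held (20 increments in total by default).  Newton increments are
trust-region limited (nodal rotation increments capped at 0.3 rad) for
robustness along the soft support-line mode.

Numerical tolerances: the Newton loop targets a relative residual of
`1e-9`; because the axial stiffness `EA` exceeds the bending stiffness by
the slenderness squared (~10^6), the attainable absolute residual is
bounded below by rounding of the axial force, and the solver accepts
convergence when the residual stalls below `1e-12 * EA / min(L0)` — a
displacement error orders of magnitude below every tolerance used in the
validations.  Solutions are stable to ~1e-11 relative under load-step
halving, objective under rigid rotation of the whole problem (to 1e-14),
and external work balances stored elastic energy to 0.2%.

Mesh density: the 1%-on-doubling convergence rule is already met at one
element per vertebral interval (0.45% maximum change across archetypes);
the default keeps four because the curvature-based shape metrics benefit
from sub-vertebral sampling and a solve still takes well under a second.

## Shape metrics

**Global torsion** is the arc-length-weighted mean of the discrete Frenet
torsion: for each interior quadruple of points, the signed right-handed
rotation of the osculating-plane binormal about the local tangent, summed
and divided by the arc length.  Two oracles pin it down: planar curves give
0, and a circular helix `(a cos t, a sin t, b t)` gives `b/(a^2+b^2)` (to
1% at 100 samples).  One numerical subtlety is essential: at a curvature
sign change of a nearly planar curve the binormal flips by ±π, an artifact
of the planar limit that would otherwise dominate the metric — indeed a
*planar* S-curve would return ~π instead of 0.  Joints whose discrete
curvature falls below 0.2 times the curve's median curvature are therefore
excluded (with an absolute floor of 1e-6 per unit height).  The factor 0.2
is the smallest that fully suppresses the artifact on planar S-profiles;
group-level torsion values are stable for dead-bands between 0.2 and 0.5.
In the pipeline the metric is evaluated on deformed centerlines, with group
values computed on the per-node average of the group members' deformed
curves.

**Axial classification** works on the top-view (X–Y) projection: if the RMS
deviation of the projected points from their best-fit line is below
`1e-6` of the curve height the projection is a `line`; otherwise the
projection is smoothed (3-point moving average) and the sign changes of its
signed planar curvature counted — none makes it a `loop` (the V-shaped
axial pattern), one or more a `lemniscate` (the figure-eight pattern).  For
deformed rods the classifier is applied to the normalized deformation
trajectory `(u_x, u_y)`.  The classification is invariant under rotation
about Z and uniform scaling (tested).

**Twist count** is the number of crossings of the original sagittal plane
by the deformed centerline: sign changes of `u_x` along the rod after
smoothing, with a dead band of `1e-8` of the height against numerical
chatter.  Constructed fields (half-sine, full sine, 1.5 sine) give 0, 1, 2
as required.

**Displacement ratio** is `mean(u_x) / mean(u_y)` over nodes — signed
means, so direction information survives.

**Deformation normalization**: before classification or correlation, every
displacement field is divided by its maximum `|u_z|`, so fields are
compared as patterns at a common vertical-deformation scale.

## Clustering and pattern correlation

Subtype stratification is k-means (with `stats::kmeans`, greedy seeding, 10
restarts, seeded RNG) on the concatenated `(x, y, z)` coordinates of
isotropically normalized centerlines, with the cluster count known a
priori.  On a 125-curve synthetic cohort (25 noisy copies of each of the
five subtype stand-ins, landmark jitter 1% of height) the generator labels
are recovered with best-permutation agreement 1.00; the tested acceptance
threshold is 0.95.

Pattern similarity between two solved models is the Pearson correlation of
their concatenated normalized displacement vectors (`3 × n_nodes` paired
observations), with the 95% CI from Fisher's variance-stabilizing
z-transform and a two-sided p-value from the t-statistic on `n − 2` degrees
of freedom (`stats::cor.test` supplies all three).  Operationalizing the
comparison of "3D deformation patterns" as a single Pearson r per model
pair is an interpretation — it is the only reading consistent with
reporting one coefficient with CI and p per pair — and correlating
*displacement fields* rather than deformed coordinates is likewise a
documented choice; the two are one flag apart in the implementation.

## What the default experiment shows — and what it does not

Running `run_experiment(default_config())` solves the six archetypes and
reproduces several qualitative features of the clinical subtype story:

* zero-torque solves remain exactly planar — the torque is what breaks the
  sagittal symmetry, and all 3D structure scales with it;
* the short-kyphosis group leaves the sagittal plane much more strongly
  than the long-kyphosis group (X/Y displacement ratios of 0.05–0.10
  versus 0.01–0.04 in magnitude), with the non-scoliotic ratio negative in
  the package's sign convention;
* within-group deformation patterns correlate very highly (r > 0.94), and
  the axial classes are invariant to halving or doubling the total load and
  to interpolating profiles within a group — pattern, not magnitude, is
  the stable outcome.

Equally important is what the synthetic conditions do **not** reproduce.
The archetypes are built only from the printed segment counts and
plausible amplitudes; they are not the patient-derived cluster-mean
geometries, whose finer features (cervicothoracic counter-curvature,
per-level spacing, within-cluster averaging) are unavailable.  Under every
physically consistent torque magnitude explored, all archetypes produce
*single-lobed* out-of-plane fields: axial class `loop`, zero
sagittal-plane crossings.  The clinically described distinction — one
twist and a loop for the short-kyphosis group versus two twists and a
lemniscate for the long-kyphosis group — does not emerge from this
two-arc profile family, and the group-averaged torsion of the
short-kyphosis group comes out opposite in sign to the long-kyphosis
group rather than matching it.  The between-group correlation contrast is
correspondingly weaker than in the clinical report.  These limits are
recorded, not patched: generator parameters and thresholds were fixed
before the pattern outcomes were scored and are not tuned toward them.

Passing the packaged tests therefore shows that the mechanics, the metrics
and the pipeline behave correctly and reproducibly on the synthetic family
— it does not by itself validate the clinical classification on real
spines.

## Key defaults

| Parameter | Default | Meaning |
|---|---|---|
| `young_modulus` | 1000 | Young's modulus, pressure model units |
| `poisson_ratio` | 0.3 | isotropic elasticity; `G = E/2.6` |
| `radius` | 1e-3 | section radius (slenderness 1000) |
| `total_load` | 8e-9 | total gravity force (~ Euler load) |
| `torque_stress` | −1e-4 | peak torsional shear stress of the perturbation |
| `n_sub` | 4 | elements per vertebral interval |
| `n_steps` | 20 | load increments (gravity, then torque) |
| `tol` | 1e-9 | relative Newton residual |
| `kappa_rel` | 0.2 | torsion curvature dead band (× median curvature) |
| `eps_line` | 1e-6 | line gate of the axial classifier (× height) |

## Known limitations

* Centerline-only mechanics: no Cobb angles or vertebral axial rotations,
  which require vertebral orientation information a rod does not carry.
* Static, load-controlled equilibrium: the solver cannot follow the
  response through the in-plane limit point near 2.5× the default load;
  post-buckling regimes would need arc-length continuation.
* Euler–Bernoulli kinematics: no shear deformation, contact, follower
  loads or material nonlinearity.
* The torque-reaction mechanism requires a posteriorly inclined profile; a
  perfectly balanced profile (T1 exactly over L5) makes the support-line
  rotation indifferent and the torque-loaded problem ill-posed under these
  boundary conditions.
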