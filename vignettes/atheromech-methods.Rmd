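---
title: "Methods: inverse plaque-stiffness estimation from deformation features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse plaque-stiffness estimation from deformation features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Atherosclerotic plaque vulnerability depends on the stiffness of the
lesion's constituents: a soft lipid-rich core behind a thin fibrous cap
is the classic rupture-prone configuration. Intravascular ultrasound
(IVUS) captures 2D cross-sectional contours of the vessel and, frame to
frame, the deformation of those contours over one cardiac pressure
increment — but not tissue stiffness itself. `atheromech` implements an
in-silico inverse workflow: simulate a large family of plaque
cross-sections under luminal pressure, extract the deformation features
an IVUS-type acquisition could measure, and train a regression network
that maps those features back to the Young's moduli of the lipid core
(`E_core`) and the fibrotic tissue (`E_plaque`).

The pipeline has five stages, each exposed as ordinary functions:

1. **Geometry** — idealized eccentric-plaque cross-sections over a
   factorial grid of stenosis ratio `SR` (40–80%, step 5), fibrous cap
   thickness (65–300 µm, 10 log-spaced values) and lipid-core thickness
   (300–800 µm, 6 values): 540 geometries. Moduli grids: `E_core` on
   1–100 kPa, log-spaced (denser at the soft end, where the clinical
   interest and the literature variability concentrate), and `E_plaque`
   on 390–1200 kPa with a fixed 90 kPa step.
2. **Forward model** — plane-strain hyperelastic inflation to 18.66 kPa
   (140 mmHg) in 28 increments of about 5 mmHg.
3. **Features** — relative lumen-diameter change `eps_theta`, relative
   cap and core thickness changes `eps_cap`, `eps_core`, extremal
   principal strains `eps1`, `eps2`, and `SR`, measured over the *last*
   5 mmHg increment (the 135–140 mmHg window an IVUS acquisition sees).
4. **Statistics** — p-value stepwise regression with a variance
   inflation factor (VIF) audit, motivating the pinned network input
   set {`eps_core^2`, `eps_cap^2`, `eps_theta^2`, `SR`}.
5. **Learning** — a 14-layer ReLU multilayer perceptron trained with
   Adam and a milestone learning-rate schedule, then adapted to
   non-idealized ("realistic") geometries by fine-tuning only its last
   four layers.

## Constitutive models and the forward solver

The lipid core and the fibrotic tissue (cap included) are isotropic,
incompressible neo-Hookean solids, `W = C10 (I1 - 3)` with
`C10 = E/6`; this one-parameter law is adequate at the small strains
(well under 1% per 5 mmHg window) the workflow operates at, and keeps
the inverse problem two-dimensional. The media and adventitia — whose
properties are not estimation targets because IVUS delineates them
poorly — use the two-fiber-family dispersed-collagen
Gasser–Ogden–Holzapfel (GOH) energy with literature parameters
(media: mu = 1.4 kPa, k1 = 206.16 kPa, k2 = 58.55, kappa = 0.29;
adventitia: mu = 8.44 kPa, k1 = 547.67 kPa, k2 = 568.01,
kappa = 0.26). Two conventions had to be fixed where the sources are
silent:

* the GOH isochoric term is implemented as `mu/2 (I1b - 3)` (the
  standard 2006 form);
* the mean fiber angle from the circumferential direction is not part
  of the published parameter set; it defaults to ±45° and is exposed as
  a configuration parameter of `goh_material()` — it is a package
  choice, not a literature value.

Incompressibility is enforced by the solver, not the material laws:
the energies use isochoric invariants (`I1b = J^(-2/3) I1`) plus a
volumetric penalty `U = kappa_bulk/2 (J - 1)^2`, integrated
selectively on the patch-averaged `J` of each quad pair — the classic
treatment that prevents volumetric locking of constant-strain
triangles. Selective integration leaves an in-patch volumetric
checkerboard mode unpenalized; in regions much softer than the
penalty (the lipid core) that mode has almost no curvature and can
stall the minimizer, so those elements additionally carry a small
element-level stabilization (0.2% of `kappa_bulk` by default,
configurable). Stiff regions carry none: an element-level penalty
there adds artificial stiffness that measurably pollutes convergence.
`kappa_bulk` defaults to 6e4 kPa; the volumetric state at the patch
integration points then stays within a fraction of a percent of
`J = 1` at full load (the test suite asserts the ±5% band), while
element-level `J` is reported separately as a diagnostic of the
oscillation the selective scheme tolerates. A much larger penalty
buys nothing: the displacement error contributed by residual
compressibility is already far below the discretization error, and
the preconditioner (below) rather than the penalty magnitude is what
governs solver effort.

The solver itself minimizes the total potential energy — strain energy
minus `P` times the enclosed deformed lumen area, which is the exact
potential of a uniform follower pressure on a closed boundary — over
the free nodal displacements. The minimizer is limited-memory
quasi-Newton (L-BFGS) with analytic gradients, preconditioned by the
Cholesky factor of a small-strain stiffness matrix (including the
penalty's rank-one patch terms, which are exactly the directions that
otherwise throttle quasi-Newton convergence). The preconditioner is
re-assembled from the deformed configuration at every pressure
increment: thin-walled mild-stenosis sections inflate by tens of
percent, where a reference-state metric goes badly stale and stalls
the iteration. This is the same family of schemes FEBio defaults to for
quasi-static hyperelasticity; a full Newton loop with a consistent
tangent would converge in fewer iterations but at a far higher
implementation and maintenance cost for these small 2D problems. Each
pressure increment warm-starts from the previous one, and increments
halve automatically (bounded) on non-convergence. The convergence
criterion is a gradient (residual) infinity-norm below 1e-3 of the
current pressure force on a typical boundary edge; at the default
meshes this bounds the displacement error near 0.02%, far below the 1%
verification tolerance.

Meshing is a boundary-conforming structured triangulation: rays from
the lumen center crossed with radial stations in five bands (inner
fibrotic band up to the cap/core interface, core band, outer fibrotic
band, media, adventitia), quads split into triangle pairs with
alternating diagonals. Rays are graded — denser over the core sector
and clustered toward the far axis point, where the feature nodes
live — and the ring counts per band are fixed relative to the
reference edge length rather than derived from each geometry's band
thicknesses, so every cross-section of a family shares one mesh
topology and discretization bias varies smoothly with the geometry
parameters instead of jumping whenever a band would gain a ring. The
cap is always resolved by at least three element rows. Outside the
core's angular extent the core band
degenerates; it is kept open as a thin fibrotic sliver so the grid
stays structured — the sliver carries the same material as the
surrounding tissue, so only the mesh, not the physics, sees it. The
element is the linear (constant-strain) triangle with the volumetric
penalty integrated on quad patches (the average of the two triangles'
`J`), the classic selective treatment that avoids volumetric locking.

Verification is against an independent closed-form solution: an
incompressible plane-strain layered cylinder, where `r^2 = R^2 + c`
reduces the kinematics to one constant and the pressure balance
`P = sum over layers of the integral of (sigma_theta - sigma_r)/r dr`
is evaluated by Gauss quadrature and inverted by root bracketing. The
finite element inner-radius displacement matches this oracle to
better than 1% at every 5 mmHg increment (about 0.2-0.4% at the
default verification mesh).

## Geometry construction choices

The sources fix the outer diameters (intima 5.596 mm, media 6.05 mm,
adventitia 6.5 mm), the nominal lumen (3.6 mm) and the base stenosis
ratio (70%), but not the rule that varies `SR`. The package keeps the
outer wall fixed and *solves* the lumen radius from the target `SR`
(plaque area = intima region minus lumen, per the area definition), so
the nominal lumen diameter is treated as descriptive rather than
binding — the printed base values are not simultaneously satisfiable
under any fixed-wall construction, and `SR` is the variable the method
actually conditions on. Eccentricity follows one rule: the healthy
(core-opposite) wall keeps a 0.25 mm thickness where space allows,
shrinking to a hard floor of 0.08 mm when the cap, the reserved core
space and a 0.05 mm clearance need the room; infeasible combinations
raise a constructive error naming the violated constraint. The
reservation uses the study's core-thickness ceiling (0.8 mm), not the
actual core, so the lumen layout — and through it every deformation
feature — depends only on stenosis ratio and cap thickness, never on
the core thickness; without this, core size would leak into the
features through the wall layout on top of its mechanical effect, and
the inverse problem would entangle a fourth latent variable. The lipid core is a
circumferential band concentric with the lumen at distance `cap_thk`,
spanning 60° with cosine-tapered (rounded) ends — the taper keeps the
cap thickness exactly defined over the core's extent while avoiding
sharp material corners.

The "realistic" family stands in for patient-derived IVUS contours,
which are not redistributable: every boundary of an idealized base
receives a smooth low-order cosine-harmonic perturbation (orders 2–4,
seeded), with amplitude capped at 15% of the thin-side wall thickness
so nesting can never break on the healthy side. Cosine-only harmonics
keep the mirror symmetry, so the same half-model solver applies. All
cap-thickness variants share one harmonic draw — the family is one
"patient" observed at 20 cap states — and the generator retries a
bounded number of times if a draw self-intersects. What this generator
does *not* emulate: true patient asymmetry (sine harmonics), multiple
cores, calcifications, and segmentation noise; transfer results on
this family therefore demonstrate the adaptation *mechanism*, not
clinical performance.

## The surrogate backend

The full factorial — 540 geometries × 300 × 10 material combinations —
is a cluster-scale campaign. For desk-scale work the package ships a
physics-based surrogate: each case maps to an equivalent concentric
layered cylinder (area-matched lumen radius from `SR`, the actual cap
thickness, a core layer that saturates smoothly toward its 0.55 mm
representative thickness as wall space allows, fibrotic remainder,
media, adventitia) solved in closed form at 135 and 140 mmHg; the
resulting features are corrected by smooth multiplicative factors
fitted, once, against 156 designed finite element solutions, with 20
seeded cases held out, and the frozen calibration ships as a JSON
artifact with the package. The correction model is a quadratic
response surface in centred stenosis ratio, log cap thickness, log
core modulus and fibrotic modulus — plus the healthy-wall thickness
implied by the eccentric placement rule, whose regime switch pure
polynomials cannot track — with a Gaussian kernel-ridge interpolant
on the residuals (bandwidth: median pairwise squared design distance;
ridge 1e-2, sized to absorb the ~1–2% solver noise rather than chase
it). Two modelling points deserve emphasis:

* In the incompressible cylinder the layer thickness changes are
  purely kinematic, so the raw cylinder features barely respond to
  `E_core`; the finite element model shows a clear deviatoric
  response of the soft core. The corrections therefore depend on the
  moduli as well as the geometry, which restores both fidelity and —
  critically — the invertibility of the feature-to-modulus map the
  inverse network relies on.
* The surrogate is defined on the *representative-core slice* of the
  family: its features carry no core-thickness dependence. The finite
  element model responds strongly to core size (a thicker soft core
  displaces stiff fibrotic tissue from the load path — up to a factor
  two in cap strain at mild stenosis), but three strain features
  cannot determine four independent latent influences; folding core
  size into the surrogate would make distinct cases collide in
  feature space and destroy the inverse problem. Calibration and
  holdout therefore both use 0.55 mm cores, the campaign's
  core-thickness column is carried for factorial bookkeeping but does
  not move the surrogate features, and surrogate features should not
  be read as FE predictions for other core sizes. The realistic
  family holds its core fixed, so the transfer experiments are
  unaffected. The shipped calibration's holdout agreement is recorded
  in the artifact and re-verified by the test suite on freshly solved
  FE cases from the same slice.

For perturbed (realistic) geometries the surrogate multiplies the
strain features by deterministic shape-modulation factors derived from
the local curvature radius of the lumen contour at the cap midpoint
relative to the equivalent circle: a locally flatter cap carries a
proportionally larger membrane strain (Laplace scaling). These factors
are part of the synthetic family's *definition* — they create the
domain shift that the transfer-learning stage then has to absorb, in
the same qualitative way real contours shifted the feature map in the
study this package reproduces.

## Statistics

The feature-selection machinery is deliberately conventional:
per-response ordinary least squares (via `lm`), two-sided t-test
p-values, adjusted R², and `VIF_j = 1/(1 - R_j^2)`. Stepwise selection
is bidirectional at a 0.05 significance level (the add/remove
narrative of the source procedure implies both directions), with one
deliberate refinement: the entry/stay level is applied family-wise
over the candidate pool (each test at `alpha/m` for `m` candidates).
Raw per-test screening at 0.05 admits a spurious predictor in about
`1 - 0.95^m` of pure-noise datasets — roughly a quarter, for nine
candidates — which defeats the purpose of selection; with the
family-wise rule the procedure recovers a single true predictor among
noise in ~99% of replicates and stays intercept-only under the null
in ~95%, while every selected predictor still has `p < 0.05` in the
final model. A `family_wise = FALSE` switch restores the raw rule.
The stepwise phase is followed by a VIF audit:
while any VIF exceeds the cap (default 10 — the conventional threshold;
the audit procedure, not the cap value, is the point), the worst
collinear pair loses the member whose removal leaves the higher
adjusted R². The network input set is *pinned* to
{`eps_core^2`, `eps_cap^2`, `eps_theta^2`, `SR`} so downstream models
are stable across re-simulated databases; `select_ann_inputs()` always
runs the data-driven procedure alongside and returns its log for
comparison. (The source material names the third squared feature
inconsistently — cap versus plaque subscripts in different places; this
package follows the input list stated with the final network, i.e. the
cap feature.)

## Network and training

The regressor is a 14-layer fully connected ReLU network: input 4,
twelve hidden layers, linear output 2. The layer count is fixed by the
architecture being reproduced; the hidden width is not stated there,
so it is a package choice — width 24, selected from a pilot grid over
conventional widths as the best accuracy-per-compute point on the
scaled-down database — and is configurable in `mlp_spec()`. The
training loop itself runs in a compiled (RcppArmadillo) kernel that
mirrors, step for step, the plain-R reference implementation shipped
alongside it; the test suite verifies the two paths agree to machine
precision, and the R functions remain the readable specification of
the algorithm. Inputs *and* targets are z-scored
with statistics from the training split only (80/10/10); the reported
mean-squared-error level of 1e-7 is interpreted on z-scored targets,
since an MSE of 1e-7 in raw kPa² would be physically implausible for
targets spanning three orders of magnitude. The moduli are
log10-transformed before z-scoring (configurable): the core modulus
grid is log-spaced over two decades, the accuracy metric of record is
the *relative* error — which is additive on the log scale — and a
raw-kPa squared loss would weight an error at 1 kPa ten-thousand-fold
less than the same relative error at 100 kPa, making uniform relative
accuracy unreachable regardless of network quality. Optimization is Adam
(0.9/0.999, eps 1e-8) at an initial rate of 1e-3 decaying tenfold at
epochs 500, 1000, 1500, 2000, 3500 and 5000, for 7000 epochs, no early
stopping; validation loss is recorded every epoch but only monitored.
The batch mode is mini-batch (256 by default): the milestone schedule
leaves little usable learning after epoch 2000, and full-batch updates
are too few to reach the loss floor, while smaller batches cost
dataset passes nothing but make many more optimization steps at the
productive learning rates. Initialization is the standard uniform
fan-in scheme, seeded; training is deterministic for a fixed seed and
thread configuration.

Transfer learning freezes everything but the last four layers and
re-trains them on a stratified half of the realistic family (stratified
over cap thickness and `E_core` decade so both halves span the ranges);
the other half is never touched during adaptation and serves as the
held-out evaluation. Fine-tuning runs Adam at the pre-training
starting rate (1e-3) for 8000 epochs, both configurable: with only
the tail trainable and about a thousand adaptation cases each epoch
is a handful of cheap steps, and pilot runs showed gentler budgets
(1e-4 for 1000 epochs) leaving the adaptation visibly unconverged —
roughly twice the held-out error of the default.

## Problem sizes and numerical defaults

The package's standard desk-scale experiment, used by the test suite
and the acceptance script, is: a 15,000-case idealized database
(60 geometries stratified over `SR` × 50 log-spaced `E_core` × 5
`E_plaque`, surrogate backend), the 14-layer width-24 network trained
for the full 7000-epoch schedule, and a 2,000-case realistic family
(20 cap variants × 20 × 5 materials) split 50/50 for fine-tuning and
evaluation. These sizes preserve the factorial structure and the
training protocol of the full-scale study while remaining reproducible
on a single workstation. Mesh defaults: target edge 0.2 mm (about 500
nodes on the half-model), at least two element rows through the cap;
verification meshes for the cylinder oracle use 0.15 mm.

## What this model family can and cannot recover

The two moduli are not equally identifiable, and the package is
explicit about it. The fibrotic tissue carries most of the load: its
modulus moves every deformation feature roughly in proportion
(log-log sensitivity near one), and the trained network recovers
`E_plaque` to well under 1% mean relative error on held-out idealized
cases and a few tenths of a percent after transfer. The soft confined
core is close to hydrostatic: varying `E_core` across its full two
decades moves the IVUS-window features by only a few percent (log-log
sensitivity around 0.05 in the finite element model — measured, and
the measurement is why the surrogate's modulus-dependent corrections
exist at all). Inverting so weak a signal amplifies every source of
fitting error by an order of magnitude or more. On the scaled-down
study this yields a mean `E_core` error around 6% on held-out
idealized cases and around 12% on the held-out realistic half after
fine-tuning — and a network trained from scratch directly on the
realistic adaptation half does *worse* (about 21%), which localizes
the limit in the physics of the feature set rather than in the
transfer mechanism; the relative improvement from fine-tuning (5-10x
over the unadapted network) is robust. Studies reporting sub-percent
core-modulus recovery from these four features imply a forward model
in which the core's stiffness imprints far more strongly on the
measured deformations than the mechanics implemented and verified
here produces. The validation-loss floor of the schedule sits near
4e-3 on z-scored log targets for the same reason.

Known limitations, beyond those already noted for the realistic
generator: 2D plane strain (no longitudinal stretch or residual
stress), a single lipid pool, no perivascular tethering, pointwise
pressure loading without fluid–structure interaction, and a surrogate
whose fidelity is verified against the package's own finite element
model — not against an external solver. The closed-form cylinder is
the independent anchor: it is derived and implemented separately from
the finite element code and pins the solver's accuracy wherever both
apply.
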