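---
title: "Methods: displacement-driven internal loads in plated metacarpal osteotomies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: displacement-driven internal loads in plated metacarpal osteotomies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the inverse-load idea

When a metacarpal shaft fracture is plated, the clinically decisive question
during early rehabilitation is how much load the fixation itself must carry
while the patient performs non-weight-bearing exercises (flexing a finger to
the palm, flexing the wrist). Those internal loads cannot be measured
directly. The inverse strategy implemented here replaces the fracture with a
defined 3 mm gap osteotomy bridged by a rectangular plate of known
stiffness; the measured rigid-body motion of the two bone fragments is then
imposed on a specimen-specific finite element model, and the load carried by
the plate is read off as the six section loads transmitted across a virtual
cut plane through the plate at the gap center. The primary outcome is the
out-of-plane bending moment `Mz` — the moment about the axis perpendicular
to the sagittal (flexion) plane — in N mm.

This package re-creates that pipeline at desk scale, with a synthetic
construct and a synthetic cohort standing in for the cadaveric experiment:

1. `metacarpal_construct()` — parametric construct geometry;
2. `mesh_construct()` — deterministic quadratic-tetrahedral mesh;
3. `solve_fe()` — small-strain linear elasticity with rigid screw ties;
4. `section_loads()` — free-body section loads at a cut plane;
5. `make_trajectory()` / `generate_cohort()` — calibrated synthetic trials;
6. `normalize_travel()` … `summarize_cohort()` — trajectory processing;
7. `analysis_gate()` — the statistics chain;
8. `safety_factor()` / `patch_stress_check()` — adhesive-patch assessment.

## Construct idealization

The two bone fragments are straight hollow tubes: a stiff cortical shell
(outer radius 4.5 mm, thickness 1.5 mm — a typical metacarpal mid-diaphysis
scale), a compliant trabecular lining on the endosteal surface (1 mm), and
an open medullary canal. The open canal is the anatomically sensible choice
at the mid-diaphysis, and it has a practical virtue: a structured polar
grid with a filled centre forces degenerate pie-slice elements at the axis,
while the hollow tube meshes into well-shaped annular hexahedra throughout
(the package enforces a minimum corner scaled Jacobian of 0.05 and rejects
meshes below it; all default refinement levels sit well above 0.1).

The plate is a rectangular envelope (24.25 x 4.25 mm; thickness is never
printed for the experimental plate, so it defaults to 1 mm and is exposed
as a parameter — all headline quantities are reported at the configured
value). Four bicortical screws sit at -10, -5, +5 and +10 mm from the gap
center. Screws are not meshed: each screw is a rigid kinematic tie group
collecting the bone nodes along its bicortical axis and the plate nodes on
its hole rim, condensed by the solver to a single 6-DOF rigid body
(master–slave elimination, no penalty or Lagrange parameters to tune).
This is the simplest contract that transfers load between plate and bone
through the screws; its known artifact — singular stresses at the tie rims
— is why the flexural stress check below evaluates the bridging span
between the innermost screws rather than the hole rims.

Materials are homogeneous per region by default (cortical 15 GPa,
trabecular 0.5 GPa, plate = PEEK 3.6 GPa with Poisson ratio 0.38, screws
titanium-like 110 GPa); these bone constants are implementation defaults at
a typical scale, not measured values. A density-to-modulus power law
`E = a * rho^b` (defaults a = 6850, b = 1.49, again implementation
defaults) is available for heterogeneous fields. Units are mm / N / MPa
throughout, so moments are natively N mm.

## Meshing

The mesher is an internal structured-to-tetrahedral subdivision, chosen so
that every mesh is bit-reproducible: hexahedral scaffolds (annular grids
for the bone, a box grid for the plate) are split into six tetrahedra per
hex around a fixed cell diagonal — a decomposition that is conforming on
any structured grid — and mid-edge nodes are added at exact edge midpoints,
so every element is an affine 10-node tetrahedron.

Edge-length parameters are interpreted as bounds on tetra edge lengths:
the scaffold pitch is set at most `max_edge / sqrt(3)` so that cell
diagonals respect the bound, the bone grid additionally solves the
diagonal budget `chord^2 + 2 h^2 <= max_edge^2` for its radial/axial pitch
(with the angular division count capped at 40 so annular cells never
become extreme slivers, and axial anisotropy capped at 4:1 against the
canal-wall chord). The refinement bound (`refinement_max_edge`, default
0.25 mm before scaling) governs the plate part and the bone's axial grid
in and around the plate. `scale_factor` multiplies all edge targets; the
default of 3 is the desk-scale operating point, and the convergence check
below is the guard on that choice. At `scale_factor = 1` the plate-region
tetra edges all fall at or below the 0.25 mm refinement target.

Screw holes are carved from the plate grid by a cell-centre test. When the
grid is coarse relative to the hole the rim nodes are snapped radially onto
the hole cylinder and the neighbourhood is relaxed by a few constrained
Laplacian iterations (otherwise volume conservation would fail at the
octagon level); on fine grids the staircase rim is already within
tolerance and snapping is skipped, which keeps element quality pristine.
Per-region mesh volumes agree with the analytic geometry within 2 % at
every default level.

## Solver and section loads

The solver assembles the standard isotropic small-strain stiffness with
4-point Gaussian quadrature (exact for the affine quadratic element),
eliminates tie groups to 6-DOF rigid bodies, applies Dirichlet conditions
by partitioning, and factorizes the reduced system with sparse Cholesky
plus one step of iterative refinement. Constrained DOFs match their
imposed values exactly; the free-equation residual is checked against
1e-8. The element is verified by a uniform-strain patch test (exact to
1e-10) and by a plate-only cantilever against the Euler–Bernoulli closed
form `P = 3 E I delta / L^3` (agreement within 5 %, actually ~2 % at the
default mesh).

Section loads are computed by free-body summation: the mesh is split at
the cut plane (elements by corner centroid — inside the gap the plane can
only cross plate elements, which the code enforces), the internal nodal
forces `k_e u_e` of one side's elements are assembled, and forces and
moments are summed over the interface nodes shared with the other side.
This is exactly equilibrated at the discrete level, so the proximal and
distal evaluations are componentwise negatives (observed ~1e-12) and the
force-couple transport law `Mz(x + dx) = Mz(x) - Fy dx` holds to the same
precision. The moment reference point is the plate cross-section centroid,
which makes `Mz` comparable with beam theory. A volume-averaged
stress-integration estimator over a thin slab is provided as an
independent cross-check at the ~10 % level; the free-body route is primary
because it is exact in the discrete sense.

The sign convention: flexion that puts the plate's outer (dorsal) fiber in
tension gives positive `Mz`. All cohort-level comparisons use magnitudes,
mirroring how the reference tables report nonnegative values.

## The prescribed motion

The proximal end face is pinned (all translations fixed; a
`single_point_pin` variant with transverse face guidance is exposed, since
a literal pin's rotational freedom cannot be resolved from a figure). The
distal fragment is driven by a rigid-body flexion rotation about the z
axis through the gap center at plate mid-height, i.e. the plate acts as
the hinge of the bridged osteotomy; an optional palmar translation can be
coupled per degree.

This mode was a deliberate design decision. A translation-dominant drive
(fragment shear) loads the bridging plate mainly in transverse shear and
membrane tension; the centroid-referenced gap-center `Mz` then becomes a
small difference of large internal loads, and calibrating the published
moment magnitudes to it requires fragment translations of several
millimetres — unphysical for a 3 mm gap — while driving patch stresses far
past any flexural strength. The hinge-flexion mode loads the plate in
near-pure bending (at one degree of flexion the default construct carries
Mz = 2.58 N mm with |Fy| < 1e-3 N), the published peak moments correspond
to 1–3.5 degrees of flexion, and the extreme-fiber stress closely follows
the beam formula `sigma = M c / I` — the regime in which a flexural
strength comparison is meaningful.

Because the model is linear, one unit solve parametrizes every loading
step; `moment_curve()` scales the unit section loads by the per-step
amplitudes, and doubling all moduli or all amplitudes doubles all loads
(verified properties).

## Synthetic cohort generator

The generator defines the study conditions: 5 hands (with the donor
covariate table), digits 2–4, two exercises, 5 trials per digit with
trials 3–5 retained (the first two emulate settling artifacts with a small
amplitude inflation), and the 4th digit of Hand 2 excluded — group sizes
15/15/12 per exercise.

Per (exercise, digit), a trajectory template stores the flexion-amplitude
profile over normalized travel. `calibrate_template()` inverts the forward
model so the resulting moment curve reproduces the reference per-step
means; with a linear model this is one unit solve plus scaling. Targets
are first projected onto the nondecreasing cone by isotonic regression
(PAVA): a flexion exercise cannot un-flex, and the single published curve
with a mild terminal dip (wrist flexion, 3rd digit) is flattened by less
than 1 %, well inside the 2 % round-trip tolerance. Fingertip-to-palm
profiles rise in an exponential-like convex way; wrist-flexion profiles
rise then plateau, and their template grid spans the analyzed first half
of travel, beyond which the profile continues with a mild (8 %) linear
overshoot emulating the overextended second half that the analysis window
discards.

Scatter has two components, split evenly in variance: a multiplicative
log-normal specimen (hand) effect with unit mean, drawn once per hand and
shared across its digits and exercises, and additive Gaussian trial noise
on the trial's overall amplitude scale. Both are parameterized by the
reference peak SDs, so the synthetic per-digit SDs land on the published
scale. The even split is a one-time modelling choice (real between-hand
and between-trial variability are of comparable magnitude in such
protocols); a consequence worth knowing is that the five shared hand
effects correlate the pooled cohort mean, so its true sampling scale is
comparable to the naive `SD / sqrt(42)` standard error — at the default
seed the pooled maxima recover the weighted targets within one such SE.
All randomness flows from one integer seed; identical seeds reproduce the
cohort bit for bit.

What the generator does **not** emulate: real marker noise and filtering,
inter-digit anatomical coupling, nonlinear gap closure or contact, and
specimen-specific geometry/density variation (all hands share the default
construct, scaled only by the stochastic effects). Passing tests therefore
validate the pipeline's mechanics and statistics on data with the study's
structure and magnitudes — they do not re-validate the cadaveric
measurements themselves.

## Trajectory processing

Travel is normalized to `s in [0, 1]` per trial. For wrist flexion only
the first half of travel is analyzed; the published per-step table spans
steps 0–1 for both exercises, which is only consistent with the half
window if the window is re-normalized onto the reporting grid — that
reading is the default (`renormalize_window = TRUE`), with the raw-window
alternative behind the flag. Curves are resampled onto the grid
{0, 0.2, …, 1} by linear interpolation (deterministic and
monotonicity-preserving; no smoothing, as none is described for the
source data); extrapolation is refused. The per-trial maximum is taken
over the analyzed window of the raw, not resampled, curve. Summaries
report mean ± SD per step and pooled per-trial maxima; both SD
conventions (sample n−1, population n) are available because the donor
table's printed descriptives use the population convention.

## Statistics chain

Implemented from the formulas, with base R and `car` as independent
cross-checks in the test suite: descriptives with both SD conventions,
paired t (outliers retained; incomplete pairs dropped), classic one-way
ANOVA, Welch ANOVA with Welch–Satterthwaite degrees of freedom, Levene's
test on absolute deviations from the group mean (median variant
available), and Games–Howell post hoc with pairwise Welch df and p-values
from the studentized-range distribution (`ptukey`; CI half-width
`q_crit * SE / sqrt(2)`). Shapiro–Wilk is the one wrapped test: base R's
implementation *is* the Royston AS R94 approximation, and re-implementing
it would add nothing but risk.

The gate logic: Shapiro–Wilk per group is reported only — non-normality
does not divert the chain, which proceeds with ANOVA on robustness
grounds; Levene at alpha = 0.05 decides between Welch + Games–Howell
(heterogeneous) and classic ANOVA (homogeneous). No named post hoc is
prescribed for the homogeneous branch, so the gate emits unadjusted
pairwise Welch t tests with an explicit warning rather than inventing a
procedure. Welch ANOVA's type-I error under a heteroscedastic null
(n = 15/15/12, SD ratio 3) sits inside the 95 % binomial interval of the
nominal 0.05 over 2000 simulations; Games–Howell's familywise error under
the same null stays at or below nominal.

Two degenerate conventions: identical groups return F = 0, p = 1 (flagged)
rather than 0/0, and a paired test with zero-variance differences returns
p = 1 when the mean difference is 0 and p -> 0 (flagged) otherwise.

## Safety assessment

`safety_factor()` is capacity over demand. The default capacities for the
light-curable composite patch are its published lowest (728 N mm) and mean
(1220 ± 300 N mm) failure moments from an ovine phalanx four-point-bending
model — a different bone and geometry, so every report carries that
cross-model caveat rather than attempting an adjustment. The default
required factor is 1 (pure pass/fail); with the pooled fingertip-to-palm
demand of ~6 N mm the conservative (lowest-capacity) factor lands above
100. `patch_stress_check()` solves the construct with the plate given the
patch's flexural modulus (6.6 GPa), scales to the demanded gap-center
moment, and compares the maximum principal stress over the bridging span
against the flexural strength (69 MPa), reporting the moment at which the
strength would be reached (linear scaling). At a rehabilitation-scale
demand of 10 N mm the span stress is ~14 MPa — far below strength — with
failure extrapolated near 51 N mm.

## Numerical choices and problem sizes

- Quadrature: 4-point Gauss for tet10 stiffness and stresses (exact for
  the affine element).
- Linear solve: CHOLMOD sparse Cholesky, one iterative-refinement step;
  under-constrained systems error out by name rather than warn.
- Default study mesh (`scale_factor = 3`): ~34k elements / ~170k DOFs,
  about a minute on one CPU for the single unit solve the whole cohort
  reuses. The convergence ladder used by tests and the acceptance script
  is `scale_factor` 12 → 6 → 3 (edge targets halving toward the
  refinement target); the gap-center `Mz` changes by ~1.9 % then ~0.5 %,
  comfortably inside the 5 % criterion.
- Tie capture tolerance: shank radius + 1e-6 mm; the structured grids
  place node lines exactly on each screw axis, so capture is exact by
  construction and validated (bicortical span, nonempty plate rim).
- Ties vs. Dirichlet overlap, conflicting prescribed values, non-monotone
  travel, zero total travel, extrapolated resampling, <5 recorded trials,
  zero-variance groups: all explicit errors, not silent repairs.

## Known limitations

- Linear kinematics: the prescribed flexion angles (up to ~3.5 degrees)
  are small, but the model would happily extrapolate beyond its validity
  if driven harder; there is no contact, so nothing stops the gap from
  interpenetrating under extreme inputs.
- Rigid screw ties overestimate local stiffness and make peri-screw
  stresses singular; screw-level load sharing is out of scope.
- The idealized tube geometry shares one construct across all hands;
  between-specimen geometric variation enters only through the stochastic
  scale effects.
- The capacity values for the adhesive patch come from a different bone
  and loading fixture; safety factors are ratios against that published
  benchmark, not predictions of in-situ failure.
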