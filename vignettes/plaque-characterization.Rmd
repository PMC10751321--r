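---
title: "In-silico inverse characterization of atherosclerotic plaque tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico inverse characterization of atherosclerotic plaque tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intravascular ultrasound (IVUS) shows the cross-section of a diseased
coronary artery from inside the lumen. Two frames taken a few mmHg of blood
pressure apart let elastography estimate a relative displacement or strain
field across the wall, and radial strain is the component such estimators
recover most reliably. The mechanical question behind plaque vulnerability —
how stiff is the fibrous cap, how soft the lipid pool, how large the stress
on the cap — cannot be read off the image; it has to be inferred by inverse
finite-element analysis: propose tissue properties, solve the forward
inflation problem, compare predicted and measured radial strains, iterate.

atheroIFEM implements that whole loop in silico. Because clinical plaque
contours from published patient studies are not publicly deposited, the
package generates parametric synthetic cross-sections that reproduce the
geometric regimes of real plaques (eccentric lumen, thin fibrous cap, one or
two lipid pools, optional calcification), simulates the IVUS measurement
from them with controlled noise, and runs two inverse characterizations
against those measurements.

## Forward model

### Geometry and mesh

`plaque_spec()` / `generate_plaque()` build closed polygonal contours: a
roughly circular outer wall and lumen (optionally perturbed by a smooth
low-order Fourier radial disturbance, seeded for reproducibility) and exact
elliptical inclusions. The fibrous-cap constraint — minimum lumen-to-lipid
distance — is validated, never silently repaired: an infeasible
specification raises a placement error. Coordinates are in mm with the
origin at the outer-contour centroid.

`mesh_plaque()` produces a conforming triangulation whose element edges
coincide with every tissue interface, so no element straddles two
materials. The triangulator is an in-package incremental Bowyer–Watson
Delaunay kernel over the resampled contour vertices plus a hexagonal
interior lattice; required contour edges missing from the Delaunay
triangulation are recovered by midpoint subdivision (which refines the
polyline without changing the geometry), elements are classified by centroid
point-in-polygon tests, and interior vertices get a few Laplacian smoothing
sweeps with an inversion guard. The mesh precondition
`target_edge_length <= min_cap_thickness / 3` guarantees at least three
element layers across every fibrous cap; `cap_element_layers()` verifies
this a posteriori by breadth-first search through the fibrotic element
adjacency graph.

### Elements and solver

Elements are 3-node linear plane-strain triangles with one-point
integration — the direct analog of the CPE3 element used for this class of
plaque model. The nonlinear solver is total-Lagrangian with an exact
consistent tangent, assembled vectorized across elements in sparse form.
The lumen pressure is a follower load (normal to the deforming lumen
surface), converted at 1 mmHg = 0.1333224 kPa. Rigid-body motion is removed
by pinning three outer-contour nodes nearest 0°, 120° and 240° from the
section centroid — equally spaced to minimize constraint-induced stress
artifacts; the analytic-oracle annulus studies instead use quarter-symmetry
rollers so that the constraint choice does not pollute the comparison.

Newton iteration runs under load stepping (default 10 equal increments to
the target pressure, relative residual tolerance 1e-8, 25 iterations per
step) with automatic step bisection on divergence, up to 6 halvings before
a hard failure that reports the last residual. Inside the inverse loop a
cheaper configuration (3 load steps, tolerance 1e-7) is used: the recovered
displacement increments are of order 1e-3 mm, far above the solver error at
that tolerance.

### Constitutive models

All moduli are in kPa, volumetric compliances in 1/kPa. Plane-strain
kinematics embed the in-plane deformation gradient into 3D with `F33 = 1`,
so `J = det F` and the invariants keep their 3D definitions.

* **Linear elastic** `(E, nu)` — used for calcifications (E = 5000 kPa,
  nu = 0.333) and for the linear characterization (nu fixed at 0.49 for
  soft tissues). Inside the finite-strain solver the linear law is extended
  as Saint Venant–Kirchhoff (quadratic in the Green strain); calcification
  strains are tiny, so the extension choice is immaterial there.
* **Neo-Hooke** `Psi = C10 (Ibar1 - 3) + (1/D1)(J - 1)^2` — lipid pools and
  the ground-truth fibrotic tissue of the linear study. The conversions
  `C10 = E / (4(1+nu))` and `D1 = 6(1-2nu)/E` (and their closed-form
  inverse) connect the model to linear constants.
* **Gasser–Ogden–Holzapfel**
  `Psi = (1/D)(J-1)^2 + mu (Ibar1 - 3) + k1/(2 k2) * sum_i [exp(k2 Ei^2) - 1]`
  with `Ei = kappa (Ibar1 - 3) + (1 - 3 kappa)(Ibar_i - 1)` — the fibrotic
  tissue of the nonlinear study, with `D = 0.005` 1/kPa and
  `kappa = 0.3333` fixed (isotropic fiber response; the fiber directions
  are then inert, which the tests verify exactly).

Two notational points deserve care. First, the deviatoric parts are written
here with the isochoric invariants `Ibar = J^(-2/3) I`. A formulation using
the raw invariant `I1` in the deviatoric term produces a spurious
hydrostatic stress `2 C10 I` in the undeformed state (the energy is not
stationary at the identity unless the volumetric term cancels it), which
breaks the zero-stress-at-identity property and visibly corrupts
low-pressure inflation solutions; the isochoric split is also the
convention whose small-strain limit the E/nu conversions above linearize
(shear modulus `2 C10`, bulk modulus `2/D1`). Second, the exponential
bracket squares the full combination `kappa (Ibar1 - 3) +
(1 - 3 kappa)(Ibar_i - 1)` rather than the canonical dispersed-fiber
`kappa Ibar1 + (1 - 3 kappa) Ibar_i - 1`; at `kappa = 1/3`, the value used
throughout, the two differ only by the 1/3 scaling of the `(Ibar1 - 3)`
term, which is absorbed into the fitted `k1, k2`. Users fitting `kappa <
1/3` should be aware the package keeps the first form.

The uniaxial behavior curve `uniaxial_curve()` (incompressible uniaxial
tension, default stretch range 1–1.3 with 100 points — configurable, chosen
to cover the physiological regime the inflation probes) is the model-free
summary used to compare recovered and true fibrotic tissue: different GOH
parameter triples can produce nearly identical curves, so parameters are
never compared directly.

## Simulated IVUS measurement

`simulate_frame_pair()` inflates the zero-pressure plaque to the two frame
pressures (default 110 and 115 mmHg) in one continued solve and records
what a displacement estimator would deliver: nodal coordinates of the
lower-pressure frame plus relative displacements to the upper frame, on
ground-truth correspondence (speckle tracking itself is out of scope).
`frame_strains()` evaluates infinitesimal strains of the increment on the
lower-pressure configuration; the cylindrical origin is the lumen centroid
of that frame (the reference never states a cylindrical origin; the lumen
centroid is the natural catheter-centered choice).

`add_noise()` models measurement noise as additive white Gaussian on the
Cartesian strain components, per-component variance
`mean(signal^2) / 10^(SNR/10)` with SNR = 20 dB by default. The noise is
applied to the Cartesian tensor only; cylindrical, principal and equivalent
components are recomputed afterwards so every rotation identity holds on
noisy fields too. The SNR is defined per component (and therefore also
jointly); `measure_snr()` verifies the contract. Noising strains (rather
than displacements) matches how the measurement is used; a displacement-
noise variant can be built by perturbing `rel_disp` directly.

What the generator deliberately does **not** emulate: ultrasound image
formation and speckle, displacement-estimator bias and spatial correlation
of its errors, segmentation error (tissue labels are ground truth),
residual stress, 3D effects, and intra-tissue heterogeneity. Passing the
recovery tests therefore demonstrates the soundness of the inverse
machinery under the stated noise model, not clinical-grade performance.

## Inverse characterization

Both pipelines minimize the radial-strain NRMSE, in percent:
`J0 = 100 * RMS(err_meas - err_model) / |mean(err_meas)|`. Radial strains
under inflation are predominantly negative, so the unsigned mean keeps J0
positive; J0 is invariant under common rescaling of both fields and zero
iff they agree.

The optimizer, `gss_minimize()`, is a Generating-Set-Search pattern search
operating in range-normalized coordinates: every parameter is affinely
mapped to [0, 100], so a poll step moves each raw parameter in proportion
to its search range — parameters with wide ranges (k1 spans [5, 1e5] kPa)
get correspondingly more relevance, and the poll mesh sizes quoted below
are percentages of range. Each iteration polls the 2d coordinate directions
opportunistically; a successful poll doubles the mesh (capped at 100 — a
step beyond the full range is meaningless), a failed full poll halves it.
Three refinements from the pattern-search literature matter in practice
and are deliberate choices. Evaluated points are cached — clamped polls at
the box boundary otherwise re-evaluate the same point repeatedly. The
direction order is dynamic: the last successful direction is polled first,
which behaves like a line search along the dominant parameter. And mesh
expansion requires sufficient decrease: a poll step expands the mesh only
when it improves the cost by more than the forcing function
`forcing * (mesh/100)^2` (default `forcing = 5`, cost units, i.e. a few
tenths of a percent at mid-size meshes — small against the roughly 12%
noise floor J0 carries at 20 dB); improvements below the threshold are
still banked but contract the mesh. Without this rule, hundredth-of-a-
percent gains along weakly identifiable parameters (a calcification
modulus, a lipid volumetric compliance) keep re-expanding the mesh and the
budget runs out before the fiber stiffness k1 — the parameter that
dominates both the strain misfit and the behavior curve — is ever polled
at the mesh size its refinement needs. Cost-function failures at a poll
point (solver divergence, inverted pull-back candidates) count as infinite
cost and never abort the search. Termination: cost below `cost_tol`
(default 1e-4 in fractional form, i.e. J0 < 0.01%), mesh below `mesh_tol`,
an evaluation budget (the primary, hardware-independent budget), or an
optional wall-clock budget.

**Linear pipeline** (`characterize_linear()`): one effective Young's
modulus per tissue; Poisson ratios fixed (0.49 soft, 0.333 calcification);
the forward model is a single 5 mmHg linear increment on the imaged
configuration, so each cost evaluation is one sparse solve (per-tissue unit
stiffness matrices are precomputed and scaled, since K is linear in E at
fixed nu). Initial poll mesh 1. Modulus search ranges: fibrotic
[390, 1200], lipid [1, 100], calcification [500, 10000] kPa. The recovered
modulus is the secant stiffness at the working pressure, not a material
constant. Accuracy per tissue is reported as the success rate
`sr = 100 (1 - |E_real - E_est| / E_real)` when ground truth is supplied.
Calcification moduli are expected to be weakly identifiable (strains in a
stiff inclusion are tiny); a post-fit profile sweep flags tissues whose
modulus moves J0 by less than 1%.

**Nonlinear pipeline** (`characterize_nonlinear()`): fibrotic GOH
(C10 in [1, 50], k1 in [5, 1e5], k2 in [1, 100]), lipids Neo-Hooke (C10 in
[0.1, 100], D1 in [0.005, 0.9]), calcifications linear (E in [500, 10000]).
Each cost evaluation runs three forward solves: a Pull-Back step at fixed
recovery factor K = 1 on the imaged geometry, then inflation of the
zero-pressure candidate to both frame pressures (continued solve), then J0
of the model's relative radial strains against the measurement. The
initial poll mesh is 100 — full-range jumps first, because the GOH cost
landscape has local minima. After termination, the full Pull-Back with
free K runs once with the best materials to produce the final zero-pressure
geometry. Fit quality is reported as the behavior-curve R² per fibrotic
tissue when ground truth is supplied.

## Pull-Back zero-pressure recovery

Imaged geometry is a loaded state; hyperelastic analysis needs the
unloaded one. The Pull-Back algorithm inflates the imaged geometry by the
imaging pressure, collects nodal displacements `u`, and forms the candidate
`X_zp = X - K u`. Imposing `-K u` as a displacement boundary condition on a
copy of the geometry produces exactly this configuration, so the direct
coordinate update is used. Inside the inverse loop K is fixed at 1 (one
displacement solve per material iterate — the cost-saving choice);
`pullback_optimize()` afterwards minimizes the re-pressurization rms over
K in [0.5, 1.5] by golden-section search (tolerance 1e-3 on K, or an rms
plateau of 1e-4 mm). The bounds and tolerances are package decisions — no
reference values exist for them; K = 1 sits centrally in the bracket and
candidates with inverted elements are rejected with the offending element
ids. The one-parameter family cannot represent the true unloaded state
exactly (the error is second order in the displacement), which is why the
recovered-radius contract in the tests is 0.5% of the outer radius rather
than machine precision.

## Numerical choices and degenerate inputs

* In-circle tests in the Delaunay kernel use circumcircle distances with a
  relative epsilon; the hexagonal interior lattice avoids the co-circular
  degeneracies of square grids. The kernel is not a robust-predicate
  implementation; it is specified for the well-spaced point sets the
  mesher feeds it.
* `nrmse_cost()` rejects a zero-mean reference field (degenerate
  normalization) rather than returning Inf.
* `add_noise()` rejects zero-power fields; `snr_db = Inf` is the documented
  "noise off" sentinel, and `measure_snr()` returns Inf for identical
  fields.
* `strain_fields()` rejects elements whose centroid coincides with the
  cylindrical origin (angle undefined).
* Ties in the golden-section bracket resolve toward the lower-K half
  (`f1 <= f2`), making the search deterministic.
* All stochastic components (contour noise, strain noise, randomized GSS
  starts, LHS) take explicit integer seeds and restore the caller's RNG
  state.

## Problem sizes

The default study plaque (outer radius 2 mm, lumen radius 0.9 mm offset
0.4 mm, one lipid pool, one calcification, 0.35 mm cap) meshes to roughly
1700–1800 elements at the standard edge length of one third of the cap
thickness — the size at which the full nonlinear recovery with a
150-evaluation budget completes in a few minutes on one core. The test
suite's bulk invariant audits use coarser surrogates (a few hundred
elements) over 100 seeds, and the analytic-oracle annuli use structured
crisscross meshes (each quadrilateral split into four triangles), a pattern
that behaves well for nearly incompressible plane strain, at 16 radial
layers. Paper-scale meshes (3000–8000 elements at ~0.06 mm edge) are
exercised once in the mesh tests.

## Known limitations

The pattern search is a local method run once per characterization; its
endpoint depends on the noise realization, and the k1–k2 trade-off in the
exponential term means distinct parameter triples fit the two-frame strain
data almost equally well. The behavior-curve R² of a single run therefore
varies from the high 0.8s to above 0.99 between noise draws even when the
strain misfit reaches its noise floor — the reason fits are compared on
curves, never on raw parameters, and the reason a production analysis
should repeat the characterization over several noise seeds.

2D plane strain overestimates stress magnitudes relative to 3D; residual
stresses and the opening-angle state are not modeled; tissues are
homogeneous per label; the displacement-formulated linear triangle locks
volumetrically as nu approaches 0.5 on unstructured meshes (the
quasi-incompressible settings used here keep the effect within the
documented oracle tolerances, and the structured crisscross pattern is used
where the comparison must be clean); and the measurement model omits
speckle-tracking physics entirely. The calcification modulus is reported
but should be treated as an order-of-magnitude classification, not an
estimate.
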