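---
title: "Heterogeneous biomechanical volumetric registration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous biomechanical volumetric registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tledreg)
```

## The registration problem

Image-guided interventions need the pre-operative image volume aligned to the
deformed intra-operative anatomy — not just the organ surface, but the
interior structures a surgeon actually cares about: tumors to resect and
vessels to avoid. A biomechanical deformable model predicts the volumetric
displacement field from the observed boundary interaction (here, plate
compressions of known position, direction and depth), so that every voxel of
the pre-operative volume can be mapped forward. The quality measure is the
target registration error (TRE): the Euclidean distance between predicted
and ground-truth positions of labeled landmarks, reported in millimetres and
split by surface vs internal (tumor / vessel) landmarks.

`tledreg` implements the full pipeline on segmented voxel data:

1. **Hexahedral meshing** directly from the labeled voxels — every
   foreground voxel becomes one 8-node element carrying one tissue label.
2. **A total-Lagrangian explicit-dynamics (TLED) finite-element solver**
   with compressible Neo-Hookean material.
3. **Split-vertex tissue–tissue coupling**: parenchyma–lesion interface
   vertices are duplicated, each copy reconstructed by moving least squares
   (MLS) from its own tissue, and tied by a penalty force.
4. **Data-driven estimation** of the two coupling coefficients from landmark
   ground truth.
5. **A coarse-to-fine scheme**: deform a coarse mesh at runtime and
   synthesize the fine-mesh microstructure from a precomputed
   detail-enrichment database.
6. **A synthetic phantom generator** so the whole pipeline is testable
   without any external data.

## Dynamics

The semi-discrete equation of motion is

$$\mathbf M \ddot{\mathbf X} + \mathbf D \dot{\mathbf X} + \mathbf F_{int}(\mathbf X) = \mathbf R$$

with lumped mass $\mathbf M$, mass-proportional damping
$\mathbf D = \alpha \mathbf M$, the assembled elastic force
$\mathbf F_{int}$, and the applied force field $\mathbf R$ (coupling forces
plus any external load; compression experiments prescribe displacements, so
$\mathbf R$ is usually just the coupling term). The total-Lagrangian
formulation refers all stresses and strains to the rest configuration, so
the shape-function derivatives — identical for every element of a uniform
grid — are precomputed once. Each step evaluates, per quadrature point, the
deformation gradient $F = I + \partial u/\partial X$, the second
Piola–Kirchhoff stress of the compressible Neo-Hookean material

$$S = \mu (I - C^{-1}) + \lambda \ln J \, C^{-1}, \qquad C = F^\top F,\; J = \det F$$

(derived from
$W = \tfrac{\mu}{2}(I_1 - 3) - \mu \ln J + \tfrac{\lambda}{2} (\ln J)^2$),
and scatters nodal forces through the rest-configuration derivatives. A
central-difference (semi-implicit leapfrog) update advances the free nodes;
prescribed nodes follow their boundary values exactly, ramped linearly over
`ramp_steps` to avoid transient crushing of the surface layer.

Registration uses the *equilibrium* of this damped dynamics: the run stops
when the largest free-node velocity component stays below
`equilibrium_tol` (default 2e-4 m/s) for `consec_steps` consecutive steps,
with at least `min_steps` steps taken so that a warm-started state cannot
be declared converged before the new loading has propagated.

### Material parameters

The defaults follow the physical phantom this emulates: Young's moduli of
2×10⁵ Pa (parenchyma), 10⁶ Pa (vessel) and 5×10⁶ Pa (tumor), all at
Poisson's ratio 0.49 — nearly incompressible soft-tissue surrogates. The
incompressible limit ν = 0.5 is rejected (λ diverges for this material
form). Mass density (default 1000 kg/m³) affects only the transient path,
never the equilibrium used for registration.

### Numerical choices

* **Quadrature.** Default is one-point (reduced) integration with
  perturbation hourglass control (stiffness `hourglass_coef` × μ ×
  V^{1/3} per mode), matching TLED practice and avoiding the volumetric
  locking that full integration exhibits at ν = 0.49. Full 8-point Gauss is
  available (`solver$quadrature = "full"`) and is what the patch and
  static-oracle tests use, since their linear-FEM references are fully
  integrated.
* **Stable time step.** dt = `dt_safety` × min(edge)/c with the
  dilatational wave speed c = √((λ+2μ)/ρ). The safety default of 0.2 is
  deliberately conservative: the master–slave condensation at the coupling
  interface amplifies effective nodal stiffness by the squared MLS weights,
  which erodes the homogeneous stability margin.
* **Selective mass scaling** (`solver$mass_scaling`, on by default): the
  density of stiffer elements is inflated so that every element shares the
  slowest dilatational wave speed. Equilibria are unchanged — mass enters
  only the transient — while the stable step grows by the tissue
  stiffness ratio (5× for the tumor/parenchyma pair above). Disable it for
  genuine dynamic studies (the momentum and energy tests do).
* **Damping.** α defaults to 500 s⁻¹, an empirical balance between ringing
  decay (rate α/2) and low-frequency creep (rate ≈ ω²/α) on organ-scale
  meshes; it is a convergence-speed knob, not a physical parameter.

## Heterogeneous coupling

Lesions (tumor, vessel) meet the parenchyma at internal surfaces. On the
voxel mesh those surfaces are the nodes shared by elements of different
labels. Each such node is split into a parenchyma-side copy `bp` and a
lesion-side copy `bq`. Both copies are *massless slaves*: they are never
time-integrated. Instead each is reconstructed every step by fixed MLS
weights over its own tissue's interior ("master") nodes,

$$bp_i = \Phi_{p,i}\, \mathbf P_i^{\Omega}, \qquad bq_i = \Phi_{q,i}\, \mathbf Q_i^{\Omega},$$

and the interpenetration gap $\delta_i = bp_i - bq_i$ generates the penalty
coupling force $f_i = -k_c\, \delta_i$, with $k_c$ the per-kind coefficient
(`k_tumor`, `k_vessel`, N/m). The force is spread over the support domains
by the same shape weights — the parenchyma side receives $f_i$, the lesion
side $-f_i$ — so the distributed field is exactly balanced (the weights sum
to one on each side). Because the restoring direction matters for
stability, the package fixes the convention that the side whose
reconstruction leads the gap is pulled back; action–reaction and the
gap-closing monotonicity in $k_c$ are both covered by tests. Element forces
that land on a slave corner are redistributed to that side's masters
through the transposed weights, the virtual-work-consistent completion of
the master–slave condensation.

The exact Signorini complementarity (gap ⊥ force) can only hold
approximately under a penalty law — by construction |f| = k_c |δ| — so
`verify_signorini()` reports the complementarity residual |f·δ| and the gap
magnitudes rather than enforcing them.

### MLS details

Shape functions use a linear basis (1, x, y, z), shifted to the query point
for conditioning, with a cubic-spline kernel of normalized distance. This
is the smallest basis with exact linear reproduction, which the coupling
relies on: at rest (and under any rigid translation) both reconstructions
return the shared rest position exactly, so the rest gap is identically
zero. Support domains take the nearest `target_nodes` (default 8)
same-tissue interior nodes, extended while coplanar; the support radius
grows by 1.3 (up to 5 times) when under-populated, and a still-singular
moment matrix is a hard error naming the vertex. Requiring lesions to be at
least 3 cells across guarantees interior support nodes exist.

One property worth knowing: the one-sided MLS reconstruction is an O(h²)
approximation of the interface kinematics. With identical materials and a
very stiff penalty, the split model therefore approaches the unsplit mesh
only as the grid refines — the consistency test runs at a resolution where
the difference is under 2%. At physically calibrated coefficients
(hundreds of N/m) the artifact forces are an order of magnitude below the
elastic force scale.

## Data-driven coupling-coefficient estimation

The two coefficients are estimated by minimizing the summed squared
residual between model-predicted and observed deformed landmark positions
over training compressions:

$$\hat k = \arg\min_{k_{t}, k_{v}} \sum_{\text{cases}} \lVert X_g - \mathcal K(k_t, k_v)\, X \rVert_2^2$$

where $\mathcal K$ is the full nonlinear forward simulation to equilibrium
(the only reading consistent with the dynamics above). The optimizer is a
7×7 logarithmic grid over [50, 5000] N/m followed by Nelder–Mead
refinement in log-parameter space from the best cell: the objective is
2-dimensional, every evaluation is a forward run, and derivative-free
search tolerates the solver-tolerance noise floor. Each training case keeps
its previous equilibrium as a warm start (with the ramp skipped), which
cuts the per-evaluation cost several-fold; the `min_steps` guard ensures a
warm start cannot short-circuit convergence detection. The default split
mirrors the five-compression protocol: three training, two validation.

## Coarse-to-fine scheme

The fine split-vertex model is accurate but costly; the runtime path
deforms a coarse mesh and synthesizes the fine detail:

* **Coarsening.** Fine cells are grouped into blocks; a coarse element
  exists iff its block contains foreground, and its label is the majority
  foreground label (ties prefer the lesion, tumor > vessel > parenchyma, so
  heterogeneity is not voted away). On the coarse mesh the tissues are
  *directly connected* with their own moduli — no splitting — which is also
  exactly the no-coupling baseline model when run with a single material.
* **Database build (offline).** For each compression condition, both models
  run to equilibrium. Every fine vertex (split vertices contribute one
  entry per side) is assigned to a coarse element by rest position (lowest
  element id on shared-face ties), and an 8-weight MLS shape set is fitted
  at its deformed position over the deformed coarse element vertices. By
  linear consistency the fit reproduces the fine equilibrium exactly at fit
  time, so the stored database is self-consistent to round-off (the audit
  tolerance is 1e-8 m); a fine vertex coincident with a coarse vertex gets
  interpolating weights so it follows that vertex exactly under any later
  deformation. Weights are stored at single-precision significance,
  positions in full precision, in a single JSON container with mesh/config
  hashes and the seed.
* **Runtime registration.** Deform the coarse mesh, look up the nearest
  stored condition — distance is a weighted sum of patch-centroid distance,
  direction angle and magnitude difference, ties broken by magnitude then
  record id — and apply that record's weights to the deformed coarse
  vertices. A single nearest record is used (no blending); interpolating
  between records is a possible extension.

## The synthetic phantom

No public dataset accompanies the physical phantom this package emulates,
so `generate_phantom()` builds one: a parenchyma ellipsoid with an embedded
tumor sphere and a vessel tube, labeled by analytic membership at voxel
centers (tumor > vessel > parenchyma precedence), with 25 landmarks — 11
sampled on the organ-surface boundary voxels and 14 on internal lesion
boundaries (7 tumor, 7 vessel) — and seeded, fully reproducible sampling.
The default grid is 16×8×12 cells at 5 mm (coarsened to 8×4×6), sized so
the full calibrate/enrich/register loop runs in minutes on one CPU; the
paper-scale grids (74×18×54 fine, 24×18×18 coarse) are supported but not
required by the tests. The vessel axis is aligned with voxel centers so its
discretized cross-section is 3 cells wide — the minimum for interior MLS
support nodes. Compression scenarios form the cross product of top-surface
patch positions × magnitudes (default 2–8 mm) × push orientations within a
20° cone of straight down; the paper-scale 5 × 50 × 20 grid is expressible
but tests use small grids. Ground-truth observations are model predictions
plus isotropic Gaussian landmark noise (σ configurable; 0.1 mm in the
acceptance pipeline).

What passing tests on this phantom do **not** show about real data: the
generator's ground truth comes from the same model family that is being
calibrated, so estimation tests measure identifiability and optimizer
correctness, not model adequacy; real tissue anisotropy, viscoelasticity,
contact with surrounding organs, segmentation error and scanner noise are
all absent. The headline TREs on the physical phantom are therefore not
reproducible here — the package's acceptance pipeline reports the TREs its
own synthetic study produces.

## Problem sizes and budgets

The shipped tests run the 16×8×12 phantom (≈600 elements, ≈200 interface
pairs), the 7³/3³ embedded-tumor block for coupling mechanics, a 21³ block
for the split-vs-direct consistency check, and a 12-condition enrichment
database (2 positions × 3 magnitudes × 2 orientations). A cold forward run
of the phantom takes on the order of a second; a full coefficient
estimation (49 grid cells + refinement, 3 cases, warm-started) a couple of
minutes.

## Known limitations

* Implicit integration, viscoelasticity, anisotropy and frictional contact
  are out of scope; boundary conditions are prescribed-displacement patches
  plus a fixed support band.
* The split-interface condensation is first-order consistent at the
  interface (see above); very stiff penalties on coarse grids overconstrain.
* Coarse-to-fine accuracy depends on the database covering the query
  conditions; a single nearest record is used, so errors grow midway
  between stored magnitudes (the held-out test quantifies this).
* NIfTI/NRRD support covers the common single-volume segmentation exports,
  not the full breadth of either standard; DICOM series are out of scope.
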