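# tledreg

Fast biomechanical volumetric registration of labeled organ volumes with
embedded lesions, for image-guided intervention research. Given a
segmentation (parenchyma / vessel / tumor), a compression scenario, and a
handful of landmark observations, `tledreg` predicts the full volumetric
displacement field — surface *and* interior — and evaluates it as a target
registration error (TRE).

The package is aimed at researchers prototyping biomechanical registration
pipelines: it runs entirely from segmented voxel data, needs no external
meshing tools, and ships a synthetic phantom generator so every stage is
testable without any scan data.

## The model

**Mesh.** A uniform hexahedral mesh is built directly from the voxels: each
foreground voxel is one 8-node element with exactly one tissue label, so
heterogeneity enters the model without any surface reconstruction.

**Dynamics.** Soft tissue follows total-Lagrangian explicit dynamics
(TLED),

```
M Ẍ + α M Ẋ + F_int(X) = R
```

with lumped mass, mass-proportional damping, and the compressible
Neo-Hookean stress `S = μ(I − C⁻¹) + λ ln J C⁻¹` evaluated against
precomputed rest-configuration shape derivatives. Registration uses the
damped equilibrium of this system under prescribed surface displacements.

**Tissue–tissue coupling.** Each vertex shared by parenchyma and lesion
elements is split into two copies, `bp` (parenchyma side) and `bq` (lesion
side). Neither copy is time-integrated: each is reconstructed every step by
moving-least-squares (MLS) shape functions over its own tissue's interior
nodes, and the penalty force

```
f = −k_c (bp − bq)        k_c in N/m, per lesion kind
```

ties the two sides together, distributed back onto both support domains by
the same MLS weights. The two coefficients (`k_tumor`, `k_vessel`; defaults
600 and 500 N/m) are *personalized*: `estimate_coupling_parameters()`
recovers them from deformed landmark observations by a log-grid search plus
Nelder–Mead refinement, each evaluation a full forward simulation.

**Coarse-to-fine.** For fast registration, the fine heterogeneous model is
run offline across a grid of compression conditions to build a
detail-enrichment database: per condition, an 8-weight MLS shape set maps
each fine vertex onto its coarse element's deformed vertices. At runtime
only a coarse direct-connection mesh is simulated; the fine microstructure
is synthesized as `x_j = Φ_jᵀ P_i` from the nearest stored condition.

## Worked example

```r
library(tledreg)

ph   <- generate_phantom()            # labeled 16x8x12 phantom + 25 landmarks
mesh <- build_hex_mesh(ph$volume)
model <- deformable_model(mesh)       # split-vertex heterogeneous model
#> <hex_mesh> 935 nodes, 624 elements, grid 16x8x12, spacing 5 x 5 x 5 mm
#>   elements: parenchyma 503, tumor 46, vessel 75

scen <- generate_scenarios(ph$volume, n_positions = 1, n_magnitudes = 1,
                           n_orientations = 1)[[1]]   # 5 mm top compression
st <- simulate_heterogeneous(model, scen, coupling_params(600, 500))
print(st)
#> <sim_state> 935 nodes, t = 0.06164 s (3606 steps), converged: TRUE
#>   max |u| = 0.005626 m, max |v| = 0.0001869 m/s

iface <- compute_coupling_forces(
  reconstruct_boundary_positions(model$interface, st$u), coupling_params(600, 500))
sprintf("max interface gap %.3f mm, max coupling force %.3f N",
        max(iface$gap) * 1e3, max(iface$f))
#> "max interface gap 2.362 mm, max coupling force 1.181 N"
```

The converged state says the 5 mm plate push produced up to 5.6 mm of
tissue motion; the interface report shows the penalty coupling transmitting
up to 1.2 N between parenchyma and lesions across a worst-case 2.4 mm
split-vertex gap (the gap scales as force / k_c — stiffer coupling closes
it, which is exactly what the coefficient calibration exploits).

How much does heterogeneity matter? Compare landmark predictions against a
homogeneous no-coupling model of the same mesh:

```r
emb  <- embed_landmarks(mesh, ph$landmarks)
pred <- predict_landmarks(model, emb, st)
base <- deformable_model(mesh, coupling = "homogeneous")
pred_b <- predict_landmarks(base, emb, simulate_heterogeneous(base, scen))
compute_tre(pred_b, pred)
#> <tre_report>
#>            group  n mean_tre_mm max_tre_mm
#>          overall 25   0.4053921  0.8799665
#>         internal 14   0.4503075  0.8799665
#>          surface 11   0.3482271  0.6116057
#>   internal-tumor  7   0.4179671  0.6018476
#>  internal-vessel  7   0.4826479  0.8799665
```

Ignoring the stiff inclusions displaces the predicted internal landmarks by
0.45 mm on average (up to 0.88 mm at the vessel) for this single moderate
compression — the error the heterogeneous coupling removes.
`tidy()` / `glance()` give the per-landmark and one-row versions of any TRE
report, and `autoplot()` plots it.

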