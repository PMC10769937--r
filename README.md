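# earalign

Non-rigid registration of a **complete** ex vivo middle-ear point cloud onto
**noisy, partial** in vivo point clouds, such as those reconstructed from
endoscopic optical coherence tomography (OCT). In vivo middle-ear scans are
shadowed by anterior structures, so the posterior ossicles (incus, stapes)
are sparsely visible and hard to interpret; registering a complete segmented
template (e.g. from micro-CT) onto the scan transfers anatomical context to
the clinical data. The package is aimed at researchers working on
image-based middle-ear diagnostics and, more generally, at anyone who needs
complete-to-partial non-rigid point-cloud registration with a fully
synthetic, ground-truthed test bed.

## Method

Registration runs in two stages. Stage one estimates a rigid transform
τ ∈ SE(3) and a sparse correspondence set σ = {(u, v)} between the template
P_exv = {x_i} and the target P_inv = {y_j} — either with a classical
geometric-descriptor matcher (voxel downsampling, normal-histogram
descriptors, mutual matching, RANSAC, trimmed-ICP polish) or with a
provenance *oracle* available for simulated data. Stage two refines the
aligned template through a hierarchical deformation pyramid: at level k the
current points are mapped to sinusoidal encodings

    Γ(p) = (sin(2^(k+k0) p), cos(2^(k+k0) p)),

and a small per-level regressor predicts a linearized rigid sub-motion
(w, v) per point, realized as the increment d = w × p + v. The regressor is
optimized per instance (Adam) on the correspondence-masked Chamfer loss

    CD(A, B) = 1/|A| Σ_x min_y |x − y| + 1/|B| Σ_y min_x |x − y|,
    L = CD(P̃_exv^σ, P_inv) + γ_k · mean ‖d‖²,

where P̃_exv^σ keeps only template points with a correspondence — this is
what stops the invisible part of the template from collapsing onto the
partial scan. Low frequencies at shallow levels express near-rigid motion;
deeper levels refine non-rigid detail. The final displacement field
φ_est(x) = τ(x) + φ_ndp(τ(x)) − x is reported in the original template
frame.

Because no public middle-ear point-cloud data exist, the package includes a
procedural simulator: a segmented parametric ear (canal-wall tube, membrane
disc, three articulated ossicle bodies), free-form-lattice shape variants,
articulated pose variants via forward kinematics, and partial-view
extraction with support-point visibility decay, depth occlusion of
posterior structures and bounded uniform jitter — with exact ground-truth
displacement fields throughout. Evaluation metrics are the Chamfer distance,
the mean displacement error MDE = mean ‖φ_est − φ_gt‖, a
structure-restricted landmark error, and the visible-points ratio
|P_inv| / |T̃|.

## Worked example

```r
library(earalign)

smp <- generate_sample(simulation_config(), seed = 42)
smp
#> <ear_sample: template 1100 pts, target 685 pts, visible ratio 0.623, mean |gt| 0.849 mm>

res <- register_c2p(smp$template, smp$target, backend = "oracle")
res
#> <registration_result [oracle]: 685 correspondences, mean |phi| = 0.818 mm>

evaluate_sample(res, smp, "demo")
#>   sample_id       mde   chamfer landmark_error visible_ratio
#> 1      demo 0.2091945 0.2679435      0.3945343     0.6227273
```

Reading the numbers: the simulated patient's anatomy differs from the
template by 0.849 mm on average (`mean |gt|`), and only 62 % of the variant
is visible in the simulated scan. The pipeline predicts a deformation of
comparable magnitude (0.818 mm) whose error against the ground-truth field
is 0.209 mm (`mde`) — a four-fold reduction over not registering at all —
with the deformed template lying 0.27 mm from the target in Chamfer distance
and same-structure landmarks off by 0.39 mm.

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/scripts/c2p-ear`): `simulate` writes a ground-truthed dataset,
`register` aligns a source/target PLY pair, `evaluate` produces a metrics
CSV.

## Package layout

- `R/core-geometry.R` — point clouds, SE(3) transforms, Procrustes fits
- `R/synthetic-ear.R` — template, lattice + armature simulation, partial views
- `R/stage1.R` — descriptor and oracle correspondence backends
- `R/pyramid.R` — sinusoidal encodings, per-level regressors, full pipeline
- `R/metrics.R`, `R/io.R`, `R/cli.R` — evaluation, serialization, CLI
- `src/nn.cpp` — exact nearest-neighbour and RANSAC kernels
- `vignettes/registration-methods.Rmd` — models, assumptions, parameters,
  numerical choices and known limitations
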