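# tpcfmesh

Spatial correlation analysis of curvature on triangular surface meshes,
for statistical shape classification of anatomical structures such as the
thoracic aorta.

## The problem and the method

Single-point curvature summaries (for example δK, the standard deviation of
the per-vertex Gaussian curvature) can tell a smooth organ surface from a
rough one, but they discard *where* the structural aberrations sit relative
to each other. `tpcfmesh` implements the **topographical pair correlation
function (TPCF)**: a pair correlation function of a per-vertex scalar field
evaluated on the surface itself, with distance measured as the minimum
number of mesh edges between vertices,

```
g(r) = ( 1 / Σ_k p_k² ) · Σ_i  (1 / n(r,i)) · Σ_{j ∈ shell(r,i)} p_i p_j
```

where `shell(r,i)` is the set of vertices whose minimum edge distance from
vertex `i` is exactly `r` (vertices reachable in fewer edges are excluded),
`n(r,i)` its size, and `p` one of four curvature metrics derived from the
principal curvatures κ₁ ≥ κ₂:

* Gaussian curvature `K = κ₁κ₂` (1/mm²),
* mean curvature `H = (κ₁ + κ₂)/2` (1/mm),
* shape index `S = (2/π)·arctan[(κ₁ + κ₂)/(κ₁ − κ₂)]` (dimensionless,
  in [−1, 1]),
* bending ratio `R = κ₂/κ₁` (dimensionless).

Counting distance in edges rather than millimetres deliberately removes
organ size from the descriptor; to make edge distances comparable across
subjects every mesh is first decimated to the same element count (5000
triangles by default) by quadric-error-metric edge collapse. `g(0) = 1` by
construction; on an ideal shape the curve plateaus at 1, while surface
perturbations drive it toward zero at a rate set by their spatial
frequency and a plateau set by their intensity.

The scalar feature extracted per mesh and metric is the area under `g(r)`
for `r = 0..30` edges; together with the mean radius (mm) it feeds a
linear support-vector classifier separating normal anatomy (label 0) from
pathology (labels 1 and 2: post-TEVAR without / with secondary
intervention).

The package provides every stage: mesh I/O (STL/PLY/OBJ/OFF), cleaning and
decimation, per-vertex principal curvatures by averaged shape operators,
the four metric fields with validity flags, BFS distance shells and the
TPCF, seeded generators for ideal/perturbed spheres, cylinders and
two-class synthetic cohorts, featurization, SVM classification, a
`run_pipeline()` driver and a command-line interface
(`inst/cli/tpcfmesh.R`).

## Worked example

```r
library(tpcfmesh)

sphere <- make_sphere(radius = 10, subdivisions = 4)
sphere
#> surface_mesh: 2562 vertices, 5120 faces
#>   area 12.551 cm^2, Euler characteristic 2

bumpy <- perturb(sphere, perturbation_spec(amplitude = 1.5, frequency = 6),
                 geometry = "sphere")

curve_ideal <- tpcf(sphere, "K", r_max = 30)
curve_bumpy <- tpcf(bumpy,  "K", r_max = 30)
round(curve_ideal$g[1:6], 4)
#> [1] 1.0000 1.0000 0.9999 0.9999 0.9999 0.9998
round(curve_bumpy$g[1:6], 4)
#> [1]  1.0000  0.6252  0.1797 -0.1001 -0.1976 -0.1713
c(auc_ideal = tpcf_auc(curve_ideal), auc_bumpy = tpcf_auc(curve_bumpy))
#>  auc_ideal  auc_bumpy
#> 29.9941297  0.9613114
```

The ideal sphere's Gaussian-curvature field is constant, so its TPCF stays
at 1 and the AUC is essentially the full window width (30). The perturbed
sphere decorrelates within a few edges — its curvature pattern alternates
in sign with the bump lattice — and the AUC collapses to about 1.

A synthetic two-class cohort (mildly textured versus strongly deformed
tubes, the stand-in for a healthy/pathological imaging cohort) is
classified from the shape-index AUC and the mean radius:

```r
cohort   <- make_cohorts(n_per_class = 10, seed = 7)
features <- build_feature_table(cohort, metrics = "S")
head(features, 3)
#>              id    auc_S mean_radius_mm label binary_label
#> 1 cylinder_0_01 28.85022       19.57449     0            0
#> 2 cylinder_0_02 29.66154       14.17541     0            0
#> 3 cylinder_0_03 29.70225       14.76609     0            0
evaluate_accuracy(features, metric = "S", folds = 5, seed = 7)
#> cv_accuracy: metric S, linear kernel, 5-fold accuracy 1.000 (folds: 1.00 1.00 1.00 1.00 1.00)
```

## Command line

```sh
Rscript inst/cli/tpcfmesh.R generate sphere --radius 10 --subdiv 4 --amplitude 0.5 --frequency 6 out.ply
Rscript inst/cli/tpcfmesh.R remesh --target-faces 5000 in.stl out.ply
Rscript inst/cli/tpcfmesh.R correlate --metric S --rmax 30 out.ply curve.csv
Rscript inst/cli/tpcfmesh.R pipeline --generate-cohorts --n 20 --seed 1 report/
```

## Package layout

* `R/mesh.R`, `R/mesh_io.R`, `R/decimate.R` — mesh container, formats,
  quadric decimation (C++ core in `src/`)
* `R/curvature.R`, `R/metrics.R` — principal curvatures and the K/H/S/R
  fields
* `R/tpcf.R` — distance shells, `g(r)`, AUC, finite-size cutoff
* `R/shapes.R` — synthetic spheres, cylinders, perturbations, cohorts
* `R/features.R`, `R/pipeline.R` — feature tables, SVM, end-to-end driver
* `vignettes/tpcf-methods.Rmd` — model, assumptions, parameter choices and
  limitations
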