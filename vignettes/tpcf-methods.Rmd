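---
title: "Topographical pair correlation functions on surface meshes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographical pair correlation functions on surface meshes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpcfmesh)
```

# The model

`tpcfmesh` treats an organ surface — here, the thoracic aorta segmented
from CT angiography, but any closed or open triangular mesh works — as a
graph whose nodes are mesh vertices and whose links are triangle edges,
carrying a per-vertex scalar field $p_i$ derived from curvature. The
topographical pair correlation function is

$$ g(r) \;=\; \frac{1}{\sum_k^N p_k^2}\;\sum_i^N \frac{1}{n(r,i)}
   \sum_{j}^{n(r,i)} p_i\, p_j , $$

where the inner sum runs over the *shell* of vertex $i$ at radius $r$: the
vertices whose minimum edge distance from $i$ is exactly $r$. Vertices
reachable in fewer edges are excluded, so the shells of a fixed source are
disjoint and $g(0) = 1$ identically — a built-in self check that the
implementation asserts. Sources whose shell at $r$ is empty contribute
zero to the outer sum; the per-$r$ count of contributing sources is kept
on the curve as a finite-size diagnostic.

Distance is counted in **edges, not millimetres**, on purpose: aortic
diameter alone is already a (crude) predictor of disease state, and the
point of this descriptor is to capture *shape* independently of size.
Because edge distance only means the same thing on meshes of equal
resolution, every mesh is decimated to the same element count before
analysis (5000 triangles by default). The normalization by $\sum p_k^2$
makes $g$ invariant under $p \to \alpha p$; the TPCF sees the spatial
*pattern* of a field, never its amplitude.

The classical pair correlation of condensed-matter physics correlates
density *fluctuations*; the definition above correlates the raw field, so
a constant field gives $g \equiv 1$ rather than $0$. That form is the
reference behaviour here. A `centered = TRUE` option subtracts the field
mean first, for users who want the fluctuation convention; it is off by
default.

# Curvature estimation

Per-vertex principal curvatures $(\kappa_1 \ge \kappa_2)$ come from the
standard shape-operator averaging estimator for triangle meshes: each
face's second fundamental form is fitted by least squares to the finite
differences of the vertex normals along its three edges (in the face's
tangent frame), and the per-face tensors are rotated into each vertex's
tangent frame and averaged with mixed-Voronoi-area weights (clamped for
obtuse triangles, the usual stabilization). Vertex normals are
angle-weighted face-normal averages. The sign convention is fixed so that
a sphere with outward-oriented faces has $\kappa_1 = \kappa_2 = +1/R$.

On an icosphere of radius 10 mm at subdivision 4 the estimates are within
2 % of $1/R$ at every vertex, and the error shrinks with refinement; on an
ideal cylinder lattice the estimator is exact to rounding
(`test-curvature.R` asserts both).

Four scalar metrics are derived:

| metric | definition | units | undefined at |
|---|---|---|---|
| $K$ | $\kappa_1 \kappa_2$ | mm$^{-2}$ | — |
| $H$ | $(\kappa_1 + \kappa_2)/2$ | mm$^{-1}$ | — |
| $S$ | $\tfrac{2}{\pi}\arctan\frac{\kappa_1+\kappa_2}{\kappa_1-\kappa_2}$ | — | flat points |
| $R$ | $\kappa_2/\kappa_1$ | — | $\kappa_1 \approx 0$ |

Singularities are handled by a per-vertex validity flag rather than by
imputing values: at curved umbilics ($\kappa_1 = \kappa_2 \ne 0$) the
shape index takes its continuity limit $\mathrm{sign}(\kappa_1)$; at flat
points it is flagged invalid, as is the bending ratio wherever
$|\kappa_1| < \varepsilon$ (default $10^{-8}$ /mm). Because one-ring shape
operators are biased on open boundaries, boundary and generator-marked cap
vertices are flagged invalid for every metric by default.

**Invalid vertices are removed from the vertex set before shells are
built**, not merely zeroed: a zero still occupies a slot in $n(r,i)$ and
would bias $g$ toward zero in an uncontrolled way. The TPCF of a field
with invalid vertices is therefore the TPCF of the valid-vertex subgraph.

The signed bending ratio is unbounded where $\kappa_1 \to 0^-$; an
optional magnitude-ordered variant (smaller-magnitude over
larger-magnitude curvature, giving $R \in [-1, 1]$) is available but off
by default, since the signed quotient is the reference definition.

# Meshing and decimation

Decimation is Garland–Heckbert quadric-error-metric edge collapse,
implemented in C++: plane quadrics accumulate per vertex, the cheapest
valid collapse is applied repeatedly, and the loop stops at *exactly* the
requested face count. Collapses that would break local manifoldness (link
condition) or flip a surviving face normal are rejected; boundary edges
contribute large penalty quadrics so open rims stay in place, which lets
the open synthetic cylinders (and any open clinical segmentation) be
decimated safely. A watertight genus-0 input keeps $V - E + F = 2$.

Two meshing policies are supported, mirroring the two ways a cohort can be
meshed: a constant element *count* (default, 5000 faces — the mode the
correlation analysis relies on) and a constant element *density*
(`density_face_target()`, faces per cm², for users who want element size
rather than element count fixed). The Hausdorff distance reported by
`decimate_to_count()` is a sampled vertex-to-vertex estimate, a cheap
diagnostic rather than an exact surface-to-surface distance.

The finite size of a mesh imposes a cutoff: mean shell size grows with
$r$, peaks, and collapses once shells start running off the far side of
the surface. On 5000-element meshes this collapse (below 10 % of peak)
happens beyond $r = 30$ edges, which is why the analysis window is
$r \in [0, 30]$ and `r_max` defaults to 30.

# Synthetic shapes and what they do (and do not) show

The generators produce icospheres ($20 \cdot 4^{s}$ faces, vertices on the
exact sphere) and grid-triangulated cylinders, plus two perturbation
families applied along vertex normals:

* **deterministic separable sinusoid** — amplitude $a$ (mm) times
  $\sin(f\theta)\sin(f\varphi)$ on the sphere or
  $\sin(f\theta)\sin(2\pi f z/h)$ on the cylinder, with integer mode count
  $f$. Amplitude 0 reproduces the ideal shape bit for bit. This is the
  default because it is exactly reproducible and exposes the two axes the
  TPCF responds to: intensity and spatial frequency.
* **random bumps** — a seeded superposition of $f^2$ signed Gaussian
  bumps, normalized so the largest displacement is $a$; a rougher,
  less structured alternative.

Calibration facts the test suite pins down: ideal spheres and cylinders
plateau at $g \approx 1$ (within 5–10 %) out to $r = 10$; the perturbed
sphere's $K$-TPCF plateau (mean of $g$ over $r \in [10, 20]$) moves
monotonically with amplitude at fixed frequency; the standard deviation of
the $K$ field grows with amplitude.

`make_cohorts()` builds a two-class benchmark standing in for a clinical
cohort of 37 non-pathological and 38 pathological aortas that cannot be
redistributed. Both classes are open tubes with radius
$\mathcal{N}(15, 2^2)$ mm and height $\mathcal{N}(200, 20^2)$ mm — scales
typical of an adult thoracic aorta — decimated to 5000 elements, with all
jitter distributions shared between classes so that with amplitudes
$(0, 0)$ the classes are statistically identical. The classes differ only
in their perturbation regime:

* class 0 ("healthy"): fine-scale texture — modes 8–12, amplitude 0.3 mm;
* class 1 ("pathological"): coarse bulges — modes 4–6, amplitude 2.0 mm,
  the analogue of aneurysmal or dissected wall deformation, optionally
  with a circular-arc centerline bend (`bend`, off by default).

The frequency contrast matters and is not cosmetic: since the TPCF is
amplitude-invariant and the Gaussian curvature of an ideal cylinder is
zero, the $K$-parameterized TPCF of a perturbed tube responds only to the
spatial frequency of the perturbation. A cohort differing in amplitude
alone is separable through $H$, $S$ and $R$ (whose baselines are nonzero,
so intensity shifts the *relative* fluctuation) but blind in $K$. Coarse,
high-amplitude deformation for the pathological class is also the
physically sensible reading of aneurysm and dissection geometry.

What passing the synthetic benchmark does **not** show: clinical aortas
are branched, bent, non-uniformly perturbed and segmented with imaging
noise, and their labels are clinical outcomes, not generator parameters.
The synthetic accuracies (typically 0.9–1.0 at $n = 20$ per class) say the
pipeline recovers a known signal of plausible scale, not that clinical
accuracy of that magnitude is guaranteed.

# Featurization and classification

Per mesh and metric the feature is the trapezoidal area under $g(r)$ over
$r \in [0, 30]$ (integer abscissae; no quadrature sophistication is
warranted on an integer grid), paired with the mean radius in mm —
analytic for synthetic shapes, metadata for imported meshes. An optional
estimator computes mean vertex distance to a user-supplied centerline
polyline; there is no automatic centerline extraction.

Classification is a support-vector machine on the standardized 2-feature
space, one SVM per metric. Defaults, all exposed as arguments: linear
kernel, cost 1, stratified 5-fold cross-validation with a seeded fold
assignment, binary task (label 0 versus labels 1 and 2). Standardization
uses training-split statistics only, and makes the reported accuracy
invariant to feature rescaling (asserted in the suite). A 3-class variant
is available by fitting on `label` instead of `binary_label` via the
underlying `e1071::svm` multiclass machinery, but the binary grouping is
the reference task. Cross-validated accuracy is the defensible summary of
classifier performance at these sample sizes, and it is what this package
reports.

# Numerical choices

* Vertex merge tolerance: $10^{-8}$ of the bounding-box diagonal (STL
  stores vertices per facet; merging must precede graph construction).
  Merging uses grid snapping, so points straddling a cell boundary within
  tolerance can stay distinct; at $10^{-8}$ of the model scale this is
  immaterial.
* Faces are counter-clockwise viewed from outside; generators verify
  orientation via signed volume and flip if needed.
* Per-face normal equations are solved in closed form; faces whose
  $3\times3$ system is singular (degenerate geometry) contribute zero
  tensors.
* Nearly antipodal vertex/face normals (where the minimal rotation is
  ill-defined) fall back to projection onto the vertex tangent plane;
  this occurs only on pathological geometry.
* `tpcf_auc` requires $r_{lo} < r_{hi}$ within the curve range; the
  degenerate all-zero or all-invalid field raises a classed error rather
  than returning `NaN`.
* Problem sizes used by the test suite and the acceptance script —
  subdivision-4 and -5 icospheres (5 120 and 20 480 faces), 5 000-element
  decimations, cohorts of 20 meshes per class, 20 random oracle meshes of
  up to ~700 vertices — were chosen so every scientific claim is exercised
  at the same element count the reference analysis uses while a full run
  stays comfortably interactive.

# Known limitations

* Geodesic (real-space) distance shells are deliberately out of scope;
  edge distance *is* the descriptor. A geodesic variant would be an
  extension, not a fix.
* Curvature is only defined here for triangular manifold meshes with
  consistent orientation; quad meshes and higher-order curvature tensors
  are not supported.
* The decimator targets manifold collapses; a heavily non-manifold input
  fails with a classed error rather than producing a broken mesh.
* The random-bump field uses Euclidean (chordal) distances to bump
  centers, which differs from geodesic bump shape on strongly curved
  regions; for the calibration roles it plays this is inconsequential.
* Imported clinical meshes must already be segmented surfaces; DICOM
  handling, isosurfacing and scanner-side smoothing live upstream of this
  package.
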