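---
title: "Generative cell and nuclear shape modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative cell and nuclear shape modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellshaper)
```

cellshaper builds *generative* models of cell and nuclear shape: models in
which every point of a low-dimensional latent space decodes to a concrete
shape, so populations can be summarized, compared, sampled from, and morphed.
This vignette describes the models, the numerical choices behind them, and
what the synthetic test battery does and does not demonstrate.

## 2D: outlines, PCA, and SCA

A segmented 2D cell is reduced to an ordered set of boundary landmarks.
`extract_outline()` traces the boundary of the single foreground component
with Moore neighbor tracing (8-connected foreground), forms the closed
polygon through boundary-pixel centers, and places `n_points` landmarks
equally spaced in arc length, starting from the leftmost boundary pixel
(ties broken by smallest y) with a fixed counterclockwise winding in image
coordinates. Sub-pixel positions come from linear interpolation along the
polygon. Defaults follow common practice for this data: 2000 landmarks for
cells, 1000 for nuclei. Landmark vectors are comparable across cells only
after `align_outline()`: centroid at the origin, second-moment major axis
along +x, and the 180-degree ambiguity resolved by requiring non-negative
x-skewness (the same flip rule the 3D alignment uses in the XY plane).

Two linear models operate on these vectors:

* **Outline PCA** (`fit_outline_pca()`): PCA of the vectorized aligned
  outlines. Encoding is the orthogonal projection
  `b = U_k'(vec(x) - mu)`; decoding is `x_hat = U_k b + mu`.
* **SCA** (`fit_sca()`): a variant operating on *preshapes* (location and
  scale removed, `to_preshape()`). It accumulates `C = sum_j x_j' x_j`
  (an n-by-n matrix over landmarks), keeps the top `r` eigenvectors as `R`,
  and represents a preshape as the unit-Frobenius-norm matrix
  `b_o = x R / ||x R||_F` with reconstruction `b_o R'`. The same projection
  applies to unseen shapes; nothing is refit at test time.

For cross-method comparisons, model dimensions are reported as
`k + n_norm_params`: outline PCA carries one explicit normalization
parameter (alignment), SCA two (alignment plus the removed size). Eigenvector
signs are fixed by making each component's largest-magnitude entry positive,
so fits are reproducible across platforms.

The landmark count of SCA's latent matrix deserves a note: `b_o` is a
d-by-r matrix, not an r-vector, so "r" understates the stored numbers by a
factor of d. The package exposes `r` directly and leaves the accounting to
the caller, because collapsing the matrix into an equivalent vector count
would silently change the meaning of "dimension" between the two models.

### Joint cell + nucleus models

`fit_joint_outline_model()` models paired cell and nuclear outlines either
**separately** (half the latent dimensions each) or **jointly** (one PCA
over the concatenated vectors). In both variants the nuclear pose relative
to the cell — centroid offset expressed in the cell-aligned frame (2
numbers) and relative major-axis angle (1 number) — is carried so pairs
reconstruct with the right spatial relationship. In the joint PCA the pose
features are z-scored before concatenation so that three numbers measured
in pixels and radians are not swamped by thousands of landmark coordinates;
after scaling they enter with weight 1. For the SCA variant the shape blocks
are concatenated preshapes and the pose is always carried explicitly, since
the C-matrix formulation has no natural slot for non-landmark features.

## 3D: the robust spherical-harmonic pipeline

A genus-0 closed surface can be mapped bijectively onto the unit sphere;
after such a *spherical parameterization* each coordinate function x, y, z
is a function on the sphere and can be expanded in spherical harmonics
(`spherical_harmonic()`, orthonormal with Condon-Shortley phase). The
complex coefficients up to degree L — the SPHARM descriptor — encode the
surface; truncation gives controlled smoothing and the inverse transform on
an evenly sampled sphere (`reconstruct_surface()`, subdivided icosahedron)
gives a reconstruction with roughly uniform vertex spacing.

The quality of the parameterization decides everything, and simple schemes
fail exactly on the shapes this package targets (cells with long thin
neurites). The robust pipeline (`parameterize_robust()`) proceeds:

1. **Topology fixation** (`fix_topology()`). Voxel masks from microscopy
   frequently carry cavities, tunnels, or pinches. Interior cavities are
   removed by 3D hole filling (background flood fill from the border,
   26-connected background against 6-connected foreground); closing alone
   cannot fill a cavity, which is why filling comes first. Then morphological
   closing with a discrete ball of increasing radius (0, 1, ..., 10) is
   applied until the boundary quad mesh (`voxels_to_quad_mesh()`, one unit
   face per exposed voxel side) is a closed manifold with Euler
   characteristic `V - E + F = 2`.
2. **Pole selection** (`graph_diameter_poles()`). The two parameterization
   poles are the vertex pair realizing the mesh-graph diameter, so the
   initial map stretches along the longest intrinsic axis — for a neurite
   this places the poles at the tips instead of the z extremes. Exact
   all-pairs BFS is used up to 5000 vertices; above that, a deterministic
   double-sweep BFS from 8 evenly spaced seeds, which on mesh graphs almost
   always realizes the true diameter. Ties break lexicographically.
3. **Initial map** (`initial_parameterization()`). Latitude solves the
   discrete Laplace equation with the poles fixed at 0 and pi; longitude
   solves a second Laplace system on the mesh cut along a shortest
   north-south vertex path, with a 2-pi jump carried across the cut, giving
   a single winding. Uniform edge weights are used; the solves are sparse
   Cholesky factorizations. Harmonic maps compress tubular parts
   exponentially, so both angles are then monotonically redistributed by
   cumulative vertex area (uniform density in cos(theta) and in phi). This
   redistribution is what makes neurite-bearing shapes tractable within a
   small optimization budget; without it the optimizer starts from maps in
   which a neurite occupies a region of the sphere too small to represent at
   any reasonable degree.
4. **Area-equalizing optimization** (`optimize_parameterization()`).
   Residuals are signed spherical face areas minus targets (4-pi split
   proportionally to original face areas). Signed areas use the solid-angle
   formula `Omega = 2 atan2(u1.(u2 x u3), 1 + u1.u2 + u2.u3 + u3.u1)` per
   triangle of each quad: the sign detects fold-over, and the formula has
   clean closed-form derivatives, which the sparse analytic Jacobian uses
   (`compute_area_residuals_and_jacobian()`; verified against central finite
   differences in the tests). Gauss-Newton steps are solved as
   box-constrained least squares by ADMM
   (`admm_constrained_least_squares()`; step bound 0.1 rad, penalty rho
   starting at 1 with standard residual balancing, inner cap 200, tolerance
   1e-8), with residual and Jacobian entries
   clipped at their 99.9th percentile. A backtracking safeguard accepts a
   step only if the objective decreases and no additional faces invert.
   Poles stay fixed. The standalone optimizer caps at 100 iterations with
   relative-residual tolerance 1e-3; inside the robust pipeline the default
   budget is 10 iterations (doubled by the refinement fallback below), which
   the synthetic battery shows is sufficient under the 100-pixel success
   criterion while keeping a 25-volume batch of 256x256x24 stacks inside a
   ten-minute desktop run.
5. **Success check and fallbacks.** The working-order descriptor (L = 31 by
   default) is fit and the Hausdorff distance between the original mesh
   vertices and the reconstruction computed; a parameterization fails if
   this exceeds 100 pixels. On failure the pipeline escalates: continue
   optimizing the same map with twice the iteration budget; restart from a
   Laplacian-smoothed surface (lambda = 0.5, one pass); restart with
   z-extreme poles (the classical initialization); smoothed surface plus
   z-extreme poles. Diagnostics record the path taken.

Two numerical choices in the descriptor fit matter. First, the
least-squares system is weighted by each vertex's share of adjacent
spherical face area, approximating the continuous inner product (uniform
weighting is available). Second, `fit_descriptor()` accepts a small
degree-weighted ridge penalty (`smoothing`, default 0): a partially
optimized map can leave sliver-shaped regions of the sphere with no
vertices, where an unregularized degree-31 fit is unconstrained and can
oscillate by hundreds of pixels; a penalty of `1e-3` (the pipeline default
for the working-order fit) suppresses those excursions while leaving
well-covered regions unchanged to several decimals. This is a data-fitting
safeguard, not extra surface smoothing: reconstructions of clean fixtures
are identical with and without it.

### Alignment

`foe_align()` aligns descriptors by the first-order ellipsoid (the degree-1
coefficients, which map the unit sphere to an ellipsoid). The shape is
rotated about the Z axis only — adherent cells are rotationally free only in
the substrate plane — so that the FOE major axis lies in the XZ plane, and a
180-degree flip enforces non-negative x-skewness of the reconstructed
surface. The rotation acts on coefficients exactly, by mixing the x and y
coefficient vectors of every degree except 0; a phase factor `e^(i m a)` on
each coordinate's coefficients would instead rotate the parameter domain
and leave the embedded surface unchanged, which is why coefficient mixing is
the correct analytic action here. Degree-0 terms (translation) are
untouched. FOEs that are rotationally degenerate about Z (spherical in XY,
or major axis along Z) are returned unrotated with a flag rather than
aligned by noise.

## Shape spaces and evolution energy

`fit_descriptor_pca()` stacks descriptors into real vectors — interleaved
real and imaginary parts of the m >= 0 coefficients per coordinate, with
negative orders implied by the reality constraint (halving the dimension and
keeping the PCA real) — and reduces them by PCA. `decode_shape()` composes
the PCA decoder with `reconstruct_surface()`. Descriptor models report one
normalization parameter (alignment) on top of `k`.

Morphing one shape into another follows the linear latent path, discretized
as `x_hat_i = (i z1 + (N - i) z2) / N` for `i = 1..N`. This published
index convention makes `x_hat_N = z1` and approaches `z2` without reaching
it; the package implements it verbatim and additionally returns both
endpoints for rendering rather than silently re-indexing. The deformation
energy

`E = 1/(2N) sum_i [ D(f(x_hat_i), f(z1)) + D(f(z2), f(x_hat_i)) ]`

uses the Hausdorff distance `D` between *decoded shapes in the original
coordinate space*, never between latent points. Dividing by `D(f(z1),
f(z2))` gives a normalized energy whose optimum is 0.5: by the triangle
inequality every summand is at least `D`, with equality exactly when every
intermediate shape lies metrically "between" the endpoints, as in a pure
translation family. The default N is 10; pairs whose endpoints decode to
(nearly) identical shapes (distance below 1e-6 px) have no defined
normalization and are skipped and counted by `energy_benchmark()`, which
samples index pairs without replacement under a fixed seed. The benchmark
default is 2000 pairs for 2D and 200 for 3D models; published analyses at
50000/5000 pairs are a configuration change, not a code change.

Energy is symmetric in the endpoints whenever the two discrete paths visit
the same point set (e.g. swapping z1 and z2 with the same N mirrors the
path; the i-indexing shifts which endpoint is sampled, so exact symmetry
holds at N where the sampled sets coincide).

## Evaluation conventions

Reconstruction error is the Hausdorff distance — the worst match between two
point sets — computed over outline landmarks in 2D and over mesh vertex sets
in 3D. Vertex sets (rather than point-to-triangle distances) keep the 3D
metric consistent with the landmark-based 2D treatment; with the dense
meshes used here the difference is below a voxel. `pixel_level_error()`
(symmetric-difference area over original area) is provided because overlap
metrics and boundary metrics can rank methods differently: overlap is
insensitive to exactly the local boundary detail the Hausdorff distance
punishes. Joint cell + nucleus errors average the two compartment means with
equal weight so nuclear errors are not drowned by the larger cell errors.

## The synthetic generator

The generators exist so the entire pipeline is testable without any imaging
data, and their defaults define the package's study conditions:

* **SNL 2D** (`generate_snl_2d()`): a soma — a disk of radius U(20, 40) px
  perturbed radially by 5 random-phase Fourier modes of orders 2-8 with
  total relative amplitude up to `boundary_roughness` (default 0.08) — plus
  neurites: quadratic Bezier strokes of length U(60, 150) px and width
  U(3, 7) px, attached at soma boundary angles separated by at least 60
  degrees (count fixed at 2 for the 2D family). Strokes are clamped 2 px
  inside the 256x256 frame, so a neurite drawn toward a corner is trimmed
  rather than clipped into a disconnected fragment.
* **SNL 3D** (`generate_snl_3d()`): the 2D generator supplies the central
  slice; slices above and below scale the soma about its profile center
  following a semicircular taper over a 12-slice slab inside the 24-slice
  stack, so consecutive slices nest and the solid is genus-0 by
  construction. Neurites appear only in the central third of the slab
  (their 3-7 px width makes them quasi-2D). Neurite count is sampled
  uniformly from 0-2. Default extent 256x256x24.
* **Blobs and pairs** (`generate_blob_3d()`,
  `generate_cell_nucleus_pair_2d()`): smooth star-shaped fixtures for round
  adherent cells and for joint-model tests; the nucleus is placed strictly
  inside the cell with configurable offset statistics.

One RNG substream is derived per shape from `(master seed, shape index)`,
so batches are reproducible and order-independent, and the global RNG state
is restored after each call.

What passing this battery shows — and what it does not. The generators
produce single-component, nearly-genus-0 shapes with known ground truth and
exercise every failure mode the pipeline guards against (thin protrusions,
tunnels, cavities, rough boundaries). They do not emulate segmentation
artifacts of real microscopy (staircase anisotropy in z, touching cells,
intensity-dependent boundary bias), nor any particular cell line's shape
statistics; absolute reconstruction errors on real datasets are therefore
not predicted by the synthetic numbers, only the qualitative behavior
(errors shrinking with latent dimension and harmonic order, zero
parameterization failures, the 0.5 energy bound).

## Numerical details and degenerate inputs

* Ties and conventions: leftmost boundary start (tie: smallest y); CCW
  winding in image coordinates; eigenvector signs by largest entry;
  lexicographic pole ties; quads triangulated along the (1,3) diagonal
  everywhere.
* Nearly isotropic outlines (equal principal moments within 1e-8 relative)
  are centered but not rotated — a circle has no major axis and rotating it
  by noise would break idempotence.
* Latitudes are clamped to [1e-6, pi - 1e-6] for non-pole vertices during
  optimization; longitudes are reduced mod 2 pi only at the end.
* The ADMM x-update factors `J'J + rho I` once per Gauss-Newton step
  (sparse Cholesky) and reuses the factor across inner iterations.
* Degenerate evolution pairs error out rather than returning infinity;
  degenerate FOEs return flagged, unrotated descriptors.
* Problem sizes in the tests: spheres of radius 4-8 voxels, a 64x40x24
  ellipsoid, 25 full-size (256x256x24) SNL volumes for the failure-rate
  battery, 30 cells / 100 pairs for the energy bound. These were chosen as
  the smallest sizes at which the properties under test are nontrivial.

## Known limitations

* The optimizer equalizes *areas*; it does not penalize face aspect ratio,
  so slivers can persist (mitigated by the fit-side ridge, above). A
  conformal or combined energy is a possible extension.
* `run_pipeline()` and the CLI cover the common simulate-parameterize-fit-
  evaluate paths; bespoke analyses should compose the exported functions.
* The double-sweep diameter heuristic can in principle underestimate the
  graph diameter on adversarial graphs; on voxel-surface meshes we have not
  observed it, and any near-diameter pair serves the purpose (well-separated
  poles).
* Serialized models use a JSON container (documented field-for-field in
  `write_shape_model()`); large cohorts may prefer a binary store, which the
  text container does not try to compete with.
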