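---
title: "Molecular surfaces by parity-checked ray casting: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular surfaces by parity-checked ray casting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfray)
```

# The problem

Continuum models of biomolecules need a closed surface separating the
low-dielectric solute from the high-dielectric solvent, together with
quantities derived from it: enclosed volume, surface area (total and
restricted to grid cubes), interior cavities, and an in/out labelling of
a finite-difference lattice.  `surfray` treats every surface definition
through one minimal contract — *a closed surface that can report its
sorted intersections with a ray, with outward normals* — and derives all
of the above from axis-aligned volumetric ray casting on a cubic grid.

# Surface models

## Solvent-excluded surface (SES), van der Waals, solvent-accessible

The SES is the boundary traced by a spherical probe of radius $r_p$
(default 1.4 Å, a water molecule) rolling over the atom spheres
$(c_i, R_i)$.  `build_ses()` constructs it as a set of trimmed analytic
patches:

* atom radii are inflated by $r_p$ and positions perturbed (see
  *Degeneracies*), and the regular (weighted Delaunay) triangulation of
  the inflated balls — computed as the lower convex hull of the lift
  $(c_i, \lVert c_i\rVert^2 - (R_i + r_p)^2)$ — supplies the candidate
  simplices;
* every exposed atom contributes a **convex sphere patch** of radius
  $R_i$.  A point $q$ on it is exposed iff the probe center
  $c_i + (R_i + r_p)\,(q - c_i)/R_i$ clears every other inflated sphere;
  after the radial map this is an ordinary sphere-outside trim, one per
  overlapping neighbour;
* every triangulation edge whose inflated spheres overlap contributes a
  **saddle torus patch**: major radius = the probe-circle radius, minor
  radius $= r_p$.  Its trims require (a) the foot probe center of the
  point to clear all neighbouring inflated spheres (partial burial of
  the circle) and (b) the point to lie on the rolling arc between the
  two atom contact points (a 2-D cone test in the axial plane).  Tori
  whose probe circle is sampled as entirely buried are dropped at build
  time;
* every triangulation triangle whose three inflated spheres admit a
  common tangent probe position (trilateration) contributes, per exposed
  position, a **concave probe patch**: the probe sphere restricted to the
  spherical triangle spanned by the three contact directions, clipped by
  any other fixed probe sphere closer than $2 r_p$ (the
  self-intersection cure: the union-of-probes boundary).

The VdW surface is the same construction with $r_p = 0$ (only trimmed
convex patches survive — the union-of-balls boundary), and the SAS is
the VdW surface of the inflated radii.  Fully developed cusp handling of
self-intersecting (spindle) tori is not implemented; the probe-probe
clipping above covers the common near-singular cases and the parity
protocol absorbs residual hairline defects.  This is the main known
approximation of the SES builder.

## Skin surface

For weighted points $(c_i, w_i = R_i^2)$ and shrink factor
$s \in (0, 1]$ (default 0.45), the skin surface is the boundary of the
union of all $s$-shrunken convex combinations of the input balls.  It
decomposes into one quadric per simplex of the regular triangulation,
supported on the mixed complex: for a $k$-simplex $X$ with orthocenter
$z$ and squared orthoradius $R^2$, the mixed cell is the Minkowski
combination $(1-s)\,X \oplus s\,\nu_X$ of the simplex with its dual
power face, and the surface inside it is

$$\frac{\lVert y_V \rVert^2}{s} - \frac{\lVert y_D \rVert^2}{1-s} = R^2,
  \qquad y = x - z,$$

with $y_D$ the component parallel to the simplex and $y_V$ the
orthogonal component: spheres of radius $\sqrt{s}\,R_i$ in vertex cells,
spheres of squared radius $(1-s)(-R^2)$ bounding interstitial voids in
tetrahedron cells, and hyperboloids of revolution in edge and triangle
cells.  Mixed cells are convex; each facet is the half-space through
$(1-s) z_{\mathrm{lower}} + s\, z_{\mathrm{upper}}$ with the in-simplex
altitude as its normal.  We verified the facet anchors analytically on a
two-ball system: the vertex-cell sphere and the edge-cell hyperboloid
meet exactly on that plane.

At $s = 1$ all non-tetrahedral mixed cells collapse and the skin is the
union-of-balls boundary, which the builder returns directly in that
limit; the construction above is used for every $s < 1$.

## Gaussian surface

`build_gaussian()` evaluates
$\mathrm{field}(x) = \sum_i \exp\!\big(B(\lVert x - c_i\rVert^2 / R_i^2 - 1)\big)$
on the grid vertices ($B < 0$ is the *blobbyness*, default $-2.5$;
atom-centered accumulation with a 6 Å cutoff) and surfaces the
iso-value 1 of the trilinear interpolant.  With this kernel an isolated
atom's isosurface is exactly its van der Waals sphere, which anchors the
definition to a closed-form test.  Ray crossings are bracketed at $h/8$
steps and bisected to $10^{-9}$; the "analytic intersections" contract
degrades gracefully to root-refined for this numeric surface.

## Imported meshes

`load_mesh_surface()` reads GeomView OFF, ascii PLY and MSMS
`.vert`/`.face` pairs, rejects anything with boundary or non-manifold
edges (the framework's closedness hypothesis), and orients the mesh
outward.  Ray/triangle tests are barycentric; a hit on a shared edge is
kept only by the triangle that traverses the edge from the smaller to
the larger vertex index, so a crossing through an edge is counted once.

# Ray casting and the parity checksum

`make_grid()` builds a cubic lattice with spacing $h = 1/\mathrm{scale}$
whose span is the largest side of the (probe-inflated) bounding box
times $100/\mathrm{perfil}$ (defaults: scale 2 grids/Å, perfil 90), with
an odd vertex count per axis — so rays start and end outside the
surface.  Grid Rays run along each axis through the cube-center rows and
classify cube centers (all three axes, majority vote, ties toward
outside) and the face centers perpendicular to the axis; Edge Rays run
along the cube-vertex rows, classify cube vertices, and store every
analytic intersection on its grid edge with its normal.  A per-axis 2-D
acceleration lattice (cell size $2h$) keeps, for each cell, the patches
whose bounding-box projection meets it — always a superset of what the
ray can hit.

A ray with both endpoints outside a closed surface must record an even
number of crossings.  Every ray is checked; on an odd count it is recast
with the same small random transverse perturbation of both endpoints
(jitter $0.01\,h$, up to 5 retries, per-ray seeded), and if the anomaly
persists the classification of the nearest previously completed
parallel ray is copied and the event is flagged in the cast report.
Grazing contacts (discriminant within $10^{-12}$ of zero, or
even-multiplicity polynomial roots) are deliberately reported as zero
crossings: tangency does not change parity.

Ray/patch intersections are closed-form for spheres and quadrics; the
ray/torus quartic is isolated with a Sturm-sequence solver (bisection to
$10^{-10}$ in the ray parameter plus guarded Newton polish).  Because
the quartics produced by the caster are monic, the whole Sturm chain has
closed-form coefficients and root isolation is vectorised across all
candidate tori of a ray; rows with degenerate chains fall back to the
generic scalar solver.

# Volume, cavities, filling

The enclosed volume discretises
$V = \iiint \chi\, dx\, dy\, dz$ with the per-ray inside intervals:
$V = A_{\mathrm{cell}} \sum_{\mathrm{rays}} \sum_k (t^{\mathrm{exit}}_k
- t^{\mathrm{entry}}_k)$.  `volume_from_intervals()` uses the Grid Rays
themselves ($A_{\mathrm{cell}} = h^2$; exact for lattice-aligned boxes);
`estimate_volume()` (the pipeline default) casts a transverse lattice of
2 rays per cube side ($A_{\mathrm{cell}} = h^2/4$), because the
transverse midpoint rule's error is dominated by silhouette cells and
scales with the ray spacing — on a unit sphere at scale 4 this moves the
error from about $+2.6\%$ to under $1\%$.  Estimates are reported per
axis and averaged; on smooth fixtures the three axes agree to better
than 1%.

Cavity detection floodfills the outside-status cube centers with
6-connectivity (the adjacency of the finite-difference stencil); the
component touching the grid boundary is the exterior, every other
outside component is a cavity with volume (voxel count)·$h^3$.
`fill_cavities()` toggles cavities below `min_volume` (default 11.49 ų
$= \tfrac43\pi\,1.4^3$, the volume of a water-probe sphere) to inside
and locally repairs the derived data so the subsequent triangulation
sees a consistent field: faces and vertices incident only to inside
cubes become inside, edges joining two inside vertices drop their hits.
Since a cavity is enclosed by solid, this one-cell repair is exact for
filled regions; a full re-cast remains available by re-running
`cast_surface()` on demand.

# Analytic-intersections marching cubes

`mc_analytic()` selects each cube's triangulation from the eight vertex
statuses and places every triangle vertex at the stored analytic
intersection on its grid edge — not at an interpolated position — so
vertices lie on the surface to root-refinement accuracy (observed
$\sim 10^{-13}$ Å on patch sets) and no triangle crosses a cube
boundary (per-cube areas are exact restrictions).  When an edge carries
several crossings, the one nearest the outside endpoint is used: the
extra pairs are sub-cell detail below grid resolution.  A mixed edge
left without a hit (possible after majority-vote status resolution near
silhouettes, or as cavity-fill residue) falls back to the edge midpoint
and is counted in the mesh's `fallbacks`.

The 256-case table is *generated* at load time by contour tracing
rather than copied from the literature: crossings on the 12 cube edges
are paired across each face, an ambiguous face (four crossings) pairs
the edges flanking each **inside** corner — so the outside region stays
connected across the face, the conservative choice matching the
tie-toward-outside vote — and the resulting loops are oriented outward
and fanned.  Because the pairing depends only on the shared face's
corner statuses, adjacent cubes always agree and the mesh is crack-free
on parity-consistent input; closedness and the Euler characteristic are
asserted in the test suite on genus-0 and genus-1 fixtures.

`mc_bisecting()` trades accuracy for one third of the casting work:
cube-vertex statuses are inferred from the up-to-eight surrounding
cube-center statuses (ties toward outside) and vertices sit at edge
midpoints.  Optional Laplacian smoothing (default off; when on,
$\lambda = 0.5$, one pass) moves each vertex toward its 1-ring centroid
— a low-pass filter that monotonically shrinks area.

The *incident-ray* area estimator
$\hat A = h^2 \sum_{\mathrm{hits}} 1 / \max(|\cos\theta|, 0.1)$ (angle
between ray and normal; the clamp avoids grazing blow-up) is provided
for comparison: single-axis and three-axis averaged variants are both
substantially more rotation-sensitive than the triangulated area, and
the test suite asserts exactly that ordering over a 7-rotation sweep.

# Degeneracies and numerical choices

Exact arithmetic is replaced by double precision plus random
perturbation: atom coordinates are shifted by up to $10^{-4}$ Å per
coordinate (the largest digit not significant in PDB files) before the
weighted triangulation; a degenerate lifted hull triggers
re-perturbation with a fresh seed (up to 5 times).  The fullerene cage
fixture — 60 atoms exactly cospherical — exercises exactly this
machinery.  Fixtures deliberately aligned with the lattice (boxes whose
faces lie in lattice planes, spheres whose radius lands on grid
vertices) exercise the jitter protocol and the half-open edge-ownership
rules instead.  Nearly coincident hits reported by two adjacent patches
for the same geometric crossing (within $10^{-7}$ Å with aligned
normals) are collapsed to one.

# What the generator emulates — and what it does not

All tests run on synthetic fixtures with closed-form or stated-oracle
truths: single atoms and bridged pairs (revolution quadrature for the
SES truth), linear chains (inclusion-exclusion), the cospherical
fullerene cage (cage radius 3.55 Å, carbon radius 1.9 Å, the common
EDTSurf-style value), Fibonacci-lattice hollow shells with a
Monte-Carlo void-volume truth, torus and box meshes, and a
lattice-aligned degenerate mesh with sliver triangles.  These cover the
geometric stress cases (cosphericity, coplanarity, cavities, genus) but
not the scale or heterogeneity of real proteins: thousands of atoms,
mixed radii, deep invaginations, near-singular SES necks.  Passing
tests therefore demonstrate correctness of the geometry and the
robustness protocol at fixture scale, not protein-scale throughput.
Problem sizes used by the suite are small by design — grids of roughly
$9^3$ to $41^3$ vertices and 1 to 80 atoms (60 for the fullerene) —
so the full suite completes in a few minutes.

A known resolution effect worth stating explicitly: the triangulated
area of an *inscribed* mesh underestimates the true curved area by the
chordal deficit, of order $(h/R)^2$ per facet.  For a 1 Å sphere this
is about 1.4% at scale 4 and 6% at scale 2; the corresponding
scikit-image marching-cubes reference on the same lattice is larger in
both cases.  Area figures at a given scale should be read with that
deficit in mind; volume estimates do not share it.

# Design choices made where the design was open

* **Tangency convention**: grazing contact reports zero intersections —
  it cannot change in/out parity, and any convention that reported one
  hit would break the checksum.
* **Mixed-cell trims** are half-spaces between incident simplices'
  cells rather than explicit dual-polygon constructions: fewer
  primitives, no unbounded-face special cases, and bounding boxes
  follow from the trim planes plus the quadric's transverse bound.
* **MC ambiguous faces** pair crossings to separate the inside corners;
  combined with vertex-status ties resolved toward outside, thin
  solvent channels stay connected — conservative for cavity detection.
* **Multiple hits per edge** keep the crossing nearest the outside
  endpoint (the visible one); sub-resolution detail is smoothed away,
  consistently with choosing the grid scale from the smallest atomic
  radius.
* **Retry/jitter defaults** (5 retries, $0.01 h$) and the
  nearest-completed-ray fallback in scan order are deterministic per
  seed; every fallback is flagged, and a run is only "clean" when the
  report shows none.
* **Volume ray density** (2 per cube side) is part of the package's
  study conditions, fixed from the quadrature analysis above.

# Known limitations

Self-intersecting spindle tori of the SES are clipped only through the
probe-probe rule; the skin builder special-cases $s = 1$; the Gaussian
surface is only as smooth as its grid (silhouette edges can need the
jitter or midpoint fallback, both logged); `project_points()` on
trimmed patches falls back to boundary-circle candidates and dense
parametric sampling, which bounds — but does not prove — global
optimality of the foot point.  Performance is adequate for the fixture
scale this package targets; protein-scale systems would want compiled
kernels and parallel ray scheduling, which change no part of the
contract.
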