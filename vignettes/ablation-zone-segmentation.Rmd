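---
title: "Graph-based segmentation of radiofrequency ablation zones: the model behind rfaseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based segmentation of radiofrequency ablation zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiofrequency ablation (RFA) destroys liver tumours by heat delivered
through a needle electrode; the resulting necrotic "ablation zone" appears as
a dark region in contrast-enhanced CT, often surrounded by a bright enhancing
rim, and — in intra-procedural scans — crossed by the very bright expandable
("umbrella") electrode that produced it. Treatment verification and follow-up
require the zone's volume, and manual slice-by-slice contouring takes minutes
per case. `rfaseg` implements a seed-based, interactive-speed alternative: the
user clicks one point inside the zone and a smoothness-constrained minimum
s-t cut through a spherical ray graph returns a closed surface and a solid
binary mask within a fraction of a second, evaluated against reference masks
by the Dice Similarity Coefficient (DSC) and voxel volumetry.

## The graph model

From the seed point $p_0$, rays are cast along the $R$ vertex directions of a
refined spherical polyhedron (12, 32, 92, 272, 812 or 2432 directions for
template levels 0–5). Along every ray $r$, $J$ nodes are sampled at radii
$j\,\Delta\rho$, $j = 1 \dots J$, with $\Delta\rho = \rho_{\max}/J$; gray
values are read by trilinear interpolation. The segmentation is, per ray, a
cut level $k_r$: nodes $1..k_r$ are ablation zone, the rest background, so
the recovered surface is star-shaped around the seed — the natural geometry
for these roughly convex thermal lesions.

Three edge families make the minimum s-t cut select exactly this structure:

* **intra-edges** (capacity $\infty$) run from node $j$ to node $j-1$ along
  each ray, forcing the source-bound set to be a contiguous prefix — the
  lesion interior is a closed set;
* **inter-edges** (capacity $\infty$) connect node $(r, j)$ to
  $(r', \max(1, j - \Delta r))$ and symmetrically for every adjacent ray pair
  $(r, r')$, enforcing $|k_r - k_{r'}| \le \Delta r$. $\Delta r = 0$ forces a
  sphere; larger values admit more irregular surfaces;
* **terminal edges** encode the image. With a per-ray cost profile
  $C(r, k)$ (below), weights $w(r,j) = C(r,j) - C(r,j-1)$ become a source
  edge of capacity $|w|$ when negative and a sink edge of capacity $w$ when
  positive; the innermost node is tied to the source with a capacity
  exceeding the ray's remaining terminal weight, pinning the seed to the
  foreground.

With this construction the minimum cut minimizes
$\sum_r C(r, k_r)$ over all $\Delta r$-feasible level vectors — a claim the
package verifies *exactly* against an independent brute-force
branch-and-bound oracle (`brute_force_cut()`) on hundreds of random cost
grids in the test suite.

## The region cost

The node cost is built from two intensity references. The ablation-zone
average $m$ is estimated over an axis-aligned cube of about
$1\,\mathrm{cm}^3$ centred on the seed (`estimate_reference_value()`); the
cube is converted to voxel counts per axis via the spacing. The pipeline
uses the **median** of that region by default: the point of integrating over
a region is robustness against the bright needle, and when the seed lands at
the umbrella hub the needle occupies enough of the cube to displace a mean
by half the lesion–background contrast, while the median is unaffected. The
background reference $M$ is the median, over rays, of the gray value at each
ray's outermost in-bounds node — the far end of the rays, which lies in
surrounding tissue whenever $\rho_{\max}$ exceeds the lesion radius (a
prerequisite of the ray construction anyway). Both references can be fixed
explicitly.

Each node then carries a foreground misfit $b = |g - m|$ and a background
misfit $a = |g - M|$, and the per-ray profile is the cumulative two-region
energy

$$C(r,k) \;=\; \sum_{j \le k} \bigl|g(r,j) - m\bigr| \;+\;
               \sum_{j > k} \bigl|g(r,j) - M\bigr|.$$

Minimizing $\sum_r C(r,k_r)$ labels every node by the region average it
resembles more. Two properties make this the right energy for ablation
zones. First, it is noise-robust: a node's misfit is paid wherever the cut
lies, so a single dark noise voxel outside the lesion cannot attract the
whole surface — in contrast to a pure *on-surface* cost
$c = |m - g|$ evaluated only at the cut nodes, which is degenerate on
homogeneous interiors (every interior surface is equally cheap noise-free,
and under noise the optimum collapses towards whichever nodes happen to
match the average; we measured DSC near zero for that variant on the
package's own noisy phantoms). Second, it handles the needle correctly: a
needle node at intensity ~1000 has a *smaller* background than foreground
misfit, so the energy prefers to exclude it and the surface does not leak
along the shaft — the characteristic failure mode of naive region growing
on these images. In the flow network the profile reduces, via the
cost-difference scheme, to exactly one source or sink edge per node with
capacity $\bigl||g-m| - |g-M|\bigr|$, bound to the terminal whose average
the node resembles more.

Out-of-bounds nodes (rays leaving the volume) are definite background:
their foreground misfit is one ray's worth of in-bounds misfit plus one,
their background misfit zero.

## Which minimum cut: the outermost

Minimum cuts are generally not unique — noise-free homogeneous interiors
produce large cost plateaus. The package resolves ties towards the *maximal*
minimum cut: the source side is the complement of the set of nodes that can
still reach the sink in the residual network. This reads as "the last nodes
of every ray still bound to the seed" and keeps the boundary at the outer
edge of a plateau (the lesion border) instead of collapsing to the innermost
ring, which is what the minimal (source-reachable) convention does. The
brute-force oracle compares costs, not index vectors, so this choice never
affects optimality.

## The spherical template

The direction counts 12, 32, 92, 272, 812, 2432 follow the refinement
recursion $V_{k+1} = V_k + F_k$, $F_{k+1} = 3F_k$ from the icosahedron
(inserting each face's centroid, projected to the sphere). The raw recursion
is kept only for the counts: its point set clusters badly (nearest-neighbour
distance ratios above 10 by level 4) and its triangulation retains every
coarse edge — an original icosahedron edge spans 63° at all levels, and a
smoothness constraint applied across such an edge clamps rays pointing in
very different directions to near-equal radii, forcing near-spherical
results whenever the seed is off-centre. The directions are therefore
redistributed by a deterministic tangential electrostatic (Thomson-style)
repulsion (300 iterations, fixed step), after which the nearest-neighbour
ratio stays below 1.3, and the triangulation — faces for the output surface,
edges for the ray adjacency — is the convex hull of the relaxed directions,
whose edges are locally uniform. Templates are deterministic per level and
cached per session.

## From cut to mask, and evaluation

The surface mesh places one vertex per ray at the last source-bound node and
reuses the template triangulation, so it is closed by construction
(`cut_to_surface()`). Voxelization marks a voxel when its *centre* lies
inside the mesh, decided by ray-parity per voxel row with a deterministic
sub-nanometre jitter of the ray origin to avoid hitting mesh edges exactly
(`voxelize_surface()`, C++). Manual slice contours are filled with an
even-odd scan-line rule on pixel centres — half-open at the boundary, hence
orientation-free — and merged by union (`voxelize_contours()`). Volumes are
voxel count × physical voxel size; `dice()` returns
$2V(M\cap S)/(V(M)+V(S))$, defined as 1 for two empty masks. Summaries use
the sample ($n-1$) standard deviation.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `delta_r` | 2 | max cut-level difference between adjacent rays (integer ≥ 0); 0 forces a sphere |
| `nodes_per_ray` | 40 | radial sampling density |
| `max_radius_mm` | 40 | outermost node radius; must exceed the lesion radius, and the radial resolution is `max_radius_mm / nodes_per_ray` — pick roughly 1.5–2× the expected lesion radius |
| `template_level` | 4 (812 rays) | angular sampling density |
| `region_volume_mm3` | 1000 | reference-averaging region around the seed |
| `reference_mode` | median (pipeline) | median rejects needle voxels; mean matches plain region averaging |

The default `max_radius_mm = 40` covers lesions up to the largest volumes
seen in post-RFA series (~120 cm³, radius ≈ 31 mm). For a known ~15 mm
lesion a tighter 25 mm radius gives 0.625 mm radial resolution; the
package's own acceptance experiments use that setting with 812 rays,
40 nodes and $\Delta r = 2$.

## The phantom generator

`phantom_spec()`/`generate_phantom()` render a piecewise-constant CT-like
scene: ellipsoidal dark lesion (default 40) in brighter tissue (110), an
optional enhancing rim shell (160), an optional umbrella needle — a shaft
cylinder entering through a volume face plus tines fanning from a hub at
45° — at 1000, plus seeded Gaussian noise. Default spacings (0.7 mm
in-plane, 2 mm slices) sit inside the ranges typical of multi-slice
abdominal CT (0.679–0.777 mm, 1–3 mm). The ground truth is the analytic
lesion ellipsoid with needle voxels excluded: the electrode is an artifact,
not ablated tissue. `phantom_case_suite()` draws case series with
log-uniform lesion volumes across 6.25–122.62 cm³ and the retained needle in
half the cases. Grids default to a fit-to-lesion bounding box plus a 10 mm
margin rather than a full 512×512 matrix; the geometry, not the matrix
padding, is what exercises the method, and the compact grids keep the whole
suite re-runnable in seconds.

What the phantoms do *not* emulate: beam-hardening streaks, textured liver
parenchyma and neighbouring organs, partial-volume blur beyond the voxel
grid, irregular (non-star-shaped) necrosis. Passing phantom tests therefore
demonstrates correctness of the machinery and robustness to the modelled
effects (noise, rim, needle, seed placement) — not clinical accuracy, which
can only be established against expert contours on real data.

## Numerical choices

* The $\infty$ stand-in is one plus the sum of all finite terminal
  capacities — provably never in a minimum cut of an unconstrained problem.
  The seed-forcing source capacities are per ray (one plus the ray's other
  terminal weight) and the out-of-bounds penalty is one ray's misfit, not
  global sums: keeping the capacity range narrow matters because the
  max-flow solver works in double precision, and a 10^13 spread makes
  sub-milli capacities vanish into rounding error (we observed corrupted
  residual reachability before conditioning the capacities this way).
* Residual reachability uses a per-edge relative saturation tolerance for
  finite edges, keeps forward residuals of $\infty$ edges unconditionally
  (they cannot saturate), and takes backward residuals at an absolute
  $10^{-7}$ flow threshold.
* Boundary-constraint points pin the nearest ray at the nearest sampled
  radius with $\infty$ terminal edges; two constraints whose forced levels
  on nearby rays are incompatible with $\Delta r$ make an $\infty$ edge
  cross the cut, which the solver detects (cut value reaching the stand-in)
  and reports as an error rather than returning a silently broken surface.
* World/voxel conventions: 0-based voxel indices, voxel-centre positions
  `origin + index * spacing`, axis-aligned volumes (no direction cosines).
  Seeds and constraints accept either frame.
* The brute-force oracle enumerates by depth-first search in natural ray
  order with branch-and-bound pruning, breaking ties towards the
  lexicographically smallest level vector; it refuses instances beyond 12
  rays.

## Problem sizes in tests and acceptance runs

Unit tests run templates at levels 0–2 and phantoms of 8–10 mm radius;
oracle-equivalence checks use 12 rays × 6–8 nodes (fully enumerable); the
acceptance experiments run the full 812 × 40 configuration on a 15 mm-radius
phantom at 0.7 × 0.7 × 2 mm spacing, where one complete segmentation
(template cached, graph build + min-cut + voxelization) takes well under a
second on one CPU. These sizes are the package's chosen reference
configuration: large enough to exercise the full graph, small enough that
every claim can be re-verified from scratch in seconds.

## Known limitations

* Star-shaped surfaces only: a cut is one radius per ray, so strongly
  concave or multi-focal zones cannot be represented; place multiple seeds
  and merge masks instead.
* The background reference assumes the outer ray ends lie in tissue; if the
  lesion is larger than `max_radius_mm` the estimate degrades (the package
  warns when both references coincide).
* No direction-cosine support in the volume model; obliquely acquired
  volumes must be resampled upstream.
* DICOM series are out of scope; convert to NIfTI or MetaImage first.
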