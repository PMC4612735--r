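# rfaseg

Semi-automatic 3D segmentation of radiofrequency-ablation (RFA) zones in CT
volumes, for interventional-radiology image analysis: treatment verification
and follow-up need the volume of the thermally destroyed zone, and manual
slice-by-slice contouring takes minutes per case. `rfaseg` needs a single
seed click inside the zone and returns a closed surface, a solid binary
mask and its volumetry at interactive speed, together with the evaluation
tooling (Dice Similarity Coefficient, per-case reports) and a synthetic CT
phantom generator with known ground truth.

## Method

From the seed, rays are cast along the `R ∈ {12, 32, 92, 272, 812, 2432}`
vertex directions of a refined spherical polyhedron and `J` nodes are
sampled along each ray at radii `j · ρ_max/J`. A directed s–t flow network
over these nodes encodes:

- **closedness** — ∞-capacity intra-edges down each ray make the
  source-bound set a contiguous prefix (one cut level `k_r` per ray);
- **smoothness** — ∞-capacity inter-edges between adjacent rays enforce
  `|k_r − k_r′| ≤ Δr`; `Δr = 0` forces a sphere;
- **image fit** — terminal edges derived from the cumulative two-region
  cost `C(r,k) = Σ_{j≤k} |g(r,j) − m| + Σ_{j>k} |g(r,j) − M|`, where `m` is
  the ablation-zone intensity estimated over ~1 cm³ around the seed
  (median by default, which rejects bright RFA-needle voxels) and `M` a
  background reference taken from the outer ends of the rays.

The minimum cut (solved via `igraph`'s max-flow) is then exactly the
`Δr`-feasible level vector minimizing `Σ_r C(r, k_r)`; ties resolve to the
outermost optimum ("the last nodes still bound to the seed"). The surface
through the cut nodes is closed by construction, voxelized by a
voxel-centre parity test, and compared to reference masks by
`DSC = 2·V(M∩S) / (V(M)+V(S))` with volumes as voxel count × physical
voxel size. A brute-force branch-and-bound oracle independently verifies
the solver on small instances.

## Worked example

Segment a synthetic post-ablation scan — 15 mm lesion, bright rim, retained
umbrella needle, noise σ = 10 — from a single seed at the needle hub:

```r
library(rfaseg)

spec <- phantom_spec(lesion_radii = c(15, 15, 15), spacing = c(0.7, 0.7, 2),
                     rim_thickness = 2, needle = TRUE, noise_sigma = 10,
                     rng_seed = 7)
ph  <- generate_phantom(spec)
seg <- segment_ablation_zone(ph$volume, seed_point(ph$spec$lesion_center),
  params = graph_cut_params(delta_r = 2, nodes_per_ray = 40,
                            max_radius_mm = 25, template_level = 4))
summary(seg)
#> Ablation-zone segmentation
#>   seed (world): (25.2, 25.2, 25) mm
#>   reference value: 40.56
#>   volume: 12627.3 mm^3 (12.63 cm^3) in 12885 voxels
#>   cut radii: 13.12 .. 15 mm (delta_r = 2)
#>   rays: 812, nodes/ray: 40, max radius: 25 mm
#>   flow value: 94618.1, boundary cost: 896351

evaluation_record("phantom-1", ph$truth, seg$mask)
#>       case volume_manual_mm3 volume_auto_mm3 voxels_manual voxels_auto dsc_percent
#>  phantom-1          14002.24         12627.3         14288       12885    94.42461
```

The reference value 40.56 shows the 1 cm³ median estimate ignoring the
needle (intensity 1000) at the seed; the mask recovers the 14.0 cm³ ground
truth at DSC 94.4% without leaking along the shaft. `write_mask()`,
`write_mesh()` (STL/OBJ/PLY) and `write_run_summary()` export the results;
`plot(seg, ph$volume)` overlays the contour on a slice.

A command-line wrapper with the same pipeline lives at
`inst/cli/rfaseg.R`:

```sh
Rscript inst/cli/rfaseg.R segment --input scan.nii.gz --seed 25.2,25.2,25 \
    --rays 812 --nodes-per-ray 40 --max-radius-mm 25 --delta-r 2 \
    --out-mask mask.nii.gz --out-mesh surface.stl --report run.json
Rscript inst/cli/rfaseg.R evaluate --mask-a manual.nii.gz --mask-b mask.nii.gz
```

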