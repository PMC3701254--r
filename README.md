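# sasmorph

Extraction and morphometry of the **synaptic apposition surface (SAS)** from
3D binary segmentations of synaptic junctions, as produced by threshold-based
segmentation of FIB/SEM image stacks.

## The problem

In volume electron microscopy the active zone (AZ) and postsynaptic density
(PSD) of a chemical synapse segment as a single flattened, electron-dense
blob — the two membrane specializations sit face to face across the cleft
and usually cannot be resolved separately. Because their areas are nearly
equal, both are well represented by one internal surface lying mid-way
through the segmented junction and following its curvature: the synaptic
apposition surface. Its area is the functionally relevant size of the
synapse (it scales with vesicle release probability and receptor number);
its perimeter, curvature statistics and perforations describe its shape.

## The method

`sasmorph` implements a hybrid of a distance transform and a deformable
planar template, operating on anisotropic voxels (e.g. 3.7 × 3.7 × 20 nm)
in physical nm throughout:

1. oriented bounding box (PCA) of the segmented junction → template normal
   **n**;
2. exact signed Euclidean distance map `d` (positive inside, negative
   outside), smoothed with a Gaussian of `σ = c_s · max(DM)`,
   `0 ≤ c_s ≤ probit(0.75) = 0.674489` (default `c_s = 0.67`);
3. planar template grid spanning the largest OBB face, seeded at the
   centroid of the deepest voxels;
4. iterative deformation `p(t+1) = p(t) + (∇d·n) n` with tricubic gradient
   sampling, converged when the mean vertex error against any of the last
   `s = 10` states falls below `ε = c = 0.001` nm;
5. clipping against the **raw** distance map, which removes overhang and
   opens perforations as interior boundary loops.

The SAS is then quantified: area, perimeter (hole loops included), area
ratio `AR(SAS) = 1 − Area(projected SAS)/Area(SAS)` (0 for a flat surface),
per-vertex principal/mean/Gaussian curvatures (κ₁, κ₂, H, K) with μ/σ
summaries, plus segmentation-level features: voxel volume, Feret's diameter
(exact minimum enclosing sphere), binary principal moments and the
equivalent ellipsoid (`a_i = √(5λ_i)`).

Correctness is validated on voxelized analytic phantoms (slabs, spheres,
shell sectors, perforated sheets, CSG combinations) with closed-form ground
truth — see `selftest()` and the methods vignette
(`vignettes/sas-extraction-methods.Rmd`).

## Worked example

Extract the SAS of a spherical-shell-sector phantom (mid-radius 250 nm,
thickness 40 nm, half-angle 45°, voxelized at 4 nm) and quantify it:

```r
library(sasmorph)

ph  <- make_phantom(phantom_spec("shell_sector", radius = 250,
                                 thickness = 40, half_angle = 45,
                                 spacing = c(4, 4, 4)))
res <- extract_sas(ph$mask)
res
#> <sas_result> label 1: 7074 vertices, 13822 facets; converged in 176
#>   iterations (final error 0.000978 nm)
#>   area 119014 nm^2, perimeter 1387.63 nm

morphometry(res)[, c("sas_area_nm2", "area_ratio", "feret_nm", "mean_H")]
#>   sas_area_nm2 area_ratio feret_nm    mean_H
#> 1       119014    0.07691    378.3 0.0001086
```

The recovered area (119 014 nm²) is within 3.5% of the analytic spherical
cap, `2πR²(1 − cos 45°) = 115 019` nm²; the area ratio is positive because
the surface is curved (a flat slab gives exactly 0); and over the cap proper
the mean curvature recovers `1/R = 0.004` nm⁻¹ (the whole-mesh `mean_H`
mixes in the oppositely curved rim skirt — see the vignette). Meshes export
with `write_mesh()` (PLY/OBJ, nm coordinates) and feature tables with
`write_feature_table()`.

Batch runs over label stacks, the phantom generator and the self-test are
also available from the shell:

```sh
Rscript inst/cli/sas.R phantom --shape slab --size 740 370 60 --out slab.nrrd
Rscript inst/cli/sas.R extract --input slab.nrrd --out results/
Rscript inst/cli/sas.R selftest
```

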