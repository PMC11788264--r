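# MicroCalcSim

Simulation of microcalcification cluster models for mammographic imaging.

Breast microcalcifications — calcium deposits of 0.01–2 mm — are a key
mammographic finding: their shape and clustering separate typically benign
patterns (round, punctate, milk of calcium, large rod-like) from suspicious
ones (amorphous, coarse heterogeneous, fine pleomorphic, fine linear).
Researchers optimizing imaging systems, running virtual clinical trials, or
training detection models need large, controllable sets of cluster models
and a way to render them into mammograms.  MicroCalcSim is an R toolbox
for exactly that, aimed at medical-physics and image-analysis groups.

It provides three coordinated pieces:

* **3D voxel modeling** — single calcifications voxelized from geometric
  primitives (sphere, ellipsoid, cylinders, "teacup", noise-only), carved
  by two-pass uniform boundary noise, morphologically cleaned and rotated;
  assembled into clusters with random / grid / predefined placement and
  BI-RADS-style clinical presets.  Each model's sphericity is
  π^(1/3) (6V)^(2/3) / A with a Knud-Thomsen surface surrogate
  (exactly 1 for a sphere).
* **2D texture-driven generation** — for a given mammogram, a cluster is
  derived from the image itself: radiomics voting over 200×200 px grid
  cells picks the location; candidates come from the intersection of the
  above-median intensity mask and a Frangi vesselness mask, filtered by
  physical size and circularity 4πA/P² (P = 2π·max(x, y)); the cluster
  grows from the sub-cell with the highest contrast
  Σᵢⱼ (i−j)² PV(i,j).
* **Hybrid insertion** — parallel-beam ray tracing to multiplicative
  exp(−μT) templates, blur/scatter degradation, For-Presentation contrast
  calibration (contrast_pres = w·contrast_proc + k, fitted by OLS), a
  distance-transform intensity-scaling surrogate
  (TV = w_dist·d + w_thick·t + w_volt·v + k) for flat 2D models, and
  bit-exact multiplicative insertion into For-Processing or
  For-Presentation images.

Everything is testable offline: a fixture module generates textured
mammogram-like backgrounds and phantom volumes with machine-readable
ground truth.  Models round-trip losslessly through a compressed sparse
container or RAW+JSON; metadata lives in CSV tables.

## Worked example

```r
library(MicroCalcSim)

# a round-type (typically benign) cluster from the clinical preset
cl <- assembleCluster(clinicalPreset("round"), seed = 42, id = "round_001")
cl
#> Cluster3D: 12 placed calcifications
#> VoxelModel3D: 568 x 568 x 568 voxels @ 0.01 mm, 588753 occupied (0.321%)
#>   occupied extent: 5.09 x 4.66 x 4.68 mm
```

The preset sampled a cubic cluster of ≈5.7 mm at the category's 0.01 mm
voxel size and placed 12 spherical calcifications (0.09–0.6 mm) at random
centres at least 0.2 mm apart; `placements(cl)` lists each one:

```r
head(placements(cl)[, c("id", "cx_mm", "extent_mm", "n_voxels")], 3)
#>                 id    cx_mm extent_mm n_voxels
#> 1 round_001_calc_1 1.832511      0.24     6627
#> 2 round_001_calc_2 5.152057      0.59   106661
#> 3 round_001_calc_3 4.611168      0.57    95365
```

A texture-tailored 2D cluster for a synthetic For-Processing mammogram —
the image is inverted internally, the breast tiled, the best cell chosen
by 22-feature radiomics voting, and 10 candidate calcifications grown
from the highest-contrast sub-cell:

```r
bg <- makeBackground(600, 0.1, "power_law_noise", baseValue = 500,
                     amplitude = 50, intent = "for_processing", seed = 1)
generateCluster2D(bg, nTarget = 10, sizeRangeMm = c(0.1, 1.0))
#> Cluster2D: 200 x 200 px mask at (401, 1), 10 calcifications
```

Ray-tracing a 0.5 mm calibration sphere (μ = 0.5 /mm) gives a projection
template whose deepest value is exp(−0.5·0.5) ≈ 0.779 — the attenuation
through the sphere's centre:

```r
rayTrace(makeSphereVolume(0.5, 0.01), muPerMm = 0.5, pixelSpacingMm = 0.1)
#> Template2D: 5 x 5 px @ 0.1 mm (for_processing), TV range [0.7788, 1]
```

A command-line front end over the same functions ships in
`inst/cli/calcsim.R` (subcommands `generate-3d`, `generate-2d`,
`segment`, `insert`, `calibrate-presentation`, `fit-scaling`,
`make-fixtures`).

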