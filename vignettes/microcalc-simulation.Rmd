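---
title: "Modeling microcalcification clusters for mammographic imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microcalcification clusters for mammographic imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicroCalcSim)
```

## The modeling problem

Microcalcifications are sub-millimetre calcium deposits in the breast whose
morphology and spatial arrangement carry diagnostic weight: regular, round
deposits are typically benign, while pleomorphic or fine linear clusters
raise suspicion of malignancy.  Simulated cluster models are used to
optimize imaging chains, to run virtual clinical trials, and to augment
training data for detection algorithms.  MicroCalcSim provides three
coordinated capabilities:

1. **3D voxel models** of single calcifications and clusters, built from
   geometric primitives, carved by uniform noise, and assembled with
   controlled placement;
2. a **2D texture-driven generator** that derives a cluster directly from
   the local textures of a given mammogram, so the simulated lesion blends
   into the surrounding tissue;
3. a **hybrid insertion engine** that renders binary models into real or
   synthetic mammograms through multiplicative projection templates.

## 3D single calcifications

A calcification starts as a voxelized solid — sphere, ellipsoid, (elliptic)
cylinder, a "teacup" (an ellipsoid minus a shifted copy of itself, giving
the concave shape of sedimented milk-of-calcium), or a filled cube for the
"random" type that is shaped entirely by noise.  A voxel is occupied iff
its centre lies inside the analytic solid; this rule is unbiased and easy
to verify by enumeration.

Irregular boundaries come from two passes of uniform noise against a
threshold $\sigma \in [0,1]$: occupied voxels survive when their noise
value exceeds $\sigma$ (so the interior survives with probability
$1-\sigma$), and a second pass on the inverted occupancy adds background
voxels that beat $1-\sigma$.  The union of the two keep-sets is used; a
single-pass variant is available (`passes = 1`).  At $\sigma = 0$ the
operation is the identity; at $\sigma = 1$ it inverts the model.

Morphological cleaning applies binary opening then closing with a
3×3×3 six-connected cross and keeps the largest 26-connected component.
The pass is repeated until the grid stabilizes (almost always within two
passes), which makes `cleanModel()` idempotent — a single pass is not,
because closing can create thin structures that a subsequent opening
removes.  Rotation uses nearest-neighbour resampling about the grid centre
in the order z, y, x; multiples of 90° reduce to exact index permutations,
and the output grid is enlarged so nothing is clipped.

The sphericity of a model with volume $V$ (occupied voxels × voxel
volume) and surface surrogate $A$ is

$$\mathrm{sphericity} = \frac{\pi^{1/3}\,(6V)^{2/3}}{A},$$

with $A$ taken from the Knud Thomsen ellipsoid approximation
$A = 4\pi\big[((xy)^{1.6}+(yz)^{1.6}+(zx)^{1.6})/3\big]^{1/1.6}$ for
sphere-like shapes (semi-axes $x,y,z$), or from
$A = 2\pi y z + 2\pi (y^2+z^2)/(2x)$ for an elliptic cylinder with radii
$(x, y)$ and height $z$ — the latter implemented exactly in the printed
form, noting that sphericity is less meaningful for elongated cylinders.
A perfect sphere scores exactly 1 (the formula cancels algebraically); a
voxelized 0.5 mm sphere at 0.01 mm voxels scores within 5% of 1.

Existing intensity volumes (simulated or clinical cluster reconstructions)
can be recycled: `segmentCalcifications()` min–max rescales to $[0,1]$,
thresholds at 0.5, and extracts every 26-connected component with a
metadata record.  Because assembly composes clusters by voxel-wise OR,
segmentation is an exact inverse for disjoint placements — a property the
test suite exercises at $k \in \{3, 10, 20\}$.

## 3D clusters

`assembleCluster()` fills a cluster volume (a validated `ClusterSpec`)
with calcifications that are either generated on the fly or selected from
a database by size and sphericity ranges (uniformly at random among the
candidates; when none qualifies and resizing is allowed, the nearest-size
model is nearest-neighbour zoomed to a target drawn from the range).
Placement is:

* **random** — rejection sampling with a pairwise minimum distance (a
  lower bound);
* **grid** — a regular lattice whose spacing *equals* the minimum
  distance, centred in the volume, taken in raster order (x fastest);
* **predefined** — a user-supplied, validated list of centres.

Centres are inset from the faces by the largest calcification half-extent
plus one voxel, so placements never crop a model; voxel-level overlap of
neighbouring calcifications is tolerated and logged in the cluster record.
All randomized steps are bit-reproducible given a seed.

### Clinical presets

`clinicalPreset()` returns an editable spec for the eight implemented
BI-RADS-style morphologies — four typically benign (round, punctate, milk
of calcium, large rod-like) and four suspicious (amorphous, coarse
heterogeneous, fine pleomorphic, fine linear).  Morphologies that depend
on surrounding breast structures (vascular, skin, suture) are rejected by
design, since the voxel models carry no tissue context.  The per-category
voxel sizes are fixed (0.01 mm for round, punctate, milk of calcium, fine
pleomorphic, coarse heterogeneous; 0.05 mm for large rod-like; 0.005 mm
for amorphous and fine linear).  Every other preset number is a package
default, chosen once on clinical grounds and fully user-overridable:
round/punctate follow the published benign configuration (spherical
calcifications 0.09–0.6 mm, 8–25 per cluster, cubic clusters
2.25–6.00 mm); rod-like uses cylinders 1–2 mm long in 8–15 mm clusters;
the suspicious categories use noise-dominated ("random") or elongated
shapes with higher noise thresholds and smaller cluster extents
(1.5–6 mm).  The suite's end-to-end check generates 10 clusters per
category with sparse storage; those cluster extents and voxel sizes give
grids up to roughly $600^3$ voxels, which one desk-class CPU core handles
comfortably.

## 2D texture-driven clusters

For a specific mammogram the generator works in presentation polarity
(structures bright); for-processing images are inverted up front, which
makes the pipeline polarity-invariant by construction.  The steps:

1. **Breast segmentation** — Otsu threshold, largest 8-connected
   component, holes filled.
2. **Tiling** — non-overlapping cells (default 200×200 px) fully inside
   the image with breast coverage above 0.9.
3. **Cell voting** — 22 radiomics features per cell (16 first-order + 6
   gray-level co-occurrence features; the exact list and each feature's
   sort direction are an editable configuration).  For each feature the
   top-10 cells are collected and the most frequent cell wins; ties break
   by lowest mean rank, then row-major order.  A manual cell bypasses the
   vote.
4. **Candidate mask** — the intersection of the above-median intensity
   mask with a thresholded Frangi vesselness response (scales 1–3 px,
   $\beta = 0.5$, threshold defaulting to the mean positive response).
   Each 8-connected component is one candidate.
5. **Filtering** — area $A$ = pixel count, radii $(x, y)$ = bounding-box
   half-extents, perimeter $P = 2\pi\max(x,y)$, circularity
   $4\pi A / P^2$; candidates are kept inside user ranges of physical
   extent (0.01–2.00 mm) and circularity (0.01–2.0).
6. **Contrast-seeded growth** — within an overlapping grid of 10×10 px
   sub-cells (stride 5 px), the contrast of each sub-cell is
   $\sum_i \sum_j (i-j)^2 \, PV(i,j)$ over 1-based pixel positions,
   implemented verbatim; for a uniform unit sub-cell of side $n$ this is
   $n^2(n^2-1)/6 = 1650$.  Note this is a pixel-index double sum, not the
   gray-level co-occurrence contrast of the same name; the printed form is
   deliberately used.  The cluster seeds at the highest-contrast sub-cell
   touching a candidate, absorbs candidates touching the region, then
   repeatedly enlarges the region around the included calcifications (one
   sub-cell width per step), adding newly touched candidates nearest-first
   until the target count is reached or candidates are exhausted.

The pipeline is fully deterministic for a fixed image and configuration.

## Insertion

For 3D models, a parallel-beam ray trace along a principal axis gives per
ray the traversed thickness $T$ and the template value
$TV = e^{-\mu T}$, where $\mu$ is the lesion's linear attenuation
coefficient; the background is exactly 1.0.  (Real acquisition geometry is
out of scope; the projection axis is configurable.)  Degradation blurs
the attenuation deficit $1 - TV$ with a Gaussian (default
$\sigma = 0.1$ mm) and applies a scatter contrast reduction
$TV' = (TV + s)/(1 + s)$, $s = f/(1-f)$ for scatter fraction $f$ —
chosen because the degradation factors are named but not prescribed in
functional form; both parameters are configurable and the background is
re-clamped to exactly 1.0.

Insertion multiplies image pixels by the template inside its footprint and
leaves everything else bit-exact.  For display-processed
("for presentation") images, which use an inverted lookup table, the Weber
contrast $(\mathrm{MPV_{calc}} - \mathrm{MPV_{bg}})/\mathrm{MPV_{bg}}$ of
the same calcifications in both image types follows a quasi-linear
relationship; `fitContrastCalibration()` estimates its slope and
intercept by ordinary least squares, and `toPresentation()` applies it
per pixel ($\mathrm{contrast} = TV - 1$; the region-mean versus per-pixel
choice is undocumented in the source method, and the per-pixel analogue is
used and flagged).  No vendor-measured coefficients are shipped — only
the functional form is reproducible — so calibrations are user-supplied
or fitted from paired measurements.

Flat 2D cluster masks cannot be ray-traced; instead an intensity-scaling
surrogate maps the Euclidean distance transform $d$ of the mask through

$$TV = w_\mathrm{dist}\, d + w_\mathrm{thick}\, t + w_\mathrm{volt}\, v
  + k,$$

with $t$ the breast thickness (mm) and $v$ the tube voltage (kV).  The
weights come from regressing ray-traced sphere templates (diameters
0.1–1.0 mm) on their silhouettes' distance transforms across
thickness/voltage conditions (`sphereTrainingSet()` +
`fitScalingWeights()`).  A linear map can only approximate the
exponential ray trace: the adequacy documented in the tests is a
correlation above 0.8 and worst-case residual below 0.2 at
$\mu = 1\,\mathrm{mm}^{-1}$, and the fitted surrogate preserves the
diameter ordering of the centre TVs (larger spheres attenuate more).
Edges are smoothed with a Gaussian (default 0.5 px) before the background
is reset to exactly 1.0.

## Storage and interchange

Models round-trip bit-exactly through two containers: a gzip-compressed
binary coordinate list (dims, voxel size, linear indices of occupied
voxels — compact at the low occupancies typical of clusters) and
headerless RAW uint8 (x-fastest, little-endian) with a JSON sidecar.
Metadata lives in plain CSV tables with a stable schema.  Images are read
from PNG/TIFF/CSV with a JSON sidecar carrying pixel spacing,
presentation intent, thickness, voltage and bit depth; 32-bit float TIFF
is the lossless image format.  DICOM containers are not parsed; the
sidecar path carries the same attributes.

## Synthetic data

The fixture generator makes every stage testable without clinical data:
half-disc "breasts" filled with flat, power-law ($1/f^\beta$ spectrum,
$\beta = 3$, the classic mammographic texture model) or clustered-blob
textures; centre-voxelized calibration spheres; and intensity volumes of
$k$ disjoint bright blobs over a noisy 0.1 background with machine-readable
ground truth.  These fixtures reproduce the *geometric and statistical*
features the pipeline consumes — they contain no detector physics, no
anatomic ductal structure and no vendor post-processing, so green tests
demonstrate algorithmic correctness, not clinical realism.  Realism of
inserted lesions must be validated per application with reader studies.

## Numerical choices and limitations

* Voxel counts from mm use round-half-up; generation retries up to 10
  times when cleaning empties a model.
* Ties (cell voting, equal contrast) break by lowest mean rank, then
  row-major index — deterministic everywhere.
* The teacup subtraction shift defaults to half the z semi-axis
  (configurable).
* Random placement guarantees centre distances only; voxel overlap is
  possible for large calcifications and is logged, not forbidden.
* No ductal-tree growth model, no CC/MLO two-view correspondence, no
  DBT projection geometry or reconstruction, and no CEM dual-energy
  physics.
* Problem sizes in the test suite (8 mm clusters at 0.05 mm voxels for
  inverse checks; 600×600 px backgrounds for the 2D pipeline; full
  preset-scale grids only in the end-to-end set generation) were chosen
  as the smallest sizes at which the properties under test are
  non-trivial.

## A worked example

```{r example, eval = FALSE}
library(MicroCalcSim)

# ten round-type clusters, stored sparsely
set <- generateClusterSet(clinicalPreset("round"), nModels = 10,
                          outDir = "round_models", format = "sparse",
                          seed = 42)
head(set$clusterRecords)

# render one model into a synthetic mammogram
bg <- makeBackground(600, 0.1, "power_law_noise", baseValue = 500,
                     amplitude = 50, intent = "for_processing", seed = 1)
model <- loadModel(set$paths[1], "sparse")
tpl <- rayTrace(model, muPerMm = 0.5, pixelSpacingMm = 0.1)
tpl <- degradeTemplate(tpl, blurSigmaMm = 0.1, scatterFraction = 0.1)
inserted <- insertTemplate(bg, tpl, location = c(250, 120))

# a texture-tailored 2D cluster for the same image
cl <- generateCluster2D(bg, nTarget = 10, sizeRangeMm = c(0.1, 1.0))
cl
```
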