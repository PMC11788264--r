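# 3D single-calcification modeling: geometric base shapes, noise-induced
# irregular boundaries, morphological cleaning, rotation, sphericity.

CALC_SHAPES <- c("sphere", "ellipsoid", "cylinder", "elliptic_cylinder",
                 "teacup", "random")

# Column schema of the per-calcification metadata table.
CALC_RECORD_COLS <- c("id", "shape_label", "req_x_mm", "req_y_mm", "req_z_mm",
                      "ext_x_mm", "ext_y_mm", "ext_z_mm",
                      "rot_x_deg", "rot_y_deg", "rot_z_deg",
                      "noise_threshold", "sphericity_value",
                      "voxel_size_mm", "n_voxels")

#' Empty calcification metadata table
#'
#' @return zero-row data.frame with the per-calcification record columns.
#' @export
emptyCalcRecords <- function() {
  df <- as.data.frame(setNames(
    c(list(character(0), character(0)), rep(list(numeric(0)), 12),
      list(integer(0))),
    c("id", "shape_label", CALC_RECORD_COLS[3:14], "n_voxels")))
  df
}

calcRecordRow <- function(id, shape, req, ext, rot, noise, sph, voxelSize,
                          nVox) {
  data.frame(id = id, shape_label = shape,
             req_x_mm = req[1], req_y_mm = req[2], req_z_mm = req[3],
             ext_x_mm = ext[1], ext_y_mm = ext[2], ext_z_mm = ext[3],
             rot_x_deg = rot[1], rot_y_deg = rot[2], rot_z_deg = rot[3],
             noise_threshold = noise, sphericity_value = sph,
             voxel_size_mm = voxelSize, n_voxels = as.integer(nVox),
             stringsAsFactors = FALSE)
}

#' Voxelize a geometric base shape
#'
#' Creates the binary starting solid for a single calcification.  A voxel is
#' occupied iff its centre lies inside the analytic solid (closed boundary).
#' The solid is centred in a grid padded by one empty voxel on every face.
#'
#' Supported shapes: \code{sphere} (diameter \code{dimsMm[1]}),
#' \code{ellipsoid} (axis extents \code{dimsMm}), \code{cylinder} (circular,
#' diameter \code{dimsMm[1]}, height \code{dimsMm[3]}),
#' \code{elliptic_cylinder} (diameters \code{dimsMm[1:2]}, height
#' \code{dimsMm[3]}), \code{teacup} (an ellipsoid minus a copy of itself
#' shifted along +z, giving a concave cup), and \code{random} (a filled cube
#' of the requested extent, meant to be carved entirely by boundary noise).
#'
#' @param shapeLabel one of
#'   \code{c("sphere","ellipsoid","cylinder","elliptic_cylinder","teacup","random")}.
#' @param dimsMm numeric(3) full extents (diameters/heights) in mm.
#' @param voxelSizeMm isotropic voxel edge in mm.
#' @param teacupShiftFrac fraction of the z semi-axis by which the subtracted
#'   ellipsoid copy is shifted (default 0.5, i.e. half the z semi-axis).
#' @return a \linkS4class{VoxelModel3D}.
#' @examples
#' m <- makeBaseShape("sphere", c(0.2, 0.2, 0.2), 0.01)
#' voxelCount(m)
#' @export
makeBaseShape <- function(shapeLabel, dimsMm, voxelSizeMm,
                          teacupShiftFrac = 0.5) {
  shapeLabel <- match.arg(shapeLabel, CALC_SHAPES)
  dimsMm <- rep(as.numeric(dimsMm), length.out = 3L)
  if (any(dimsMm <= 0) || voxelSizeMm <= 0)
    stop("dimensions and voxel size must be positive")
  if (shapeLabel %in% c("sphere", "cylinder")) dimsMm[2] <- dimsMm[1]
  if (shapeLabel == "sphere") dimsMm[3] <- dimsMm[1]
  if (any(dimsMm < voxelSizeMm))
    stop("requested dimensions are smaller than one voxel")

  nvox <- vapply(dimsMm, mmToVoxels, integer(1), voxelSize = voxelSizeMm)
  gd <- nvox + 2L  # one empty pad voxel per face
  # voxel-centre coordinates relative to the grid centre, in mm
  cc <- lapply(gd, function(n) ((seq_len(n) - 0.5) - n / 2) * voxelSizeMm)
  a <- dimsMm / 2  # semi-axes

  insideEllipsoid <- function(zShift = 0) {
    x2 <- (cc[[1]] / a[1])^2
    y2 <- (cc[[2]] / a[2])^2
    z2 <- ((cc[[3]] - zShift) / a[3])^2
    outer(outer(x2, y2, `+`), z2, `+`) <= 1
  }
  grid <- switch(shapeLabel,
    sphere = ,
    ellipsoid = insideEllipsoid(),
    teacup = {
      shift <- teacupShiftFrac * a[3]
      g <- insideEllipsoid() & !insideEllipsoid(zShift = shift)
      if (!any(g))
        stop("teacup subtraction produced an empty model (shift too small)")
      g
    },
    cylinder = ,
    elliptic_cylinder = {
      r2 <- outer((cc[[1]] / a[1])^2, (cc[[2]] / a[2])^2, `+`) <= 1
      zin <- abs(cc[[3]]) <= a[3]
      outer(r2, zin, `&`)
    },
    random = {
      g <- array(FALSE, gd)
      g[2:(gd[1] - 1L), 2:(gd[2] - 1L), 2:(gd[3] - 1L)] <- TRUE
      g
    })
  dim(grid) <- gd
  if (!any(grid)) stop("voxelization produced an empty model")
  VoxelModel3D(grid, voxelSizeMm)
}

#' Introduce irregular boundaries with uniform noise
#'
#' Two-pass uniform-noise carving: pass 1 multiplies the occupancy by i.i.d.
#' Uniform(0,1) values and keeps voxels whose product exceeds \code{sigma};
#' pass 2 repeats on the inverted occupancy with fresh noise, keeping values
#' above \code{1 - sigma}.  The returned model is the union of the two kept
#' sets (configurable to pass 1 only via \code{passes = 1}).
#'
#' @param model a \linkS4class{VoxelModel3D}.
#' @param sigma noise threshold in [0, 1]; 0 is the identity, 1 approximately
#'   inverts the model.
#' @param seed optional RNG seed for bit-reproducibility.
#' @param passes 2 (default, union of both passes) or 1 (carve only).
#' @return a \linkS4class{VoxelModel3D}.
#' @export
applyBoundaryNoise <- function(model, sigma, seed = NULL, passes = 2L) {
  stopifnot(is(model, "VoxelModel3D"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0 || sigma > 1)
    stop("sigma must be a single value in [0, 1]")
  checkSeed(seed)
  g <- model@grid
  n <- length(g)
  keep1 <- g & (stats::runif(n) > sigma)
  if (passes >= 2L) {
    keep2 <- (!g) & (stats::runif(n) > 1 - sigma)
    keep1 <- keep1 | keep2
  }
  dim(keep1) <- dim(g)
  VoxelModel3D(keep1, model@voxelSize)
}

#' Morphological cleaning of a calcification model
#'
#' Binary opening (removes small spurious islands) followed by closing
#' (fills small holes), both with a 3x3x3 six-connected cross structuring
#' element, then retention of the largest 26-connected component.  The
#' open/close/select pass is repeated until the grid stops changing (at
#' most \code{maxPasses} times), making the operation idempotent on its own
#' output; convergence almost always occurs within two passes.  The result
#' has exactly one connected component, or is empty.
#'
#' @param model a \linkS4class{VoxelModel3D}.
#' @param maxPasses stabilization cap (default 10).
#' @return a cleaned \linkS4class{VoxelModel3D}.
#' @export
cleanModel <- function(model, maxPasses = 10L) {
  stopifnot(is(model, "VoxelModel3D"))
  g <- model@grid
  for (pass in seq_len(max(1L, maxPasses))) {
    if (!any(g)) break
    g2 <- closeBinary(openBinary(g))
    if (any(g2)) {
      lab <- labelComponents(g2, full = TRUE)
      counts <- tabulate(lab[lab > 0L])
      g2 <- lab == which.max(counts)
    }
    if (identical(g2, g)) break
    g <- g2
  }
  VoxelModel3D(g, model@voxelSize)
}

rotationMatrix3 <- function(anglesDeg) {
  th <- anglesDeg * pi / 180
  cz <- cos(th[3]); sz <- sin(th[3])
  cy <- cos(th[2]); sy <- sin(th[2])
  cx <- cos(th[1]); sx <- sin(th[1])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rx %*% Ry %*% Rz  # applied in the order z, then y, then x
}

#' Rotate a voxel model about the three principal axes
#'
#' Sequential right-handed rotations about z, then y, then x, with
#' nearest-neighbour resampling about the grid centre.  The output grid is
#' enlarged so that no occupied voxel is clipped; rotations by multiples of
#' 90 degrees are exact index permutations.
#'
#' @param model a \linkS4class{VoxelModel3D}.
#' @param anglesDeg numeric(3) rotation angles (x, y, z) in degrees,
#'   each in [0, 360).
#' @return the rotated \linkS4class{VoxelModel3D}.
#' @export
rotateModel <- function(model, anglesDeg) {
  stopifnot(is(model, "VoxelModel3D"))
  anglesDeg <- rep(as.numeric(anglesDeg), length.out = 3L)
  if (all(anglesDeg %% 360 == 0)) return(model)
  R <- rotationMatrix3(anglesDeg)
  d <- dim(model@grid)
  # rotated extent of the full grid [-d/2, d/2]^3 (voxel units)
  corners <- as.matrix(expand.grid(c(-1, 1) * d[1] / 2,
                                   c(-1, 1) * d[2] / 2,
                                   c(-1, 1) * d[3] / 2))
  rc <- corners %*% t(R)
  m <- pmax(1L, as.integer(ceiling(apply(rc, 2, max) - apply(rc, 2, min) - 1e-9)))
  Rinv <- t(R)
  # output voxel-centre coordinates (centred, voxel units)
  vx <- (seq_len(m[1]) - 0.5) - m[1] / 2
  vy <- (seq_len(m[2]) - 0.5) - m[2] / 2
  vz <- (seq_len(m[3]) - 0.5) - m[3] / 2
  co <- as.matrix(expand.grid(vx, vy, vz))
  p <- co %*% t(Rinv)
  ix <- as.integer(round(p[, 1] + 0.5 + d[1] / 2))
  iy <- as.integer(round(p[, 2] + 0.5 + d[2] / 2))
  iz <- as.integer(round(p[, 3] + 0.5 + d[3] / 2))
  ok <- ix >= 1L & ix <= d[1] & iy >= 1L & iy <= d[2] & iz >= 1L & iz <= d[3]
  out <- logical(prod(m))
  lin <- (iz[ok] - 1L) * (d[1] * d[2]) + (iy[ok] - 1L) * d[1] + ix[ok]
  out[ok] <- model@grid[lin]
  dim(out) <- m
  VoxelModel3D(out, model@voxelSize)
}

#' Sphericity of a calcification
#'
#' Computes sphericity = pi^(1/3) (6V)^(2/3) / A, where V is the model
#' volume and A an analytic surface-area surrogate built from the shape's
#' semi-axes: the Knud Thomsen ellipsoid approximation with exponent 1.6
#' (sphere, ellipsoid, random, teacup, segmented components) or the
#' elliptic-cylinder form A = 2*pi*y*z + 2*pi*(y^2 + z^2)/(2x) for radii
#' (x, y) and height z.  A perfect sphere scores exactly 1.0; for cylinders
#' the value is reported but less meaningful given their elongated profile.
#'
#' @param semiAxesMm numeric(3) semi-axes in mm (for cylinders: the two
#'   radii and the half-height; the height used in the surface term is
#'   \code{2 * semiAxesMm[3]}).
#' @param shapeLabel shape name controlling the surface surrogate.
#' @param volumeMm3 model volume in mm^3 (occupied voxels x voxel volume,
#'   or the analytic volume).
#' @return dimensionless sphericity (> 0).
#' @examples
#' r <- 0.5
#' shapeSphericity(c(r, r, r), "sphere", 4 / 3 * pi * r^3)  # exactly 1
#' @export
shapeSphericity <- function(semiAxesMm, shapeLabel, volumeMm3) {
  semiAxesMm <- rep(as.numeric(semiAxesMm), length.out = 3L)
  if (!is.finite(volumeMm3) || volumeMm3 <= 0)
    stop("volume must be positive")
  if (any(semiAxesMm <= 0)) stop("semi-axes must be positive")
  x <- semiAxesMm[1]; y <- semiAxesMm[2]; z <- semiAxesMm[3]
  A <- if (shapeLabel %in% c("cylinder", "elliptic_cylinder")) {
    h <- 2 * z  # height
    2 * pi * y * h + 2 * pi * (y^2 + h^2) / (2 * x)
  } else {
    p <- 1.6
    4 * pi * (((x * y)^p + (y * z)^p + (z * x)^p) / 3)^(1 / p)
  }
  pi^(1 / 3) * (6 * volumeMm3)^(2 / 3) / A
}

#' Sphericity of a voxel model
#'
#' Convenience wrapper: V is taken as occupied-voxel count times voxel
#' volume; the surface semi-axes default to the occupied bounding-box
#' half-extents.
#'
#' @param model a \linkS4class{VoxelModel3D}.
#' @param shapeLabel surface surrogate selector (see
#'   \code{\link{shapeSphericity}}).
#' @param semiAxesMm optional semi-axes override in mm.
#' @return dimensionless sphericity.
#' @export
modelSphericity <- function(model, shapeLabel = "ellipsoid",
                            semiAxesMm = NULL) {
  V <- voxelCount(model) * model@voxelSize^3
  if (is.null(semiAxesMm)) semiAxesMm <- extentMm(model) / 2
  shapeSphericity(semiAxesMm, shapeLabel, V)
}

#' Generate one single-calcification model
#'
#' Samples one value per tuning range (uniformly, seeded), then runs the
#' pipeline base shape -> boundary noise -> morphological cleaning ->
#' rotation, and records the sampled values and resulting sphericity.
#' If cleaning empties the model, generation is retried with fresh noise up
#' to \code{attempts} times.
#'
#' @param spec list with fields \code{shape} (label), \code{sizeMm} (either
#'   a c(min, max) range applied per dimension or a list of three ranges),
#'   \code{noise} (sigma value or range in [0,1]), \code{rotationDeg}
#'   (range in [0, 360), or FALSE/NULL for none), \code{voxelSizeMm},
#'   optionally \code{teacupShiftFrac} and \code{noisePasses}.
#' @param seed optional RNG seed.
#' @param attempts retry cap when cleaning yields an empty model.
#' @param id record identifier.
#' @return list with elements \code{model} (\linkS4class{VoxelModel3D}) and
#'   \code{record} (one-row data.frame).
#' @export
generateCalcification <- function(spec, seed = NULL, attempts = 10L,
                                  id = "calc_1") {
  checkSeed(seed)
  shape <- match.arg(spec$shape, CALC_SHAPES)
  voxelSize <- spec$voxelSizeMm
  if (is.null(voxelSize) || voxelSize <= 0) stop("spec$voxelSizeMm required")
  sizeRanges <- spec$sizeMm
  if (!is.list(sizeRanges)) sizeRanges <- rep(list(sizeRanges), 3L)
  bad <- vapply(sizeRanges, function(r) any(r < 0.01 - 1e-12 | r > 2.00 + 1e-12),
                logical(1))
  if (any(bad))
    stop("calcification sizes must lie within 0.01-2.00 mm")
  noiseRange <- if (is.null(spec$noise)) 0 else spec$noise
  if (any(noiseRange < 0 | noiseRange > 1))
    stop("noise threshold must lie within 0.00-1.00")
  rotRange <- spec$rotationDeg
  doRotate <- !is.null(rotRange) && !identical(rotRange, FALSE)
  if (doRotate && any(rotRange < 0 | rotRange > 360))
    stop("rotation angles must lie within 0-360 degrees")
  shiftFrac <- if (is.null(spec$teacupShiftFrac)) 0.5 else spec$teacupShiftFrac
  passes <- if (is.null(spec$noisePasses)) 2L else spec$noisePasses

  for (att in seq_len(max(1L, attempts))) {
    dims <- vapply(sizeRanges, sampleRange, numeric(1))
    sigma <- sampleRange(noiseRange)
    rot <- if (doRotate) sampleRange(rotRange, 3L) else c(0, 0, 0)
    model <- makeBaseShape(shape, dims, voxelSize, teacupShiftFrac = shiftFrac)
    if (sigma > 0) model <- applyBoundaryNoise(model, sigma, passes = passes)
    model <- cleanModel(model)
    if (voxelCount(model) > 0L) {
      if (doRotate && any(rot != 0)) model <- rotateModel(model, rot)
      model <- VoxelModel3D(cropToBoundingBox(model@grid, pad = 1L), voxelSize)
      if (shape %in% c("sphere", "cylinder")) dims[2] <- dims[1]
      if (shape == "sphere") dims[3] <- dims[1]
      sph <- shapeSphericity(dims / 2, shape,
                             voxelCount(model) * voxelSize^3)
      rec <- calcRecordRow(id, shape, dims, extentMm(model), rot, sigma, sph,
                           voxelSize, voxelCount(model))
      return(list(model = model, record = rec))
    }
  }
  stop(sprintf("cleaning produced an empty model in all %d attempts", attempts))
}

#' Segment single calcifications from an intensity volume
#'
#' Min-max rescales the volume to [0, 1], binarizes at 0.5, and extracts
#' every 26-connected component as a tightly cropped
#' \linkS4class{VoxelModel3D} with a metadata record (shape label
#' \code{"segmented"}; sphericity from the component's bounding-box
#' semi-axes).
#'
#' @param intensityVolume 3D numeric array.
#' @param voxelSizeMm isotropic voxel size in mm.
#' @param minVoxels drop components smaller than this many voxels
#'   (default 1 = keep all).
#' @return list with elements \code{models} (list of
#'   \linkS4class{VoxelModel3D}) and \code{records} (data.frame).
#' @export
segmentCalcifications <- function(intensityVolume, voxelSizeMm,
                                  minVoxels = 1L) {
  if (length(dim(intensityVolume)) != 3L)
    stop("intensityVolume must be a 3D array")
  rng <- range(intensityVolume)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("volume has no dynamic range (constant values)")
  scaled <- (intensityVolume - rng[1]) / (rng[2] - rng[1])
  bin <- scaled >= 0.5
  dim(bin) <- dim(intensityVolume)
  lab <- labelComponents(bin, full = TRUE)
  k <- max(lab)
  if (k == 0L) stop("no voxels above threshold after rescaling")
  models <- list()
  records <- emptyCalcRecords()
  kept <- 0L
  for (i in seq_len(k)) {
    comp <- lab == i
    nv <- sum(comp)
    if (nv < minVoxels) next
    kept <- kept + 1L
    g <- cropToBoundingBox(comp, pad = 1L)
    m <- VoxelModel3D(g, voxelSizeMm)
    semi <- pmax(extentMm(m) / 2, voxelSizeMm / 2)
    sph <- shapeSphericity(semi, "segmented", nv * voxelSizeMm^3)
    models[[kept]] <- m
    records <- rbind(records, calcRecordRow(
      sprintf("segmented_%d", kept), "segmented", c(NA, NA, NA),
      extentMm(m), c(0, 0, 0), NA_real_, sph, voxelSizeMm, nv))
  }
  if (kept == 0L) stop("all components smaller than minVoxels")
  list(models = models, records = records)
}
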