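# Synthetic data generation: textured mammogram-like backgrounds, analytic
# phantoms, and intensity cluster volumes.  These stand in for clinical
# images so that every pipeline stage is testable without patient data.

#' Generate a synthetic mammogram-like background
#'
#' A half-disc "breast" region (flat side at the left image edge) filled
#' with a chosen texture over a dark air background.  Textures:
#' \code{"flat"} (constant), \code{"power_law_noise"} (Gaussian noise
#' shaped to a 1/f^beta power spectrum, the classic mammographic texture
#' model; beta defaults to 3) and \code{"clustered_blobs"} (flat base plus
#' k Gaussian bumps at seeded positions).  Deterministic per seed.
#'
#' @param sizePx image side length in pixels (square image).
#' @param pixelSpacingMm pixel pitch in mm.
#' @param texture texture model.
#' @param baseValue mean pixel value inside the breast.
#' @param amplitude texture amplitude (standard deviation for power-law
#'   noise; bump height for blobs).
#' @param beta power-law exponent.
#' @param nBlobs number of bumps for \code{"clustered_blobs"}.
#' @param blobSigmaPx bump scale in pixels.
#' @param radiusFrac breast radius as a fraction of the image side.
#' @param intent,systemId,breastThickness,tubeVoltage,bitDepth image
#'   metadata (see \linkS4class{Image2D}).
#' @param seed RNG seed.
#' @return an \linkS4class{Image2D}; the breast mask is attached as
#'   attribute \code{"breastMask"} and blob centres (if any) as
#'   \code{"blobCenters"}.
#' @export
makeBackground <- function(sizePx = 600L, pixelSpacingMm = 0.1,
                           texture = c("flat", "power_law_noise",
                                       "clustered_blobs"),
                           baseValue = 500, amplitude = 50, beta = 3,
                           nBlobs = 5L, blobSigmaPx = 10,
                           radiusFrac = 0.95,
                           intent = "for_presentation",
                           systemId = "synthetic",
                           breastThickness = 50, tubeVoltage = 28,
                           bitDepth = NA_integer_, seed = NULL) {
  texture <- match.arg(texture)
  checkSeed(seed)
  n <- as.integer(sizePx)
  rowc <- matrix(seq_len(n), n, n)
  colc <- matrix(seq_len(n), n, n, byrow = TRUE)
  R <- radiusFrac * n
  mask <- (colc - 1)^2 + (rowc - n / 2)^2 <= R^2

  px <- matrix(0, n, n)
  blobCenters <- NULL
  tex <- switch(texture,
    flat = matrix(baseValue, n, n),
    power_law_noise = {
      white <- matrix(stats::rnorm(n * n), n, n)
      f1 <- c(0, seq_len(n - 1))
      f1 <- pmin(f1, n - f1) / n
      fr <- sqrt(outer(f1^2, f1^2, `+`))
      fr[1, 1] <- fr[1, 2]  # avoid the DC singularity
      shaped <- Re(stats::fft(stats::fft(white) * fr^(-beta / 2),
                              inverse = TRUE)) / (n * n)
      shaped <- shaped / stats::sd(shaped)
      baseValue + amplitude * shaped
    },
    clustered_blobs = {
      tex <- matrix(baseValue, n, n)
      ctr <- matrix(NA_real_, nBlobs, 2)
      got <- 0L
      att <- 0L
      while (got < nBlobs && att < 10000L) {
        att <- att + 1L
        cand <- c(stats::runif(1, 0.15 * n, 0.85 * n),
                  stats::runif(1, 0.1 * n, 0.6 * n))
        if (!mask[round(cand[1]), round(cand[2])]) next
        if (got > 0L) {
          d2 <- colSums((t(ctr[seq_len(got), , drop = FALSE]) - cand)^2)
          if (any(d2 < (6 * blobSigmaPx)^2)) next
        }
        got <- got + 1L
        ctr[got, ] <- cand
      }
      if (got < nBlobs) stop("could not place the requested blobs")
      for (i in seq_len(nBlobs)) {
        d2 <- (rowc - ctr[i, 1])^2 + (colc - ctr[i, 2])^2
        tex <- tex + amplitude * exp(-d2 / (2 * blobSigmaPx^2))
      }
      blobCenters <- ctr
      tex
    })
  px[mask] <- tex[mask]
  if (intent == "for_processing") {
    # detector-proportional polarity: air bright, dense tissue dark
    rng <- range(px)
    px <- rng[1] + rng[2] - px
  }
  img <- Image2D(px, pixelSpacingMm, intent = intent, systemId = systemId,
                 breastThickness = breastThickness, tubeVoltage = tubeVoltage,
                 bitDepth = bitDepth)
  attr(img, "breastMask") <- mask
  attr(img, "blobCenters") <- blobCenters
  img
}

#' Voxelized calibration sphere
#'
#' Centre-voxelized sphere sharing the toolbox voxelization rule (a voxel
#' is occupied iff its centre lies inside the sphere); used for the
#' intensity-scaling calibration with sphere diameters 0.1-1.0 mm.
#'
#' @param diameterMm sphere diameter in mm (>= voxel size).
#' @param voxelSizeMm isotropic voxel size in mm.
#' @return a \linkS4class{VoxelModel3D}.
#' @export
makeSphereVolume <- function(diameterMm, voxelSizeMm) {
  if (diameterMm < voxelSizeMm)
    stop("sphere diameter is smaller than one voxel")
  makeBaseShape("sphere", rep(diameterMm, 3L), voxelSizeMm)
}

#' Synthetic intensity cluster volume with ground truth
#'
#' k disjoint bright spherical blobs (value 1.0, with a dimmer one-voxel
#' transition shell) over a 0.1-valued noisy background; built to exercise
#' segmentation: after min-max rescaling and thresholding exactly the k
#' blob cores survive.  For \code{k = 0} the volume is exactly constant,
#' so downstream segmentation fails its dynamic-range guard.
#'
#' @param k number of blobs.
#' @param sizesMm blob diameters in mm (recycled to length k).
#' @param volumeDimsMm numeric(3) volume extent in mm.
#' @param voxelSizeMm voxel size in mm.
#' @param seed RNG seed.
#' @return list: \code{volume} (3D numeric array), \code{voxelSizeMm}, and
#'   \code{components} (data.frame of ground-truth centres and voxel
#'   counts).
#' @export
makeIntensityCluster <- function(k, sizesMm = 0.3,
                                 volumeDimsMm = c(5, 5, 5),
                                 voxelSizeMm = 0.05, seed = NULL) {
  checkSeed(seed)
  gd <- vapply(volumeDimsMm, mmToVoxels, integer(1), voxelSize = voxelSizeMm)
  if (k == 0L) {
    return(list(volume = array(0.1, gd), voxelSizeMm = voxelSizeMm,
                components = data.frame()))
  }
  sizes <- rep(sizesMm, length.out = k)
  margin <- max(sizes) / 2 + 2 * voxelSizeMm
  centers <- planPlacements("random", volumeDimsMm, voxelSizeMm, k,
                            minDistanceMm = max(sizes) + 4 * voxelSizeMm,
                            marginMm = margin)
  vol <- array(0.1 + stats::runif(prod(gd), 0, 0.05), gd)
  comp <- data.frame(id = seq_len(k), cx_mm = centers[, 1],
                     cy_mm = centers[, 2], cz_mm = centers[, 3],
                     diameter_mm = sizes, n_voxels = NA_integer_)
  for (i in seq_len(k)) {
    sph <- makeSphereVolume(sizes[i], voxelSizeMm)
    core <- cropToBoundingBox(sph@grid)
    shell <- dilateBinary(padArray(core, 1L))
    bd <- dim(shell)
    ctr <- pmin(gd, pmax(1L, as.integer(floor(centers[i, ] / voxelSizeMm)) + 1L))
    start <- pmax(1L, pmin(ctr - as.integer(floor(bd / 2)), gd - bd + 1L))
    ix <- seq.int(start[1], start[1] + bd[1] - 1L)
    iy <- seq.int(start[2], start[2] + bd[2] - 1L)
    iz <- seq.int(start[3], start[3] + bd[3] - 1L)
    block <- vol[ix, iy, iz]
    block[shell] <- 0.4       # transition shell, below the 0.5 threshold
    block[padArray(core, 1L)] <- 1.0
    vol[ix, iy, iz] <- block
    comp$n_voxels[i] <- sum(core)
  }
  list(volume = vol, voxelSizeMm = voxelSizeMm, components = comp)
}
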