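# Hybrid insertion engine: exp(-mu*T) projection templates, degradation,
# For-Presentation contrast calibration, distance-transform intensity
# scaling for 2D models, and multiplicative insertion.

#' Ray-trace a voxel model into a projection template
#'
#' Parallel-beam projection along a principal axis: the traversed thickness
#' T per ray is the occupied-voxel count times the voxel size, and the
#' template value is exp(-mu * T).  The template is resampled to the target
#' pixel spacing by nearest neighbour; the background is exactly 1.0.
#'
#' @param model a non-empty \linkS4class{VoxelModel3D}.
#' @param muPerMm linear attenuation coefficient of the lesion material
#'   (1/mm, > 0).
#' @param axis projection axis: \code{"z"} (default), \code{"y"} or
#'   \code{"x"}.
#' @param pixelSpacingMm output pixel pitch (default: the voxel size).
#' @return a \linkS4class{Template2D} in processing polarity.
#' @examples
#' slab <- VoxelModel3D(array(TRUE, c(5, 5, 10)), 0.1)  # T = 1 mm along z
#' min(templateValues(rayTrace(slab, muPerMm = 0.5)))   # exp(-0.5)
#' @export
rayTrace <- function(model, muPerMm, axis = c("z", "y", "x"),
                     pixelSpacingMm = voxelSize(model)) {
  stopifnot(is(model, "VoxelModel3D"))
  axis <- match.arg(axis)
  if (muPerMm <= 0) stop("muPerMm must be > 0")
  if (voxelCount(model) == 0L) stop("cannot ray-trace an empty model")
  ax <- match(axis, c("x", "y", "z"))
  counts <- cpp_project_counts(as.vector(model@grid), dim(model@grid), ax)
  tv <- exp(-muPerMm * counts * model@voxelSize)
  if (abs(pixelSpacingMm - model@voxelSize) > 1e-12) {
    f <- model@voxelSize / pixelSpacingMm
    nd <- pmax(1L, as.integer(round(dim(tv) * f)))
    idx <- lapply(1:2, function(k)
      pmin(dim(tv)[k], pmax(1L, as.integer(ceiling((seq_len(nd[k]) - 0.5) / f)))))
    tv <- tv[idx[[1]], idx[[2]], drop = FALSE]
  }
  Template2D(tv, pixelSpacingMm, polarity = "for_processing")
}

#' Apply degradation factors to a template
#'
#' Models the blurring and x-ray scatter an ideal projection undergoes:
#' Gaussian blur of the attenuation deficit (1 - TV) with
#' \code{blurSigmaMm}, followed by a scatter contrast reduction
#' TV' = (TV + s) / (1 + s) with s = scatter / (1 - scatter).  The
#' background outside the (dilated) lesion support is re-clamped to
#' exactly 1.0.
#'
#' @param template a \linkS4class{Template2D}.
#' @param blurSigmaMm Gaussian blur sigma in mm (>= 0; default 0.1).
#' @param scatterFraction scatter-to-total fraction in [0, 1) (default 0).
#' @return the degraded \linkS4class{Template2D}.
#' @export
degradeTemplate <- function(template, blurSigmaMm = 0.1,
                            scatterFraction = 0) {
  stopifnot(is(template, "Template2D"))
  if (blurSigmaMm < 0) stop("blurSigmaMm must be >= 0")
  if (scatterFraction < 0 || scatterFraction >= 1)
    stop("scatterFraction must lie in [0, 1)")
  tv <- template@values
  support <- tv != 1
  if (blurSigmaMm > 0 && any(support)) {
    sigmaPx <- blurSigmaMm / template@pixelSpacing
    deficit <- 1 - tv
    deficit <- ebMatrix(EBImage::gblur(EBImage::Image(deficit),
                                        sigma = sigmaPx))
    tv <- 1 - deficit
    radius <- as.integer(ceiling(3 * sigmaPx))
    supp <- EBImage::dilate(EBImage::Image(support * 1),
                            EBImage::makeBrush(2L * radius + 1L,
                                               shape = "box")) > 0
    support <- matrix(as.logical(supp), nrow(tv), ncol(tv))
  }
  if (scatterFraction > 0) {
    s <- scatterFraction / (1 - scatterFraction)
    tv <- (tv + s) / (1 + s)
  }
  tv[!support] <- 1
  Template2D(tv, template@pixelSpacing, polarity = template@polarity)
}

#' Weber contrast between mean pixel values
#'
#' (MPV_calcification - MPV_background) / MPV_background; negative in
#' processing polarity (calcifications darker), positive in presentation
#' polarity.
#'
#' @param mpvCalc mean pixel value over the calcification region.
#' @param mpvBackground mean pixel value over the adjacent background
#'   (non-zero).
#' @return dimensionless contrast.
#' @export
weberContrast <- function(mpvCalc, mpvBackground) {
  if (any(mpvBackground == 0)) stop("background mean must be non-zero")
  (mpvCalc - mpvBackground) / mpvBackground
}

#' Fit the For-Presentation contrast calibration
#'
#' Ordinary least squares for the quasi-linear relationship
#' presentation contrast = w * processing contrast + k, from paired Weber
#' contrasts of the same calcifications measured in both image types.
#'
#' @param processingContrast numeric vector of For-Processing contrasts.
#' @param presentationContrast matching For-Presentation contrasts.
#' @param systemId acquisition system label.
#' @return a \linkS4class{ContrastCalibration}.
#' @export
fitContrastCalibration <- function(processingContrast, presentationContrast,
                                   systemId = "unknown") {
  if (length(processingContrast) != length(presentationContrast))
    stop("contrast vectors must have equal length")
  if (length(processingContrast) < 2L)
    stop("at least two contrast pairs are required")
  if (stats::var(processingContrast) == 0)
    stop("degenerate design: all processing contrasts are equal")
  fit <- stats::lm(presentationContrast ~ processingContrast)
  co <- stats::coef(fit)
  ContrastCalibration(wContrast = unname(co[2]), kContrast = unname(co[1]),
                      systemId = systemId)
}

#' Correct a processing template for For-Presentation insertion
#'
#' Per pixel with TV < 1 the processing contrast TV - 1 is mapped through
#' the calibrated linear relationship and the presentation TV becomes
#' 1 + (w * (TV - 1) + k); background pixels (TV = 1) are untouched.  For
#' physically sensible calibrations (w < 0, k >= 0) calcification TVs
#' exceed 1.0, brightening the calcifications on multiplication.
#'
#' @param template a processing-polarity \linkS4class{Template2D}.
#' @param calibration a \linkS4class{ContrastCalibration}.
#' @return a presentation-polarity \linkS4class{Template2D}.
#' @export
toPresentation <- function(template, calibration) {
  stopifnot(is(template, "Template2D"), is(calibration, "ContrastCalibration"))
  if (template@polarity != "for_processing")
    stop("template is already in presentation polarity")
  tv <- template@values
  calc <- tv < 1
  tv[calc] <- 1 + (calibration@wContrast * (tv[calc] - 1) +
                     calibration@kContrast)
  Template2D(tv, template@pixelSpacing, polarity = "for_presentation")
}

#' Fit the distance-transform intensity-scaling weights
#'
#' Multiple linear regression of ray-traced template values on Euclidean
#' distance-transform values, breast thickness (mm) and tube voltage (kV):
#' TV = w_dist * d + w_thick * thickness + w_volt * voltage + k.  The
#' training set pairs, for each calibration sphere, the distance transform
#' of the sphere's binary silhouette with its ray-traced template across
#' thicknesses and voltages.
#'
#' @param distValues numeric vector of distance-transform values.
#' @param rayTracedTV matching ray-traced template values.
#' @param thicknessMm matching breast thickness values (mm).
#' @param voltageKV matching tube voltage values (kV).
#' @return a \linkS4class{ScalingWeights}.
#' @export
fitScalingWeights <- function(distValues, rayTracedTV, thicknessMm,
                              voltageKV) {
  n <- length(rayTracedTV)
  if (length(distValues) != n || length(thicknessMm) != n ||
      length(voltageKV) != n)
    stop("all regression inputs must have equal length")
  fit <- stats::lm(rayTracedTV ~ distValues + thicknessMm + voltageKV)
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("rank-deficient design: vary thickness and voltage across spheres")
  ScalingWeights(wDist = unname(co["distValues"]),
                 wThick = unname(co["thicknessMm"]),
                 wVolt = unname(co["voltageKV"]),
                 kIntensity = unname(co["(Intercept)"]))
}

#' Build the sphere training set for the scaling-weight fit
#'
#' Ray-traces binary spheres (one per diameter), converts each template's
#' lesion support to a binary silhouette, distance-transforms it, and pairs
#' the in-support distance values with the ray-traced TVs for each
#' (thickness, voltage) combination.  A thickness/voltage perturbation of
#' the TVs can be supplied to emulate system dependence when building
#' synthetic calibration data.
#'
#' @param diametersMm sphere diameters in mm (default 0.1-1.0).
#' @param voxelSizeMm sphere voxel size.
#' @param muPerMm attenuation coefficient used for ray-tracing.
#' @param thicknessMm,voltageKV vectors of condition values; the training
#'   set is their Cartesian product.
#' @param tvModifier optional function(tv, thickness, voltage) returning
#'   modified TVs per condition.
#' @return data.frame with columns dist, tv, thickness, voltage, diameter.
#' @export
sphereTrainingSet <- function(diametersMm = seq(0.1, 1.0, by = 0.1),
                              voxelSizeMm = 0.02, muPerMm = 1.0,
                              thicknessMm = 50, voltageKV = 28,
                              tvModifier = NULL) {
  out <- list()
  for (d in diametersMm) {
    sph <- makeSphereVolume(d, voxelSizeMm)
    tpl <- rayTrace(sph, muPerMm = muPerMm)
    tv <- templateValues(tpl)
    silhouette <- tv < 1
    dist <- ebMatrix(EBImage::distmap(EBImage::Image(silhouette * 1)))
    inside <- silhouette
    for (t in thicknessMm) for (v in voltageKV) {
      tvc <- if (is.null(tvModifier)) tv else tvModifier(tv, t, v)
      out[[length(out) + 1L]] <- data.frame(
        dist = dist[inside], tv = tvc[inside], thickness = t, voltage = v,
        diameter = d)
    }
  }
  do.call(rbind, out)
}

#' Intensity-scale a 2D cluster model into a template
#'
#' The ray-tracing surrogate for flat 2D models: Euclidean
#' distance-to-background transform of the binary mask, mapping of the
#' non-zero distances through the fitted linear relationship (distance,
#' thickness, voltage), background reset to exactly 1.0, and Gaussian
#' smoothing of the calcification edges with the background support
#' protected.
#'
#' @param cluster a non-empty \linkS4class{Cluster2D}.
#' @param weights a \linkS4class{ScalingWeights}.
#' @param thicknessMm breast thickness of the target image (mm).
#' @param voltageKV tube voltage of the target image (kV).
#' @param pixelSpacingMm template pixel pitch in mm.
#' @param smoothSigmaPx edge-smoothing Gaussian sigma in px (default 0.5).
#' @return a processing-polarity \linkS4class{Template2D}.
#' @export
scale2DTemplate <- function(cluster, weights, thicknessMm, voltageKV,
                            pixelSpacingMm, smoothSigmaPx = 0.5) {
  stopifnot(is(cluster, "Cluster2D"), is(weights, "ScalingWeights"))
  mask <- cluster@mask
  if (!any(mask)) stop("cannot scale an empty cluster mask")
  d <- ebMatrix(EBImage::distmap(EBImage::Image(mask * 1)))
  tv <- matrix(1, nrow(mask), ncol(mask))
  tv[mask] <- weights@wDist * d[mask] + weights@wThick * thicknessMm +
    weights@wVolt * voltageKV + weights@kIntensity
  if (smoothSigmaPx > 0) {
    tv <- ebMatrix(EBImage::gblur(EBImage::Image(tv), sigma = smoothSigmaPx))
    tv[!mask] <- 1  # protect the background support
  }
  Template2D(tv, pixelSpacingMm, polarity = "for_processing")
}

#' Insert a template into a mammographic image by multiplication
#'
#' Pixels under the template footprint are multiplied by the template
#' values; every pixel outside is bit-exact unchanged.  The template
#' polarity must match the image intent (run \code{\link{toPresentation}}
#' first for For-Presentation images).  Integer-typed images are rounded
#' half up and clipped to the stored bit depth.
#'
#' @param image an \linkS4class{Image2D}.
#' @param template a \linkS4class{Template2D}.
#' @param location 1-based (row, col) of the template's top-left corner.
#' @return the modified \linkS4class{Image2D}.
#' @export
insertTemplate <- function(image, template, location) {
  stopifnot(is(image, "Image2D"), is(template, "Template2D"))
  if (template@polarity != image@intent)
    stop(sprintf(
      "polarity mismatch: %s template on a %s image (apply toPresentation())",
      template@polarity, image@intent))
  loc <- as.integer(location)
  tv <- template@values
  r2 <- loc[1] + nrow(tv) - 1L
  c2 <- loc[2] + ncol(tv) - 1L
  if (loc[1] < 1L || loc[2] < 1L || r2 > nrow(image@pixels) ||
      c2 > ncol(image@pixels))
    stop("template footprint extends beyond the image")
  px <- image@pixels
  patch <- px[loc[1]:r2, loc[2]:c2] * tv
  if (!is.na(image@bitDepth)) {
    maxv <- 2^image@bitDepth - 1
    patch <- pmin(maxv, pmax(0, floor(patch + 0.5)))
  }
  px[loc[1]:r2, loc[2]:c2] <- patch
  new("Image2D", pixels = px, pixelSpacing = image@pixelSpacing,
      intent = image@intent, systemId = image@systemId,
      breastThickness = image@breastThickness,
      tubeVoltage = image@tubeVoltage, bitDepth = image@bitDepth)
}
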