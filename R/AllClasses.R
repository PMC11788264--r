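#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib MicroCalcSim, .registration = TRUE
NULL

#' VoxelModel3D: binary occupancy grid with isotropic voxel size
#'
#' The central lesion representation: a 3D array of 0/1 occupancy values
#' together with the physical edge length of one (isotropic) voxel in mm.
#'
#' @slot grid logical 3D array; \code{TRUE} marks occupied voxels.
#' @slot voxelSize numeric(1), edge length of a voxel in mm (> 0).
#' @exportClass VoxelModel3D
setClass("VoxelModel3D",
  representation(grid = "array", voxelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@grid)) != 3L)
      msg <- c(msg, "grid must be a 3D array")
    if (!is.logical(object@grid))
      msg <- c(msg, "grid must be logical (binary occupancy)")
    if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
        object@voxelSize <= 0)
      msg <- c(msg, "voxelSize must be a single positive number")
    if (!is.null(dim(object@grid)) && any(dim(object@grid) < 1L))
      msg <- c(msg, "grid dimensions must all be >= 1")
    if (anyNA(object@grid))
      msg <- c(msg, "grid must not contain NA")
    if (is.null(msg)) TRUE else msg
  })

#' Image2D: a mammogram-like 2D pixel matrix with acquisition metadata
#'
#' @slot pixels numeric matrix of pixel values.
#' @slot pixelSpacing numeric(1), pixel pitch in mm (> 0).
#' @slot intent \code{"for_presentation"} (display-processed, calcifications
#'   bright) or \code{"for_processing"} (detector-proportional, calcifications
#'   dark; inverted before texture analysis).
#' @slot systemId character(1) free-text acquisition system identifier.
#' @slot breastThickness numeric(1), compressed breast thickness in mm.
#' @slot tubeVoltage numeric(1), tube voltage in kV.
#' @slot bitDepth integer(1); stored integer bit depth, or \code{NA} for
#'   floating-point images (no rounding on insertion).
#' @exportClass Image2D
setClass("Image2D",
  representation(pixels = "matrix", pixelSpacing = "numeric",
                 intent = "character", systemId = "character",
                 breastThickness = "numeric", tubeVoltage = "numeric",
                 bitDepth = "integer"),
  prototype(systemId = "unknown", breastThickness = NA_real_,
            tubeVoltage = NA_real_, bitDepth = NA_integer_),
  validity = function(object) {
    msg <- NULL
    if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
        object@pixelSpacing <= 0)
      msg <- c(msg, "pixelSpacing must be a single positive number (mm)")
    if (!object@intent %in% c("for_presentation", "for_processing"))
      msg <- c(msg, "intent must be 'for_presentation' or 'for_processing'")
    if (is.null(msg)) TRUE else msg
  })

#' Template2D: multiplicative projection template
#'
#' Real-valued template values (TVs); background is exactly 1.0.  In
#' processing polarity calcification TVs lie in (0, 1]; after
#' For-Presentation correction calcification TVs exceed 1.0.
#'
#' @slot values numeric matrix of template values.
#' @slot pixelSpacing numeric(1), mm.
#' @slot polarity \code{"for_processing"} or \code{"for_presentation"}.
#' @exportClass Template2D
setClass("Template2D",
  representation(values = "matrix", pixelSpacing = "numeric",
                 polarity = "character"),
  prototype(polarity = "for_processing"),
  validity = function(object) {
    msg <- NULL
    if (length(object@pixelSpacing) != 1L || object@pixelSpacing <= 0)
      msg <- c(msg, "pixelSpacing must be positive")
    if (!object@polarity %in% c("for_presentation", "for_processing"))
      msg <- c(msg, "polarity must be 'for_presentation' or 'for_processing'")
    if (anyNA(object@values) || any(!is.finite(object@values)))
      msg <- c(msg, "template values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Cluster2D: binary 2D cluster mask anchored in image coordinates
#'
#' @slot mask logical matrix; \code{TRUE} marks calcification pixels.
#' @slot origin integer(2), 1-based (row, col) of the mask's top-left corner
#'   in the source image.
#' @slot nCalcs integer(1), number of 8-connected components.
#' @exportClass Cluster2D
setClass("Cluster2D",
  representation(mask = "matrix", origin = "integer", nCalcs = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (length(object@origin) != 2L) msg <- c(msg, "origin must be (row, col)")
    if (is.null(msg)) TRUE else msg
  })

#' Cluster3D: an assembled 3D microcalcification cluster
#'
#' @slot model the combined \linkS4class{VoxelModel3D}.
#' @slot placements data.frame with one row per placed calcification
#'   (id, center voxel indices, center mm, extent).
#' @slot record list of bookkeeping fields (cluster dims, voxel size, seed,
#'   placement mode, overlap log).
#' @exportClass Cluster3D
setClass("Cluster3D",
  representation(model = "VoxelModel3D", placements = "data.frame",
                 record = "list"))

#' CalcDatabase: a set of single-calcification models with metadata
#'
#' @slot records data.frame, one row per model (shape, dims, sphericity, ...).
#' @slot models list of \linkS4class{VoxelModel3D}, parallel to
#'   \code{records}.
#' @exportClass CalcDatabase
setClass("CalcDatabase",
  representation(records = "data.frame", models = "list"),
  validity = function(object) {
    if (nrow(object@records) != length(object@models))
      "one record per stored model required" else TRUE
  })

#' ContrastCalibration: For-Presentation contrast mapping coefficients
#'
#' Linear map from For-Processing Weber contrast to For-Presentation Weber
#' contrast for one acquisition system.
#'
#' @slot systemId character(1).
#' @slot wContrast numeric(1) slope.
#' @slot kContrast numeric(1) intercept.
#' @exportClass ContrastCalibration
setClass("ContrastCalibration",
  representation(systemId = "character", wContrast = "numeric",
                 kContrast = "numeric"),
  prototype(systemId = "unknown"),
  validity = function(object) {
    if (!all(is.finite(c(object@wContrast, object@kContrast))))
      "coefficients must be finite" else TRUE
  })

#' ScalingWeights: distance-transform intensity-scaling coefficients
#'
#' Coefficients of the empirical map from Euclidean distance-transform
#' values, breast thickness (mm) and tube voltage (kV) to ray-traced
#' template values.
#'
#' @slot wDist numeric(1) weight of the distance-transform value.
#' @slot wThick numeric(1) weight of breast thickness.
#' @slot wVolt numeric(1) weight of tube voltage.
#' @slot kIntensity numeric(1) intercept.
#' @exportClass ScalingWeights
setClass("ScalingWeights",
  representation(wDist = "numeric", wThick = "numeric", wVolt = "numeric",
                 kIntensity = "numeric"),
  validity = function(object) {
    v <- c(object@wDist, object@wThick, object@wVolt, object@kIntensity)
    if (length(v) != 4L || !all(is.finite(v)))
      "all four coefficients must be finite scalars" else TRUE
  })

## ---- constructors -------------------------------------------------------

#' Create a VoxelModel3D
#'
#' @param grid a 3D array coercible to logical occupancy (0/1).
#' @param voxelSize voxel edge length in mm.
#' @return a \linkS4class{VoxelModel3D}.
#' @examples
#' m <- VoxelModel3D(array(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3)), 0.1)
#' voxelCount(m)
#' @export
VoxelModel3D <- function(grid, voxelSize) {
  if (!is.logical(grid)) {
    g <- grid != 0
    dim(g) <- dim(grid)
    grid <- g
  }
  new("VoxelModel3D", grid = grid, voxelSize = as.numeric(voxelSize))
}

#' Create an Image2D
#'
#' @param pixels numeric matrix.
#' @param pixelSpacing pixel pitch in mm.
#' @param intent DICOM-style presentation intent, \code{"for_presentation"}
#'   or \code{"for_processing"}.
#' @param systemId acquisition system identifier.
#' @param breastThickness compressed breast thickness in mm.
#' @param tubeVoltage tube voltage in kV.
#' @param bitDepth stored integer bit depth or \code{NA} for float.
#' @return an \linkS4class{Image2D}.
#' @export
Image2D <- function(pixels, pixelSpacing, intent = "for_presentation",
                    systemId = "unknown", breastThickness = NA_real_,
                    tubeVoltage = NA_real_, bitDepth = NA_integer_) {
  new("Image2D", pixels = as.matrix(pixels),
      pixelSpacing = as.numeric(pixelSpacing), intent = intent,
      systemId = systemId, breastThickness = as.numeric(breastThickness),
      tubeVoltage = as.numeric(tubeVoltage),
      bitDepth = as.integer(bitDepth))
}

#' Create a Template2D
#' @param values numeric matrix of template values (background 1.0).
#' @param pixelSpacing pixel pitch in mm.
#' @param polarity template polarity.
#' @return a \linkS4class{Template2D}.
#' @export
Template2D <- function(values, pixelSpacing, polarity = "for_processing") {
  new("Template2D", values = as.matrix(values),
      pixelSpacing = as.numeric(pixelSpacing), polarity = polarity)
}

#' Create a Cluster2D
#' @param mask logical matrix (TRUE = calcification).
#' @param origin 1-based (row, col) of the top-left corner in the image.
#' @return a \linkS4class{Cluster2D}.
#' @export
Cluster2D <- function(mask, origin = c(1L, 1L)) {
  mask <- mask != 0
  n <- countComponents2D(mask)
  new("Cluster2D", mask = mask, origin = as.integer(origin),
      nCalcs = as.integer(n))
}

#' Create an empty calcification database
#' @param records data.frame of metadata rows.
#' @param models list of \linkS4class{VoxelModel3D}.
#' @return a \linkS4class{CalcDatabase}.
#' @export
CalcDatabase <- function(records = emptyCalcRecords(), models = list()) {
  new("CalcDatabase", records = records, models = models)
}

#' @rdname ContrastCalibration-class
#' @param systemId system identifier.
#' @param wContrast slope.
#' @param kContrast intercept.
#' @export
ContrastCalibration <- function(wContrast, kContrast, systemId = "unknown") {
  new("ContrastCalibration", systemId = systemId,
      wContrast = as.numeric(wContrast), kContrast = as.numeric(kContrast))
}

#' @rdname ScalingWeights-class
#' @param wDist,wThick,wVolt,kIntensity regression coefficients.
#' @export
ScalingWeights <- function(wDist, wThick, wVolt, kIntensity) {
  new("ScalingWeights", wDist = as.numeric(wDist),
      wThick = as.numeric(wThick), wVolt = as.numeric(wVolt),
      kIntensity = as.numeric(kIntensity))
}

## ---- accessors ----------------------------------------------------------

#' @describeIn VoxelModel3D-class occupancy grid (logical array)
#' @param object a VoxelModel3D.
#' @export
setGeneric("voxelGrid", function(object) standardGeneric("voxelGrid"))
#' @rdname VoxelModel3D-class
setMethod("voxelGrid", "VoxelModel3D", function(object) object@grid)

#' @describeIn VoxelModel3D-class voxel edge length in mm
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname VoxelModel3D-class
setMethod("voxelSize", "VoxelModel3D", function(object) object@voxelSize)
#' @rdname VoxelModel3D-class
setMethod("voxelSize", "Cluster3D", function(object) object@model@voxelSize)

#' @describeIn VoxelModel3D-class number of occupied voxels (V of the
#'   sphericity formula, in voxels)
#' @export
setGeneric("voxelCount", function(object) standardGeneric("voxelCount"))
#' @rdname VoxelModel3D-class
setMethod("voxelCount", "VoxelModel3D", function(object) sum(object@grid))

#' @describeIn VoxelModel3D-class occupied bounding-box extent in mm per axis
#' @export
setGeneric("extentMm", function(object) standardGeneric("extentMm"))
#' @rdname VoxelModel3D-class
setMethod("extentMm", "VoxelModel3D", function(object) {
  bb <- boundingBox(object@grid)
  if (is.null(bb)) return(c(0, 0, 0))
  (bb[2, ] - bb[1, ] + 1L) * object@voxelSize
})

#' @describeIn Image2D-class pixel matrix
#' @param object an Image2D.
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
#' @rdname Image2D-class
setMethod("imagePixels", "Image2D", function(object) object@pixels)

#' @describeIn Image2D-class pixel pitch in mm
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname Image2D-class
setMethod("pixelSpacing", "Image2D", function(object) object@pixelSpacing)
#' @rdname Template2D-class
setMethod("pixelSpacing", "Template2D", function(object) object@pixelSpacing)

#' @describeIn Image2D-class presentation intent
#' @export
setGeneric("imageIntent", function(object) standardGeneric("imageIntent"))
#' @rdname Image2D-class
setMethod("imageIntent", "Image2D", function(object) object@intent)

#' @describeIn Template2D-class template value matrix
#' @param object a Template2D.
#' @export
setGeneric("templateValues", function(object) standardGeneric("templateValues"))
#' @rdname Template2D-class
setMethod("templateValues", "Template2D", function(object) object@values)

#' @describeIn Template2D-class template polarity
#' @export
setGeneric("templatePolarity",
           function(object) standardGeneric("templatePolarity"))
#' @rdname Template2D-class
setMethod("templatePolarity", "Template2D", function(object) object@polarity)

#' @describeIn Cluster2D-class binary mask
#' @param object a Cluster2D.
#' @export
setGeneric("clusterMask", function(object) standardGeneric("clusterMask"))
#' @rdname Cluster2D-class
setMethod("clusterMask", "Cluster2D", function(object) object@mask)

#' @describeIn Cluster2D-class (row, col) origin in the image
#' @export
setGeneric("clusterOrigin", function(object) standardGeneric("clusterOrigin"))
#' @rdname Cluster2D-class
setMethod("clusterOrigin", "Cluster2D", function(object) object@origin)

#' @describeIn Cluster2D-class number of connected components
#' @export
setGeneric("nCalcs", function(object) standardGeneric("nCalcs"))
#' @rdname Cluster2D-class
setMethod("nCalcs", "Cluster2D", function(object) object@nCalcs)
#' @rdname Cluster3D-class
setMethod("nCalcs", "Cluster3D", function(object) nrow(object@placements))

#' @describeIn Cluster3D-class combined voxel model
#' @param object a Cluster3D.
#' @export
setGeneric("clusterModel", function(object) standardGeneric("clusterModel"))
#' @rdname Cluster3D-class
setMethod("clusterModel", "Cluster3D", function(object) object@model)

#' @describeIn Cluster3D-class placement table (one row per calcification)
#' @export
setGeneric("placements", function(object) standardGeneric("placements"))
#' @rdname Cluster3D-class
setMethod("placements", "Cluster3D", function(object) object@placements)

#' @describeIn Cluster3D-class bookkeeping record
#' @export
setGeneric("clusterRecord", function(object) standardGeneric("clusterRecord"))
#' @rdname Cluster3D-class
setMethod("clusterRecord", "Cluster3D", function(object) object@record)

#' @describeIn CalcDatabase-class metadata table
#' @param object a CalcDatabase.
#' @export
setGeneric("dbRecords", function(object) standardGeneric("dbRecords"))
#' @rdname CalcDatabase-class
setMethod("dbRecords", "CalcDatabase", function(object) object@records)

#' @describeIn CalcDatabase-class list of stored models
#' @export
setGeneric("dbModels", function(object) standardGeneric("dbModels"))
#' @rdname CalcDatabase-class
setMethod("dbModels", "CalcDatabase", function(object) object@models)

## ---- show methods -------------------------------------------------------

setMethod("show", "VoxelModel3D", function(object) {
  d <- dim(object@grid)
  cat(sprintf("VoxelModel3D: %d x %d x %d voxels @ %g mm, %d occupied (%.3g%%)\n",
              d[1], d[2], d[3], object@voxelSize, sum(object@grid),
              100 * mean(object@grid)))
  ext <- extentMm(object)
  cat(sprintf("  occupied extent: %.3g x %.3g x %.3g mm\n",
              ext[1], ext[2], ext[3]))
})

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Image2D: %d x %d px @ %g mm (%s)\n", d[1], d[2],
              object@pixelSpacing, object@intent))
  cat(sprintf("  system: %s, thickness: %g mm, voltage: %g kV\n",
              object@systemId, object@breastThickness, object@tubeVoltage))
})

setMethod("show", "Template2D", function(object) {
  d <- dim(object@values)
  cat(sprintf("Template2D: %d x %d px @ %g mm (%s), TV range [%.4g, %.4g]\n",
              d[1], d[2], object@pixelSpacing, object@polarity,
              min(object@values), max(object@values)))
})

setMethod("show", "Cluster2D", function(object) {
  d <- dim(object@mask)
  cat(sprintf("Cluster2D: %d x %d px mask at (%d, %d), %d calcifications\n",
              d[1], d[2], object@origin[1], object@origin[2], object@nCalcs))
})

setMethod("show", "Cluster3D", function(object) {
  cat(sprintf("Cluster3D: %d placed calcifications\n", nrow(object@placements)))
  show(object@model)
})

setMethod("show", "CalcDatabase", function(object) {
  cat(sprintf("CalcDatabase: %d models\n", length(object@models)))
  if (nrow(object@records))
    print(utils::head(object@records, 5))
})

setMethod("show", "ContrastCalibration", function(object) {
  cat(sprintf("ContrastCalibration [%s]: presentation = %.4g * processing + %.4g\n",
              object@systemId, object@wContrast, object@kContrast))
})

setMethod("show", "ScalingWeights", function(object) {
  cat(sprintf("ScalingWeights: TV = %.4g*dist + %.4g*thickness + %.4g*voltage + %.4g\n",
              object@wDist, object@wThick, object@wVolt, object@kIntensity))
})
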