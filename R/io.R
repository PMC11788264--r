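# Model and image storage: sparse and RAW voxel containers, metadata
# tables, raster images with JSON sidecars.

SPARSE_MAGIC <- charToRaw("MCSVOX01")

#' Save a voxel model
#'
#' Two lossless containers are provided.  \code{"sparse"}: a (by default
#' gzip-compressed) binary coordinate-list file holding the grid
#' dimensions, voxel size and the linear indices of occupied voxels --
#' compact whenever occupancy is low.  \code{"raw"}: headerless uint8
#' (x-fastest, little-endian) with a JSON sidecar (\code{<path>.json})
#' carrying dimensions and voxel size.  Both round-trip bit-exactly.
#'
#' @param model a \linkS4class{VoxelModel3D}.
#' @param path output file path (sidecar written next to it for raw).
#' @param format \code{"sparse"} or \code{"raw"}.
#' @param compress gzip the sparse container (default TRUE).
#' @return the path, invisibly.
#' @export
saveModel <- function(model, path, format = c("sparse", "raw"),
                      compress = TRUE) {
  stopifnot(is(model, "VoxelModel3D"))
  format <- match.arg(format)
  d <- dim(model@grid)
  if (format == "sparse") {
    idx <- which(model@grid)
    con <- if (compress) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeBin(SPARSE_MAGIC, con)
    writeBin(as.integer(d), con, size = 4L, endian = "little")
    writeBin(as.numeric(model@voxelSize), con, size = 8L, endian = "little")
    writeBin(length(idx), con, size = 4L, endian = "little")
    writeBin(as.integer(idx), con, size = 4L, endian = "little")
  } else {
    con <- file(path, "wb")
    writeBin(as.raw(as.integer(model@grid)), con)  # x-fastest (column-major)
    close(con)
    jsonlite::write_json(
      list(dims = d, voxel_size_mm = model@voxelSize,
           format = "raw-uint8-le-x-fastest"),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Load a voxel model saved by \code{\link{saveModel}}
#'
#' @param path file path.
#' @param format \code{"sparse"} or \code{"raw"} (raw requires the JSON
#'   sidecar next to the file).
#' @return a \linkS4class{VoxelModel3D}.
#' @export
loadModel <- function(path, format = c("sparse", "raw")) {
  format <- match.arg(format)
  if (format == "sparse") {
    con <- gzfile(path, "rb")  # reads plain files transparently too
    on.exit(close(con))
    magic <- readBin(con, "raw", n = length(SPARSE_MAGIC))
    if (!identical(magic, SPARSE_MAGIC))
      stop("not a sparse voxel-model file (bad magic)")
    d <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
    vs <- readBin(con, "numeric", n = 1L, size = 8L, endian = "little")
    n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    idx <- readBin(con, "integer", n = n, size = 4L, endian = "little")
    if (length(idx) != n) stop("corrupt sparse model file (truncated)")
    g <- logical(prod(d))
    g[idx] <- TRUE
    dim(g) <- d
    VoxelModel3D(g, vs)
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("RAW model requires the JSON sidecar: ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    d <- as.integer(meta$dims)
    bytes <- readBin(path, "raw", n = prod(d) + 1L)
    if (length(bytes) != prod(d))
      stop("RAW file size does not match sidecar dims")
    g <- as.logical(as.integer(bytes))
    dim(g) <- d
    VoxelModel3D(g, as.numeric(meta$voxel_size_mm))
  }
}

#' Write a metadata table to CSV
#'
#' Stable column order, lossless round trip via \code{\link{readRecords}}.
#'
#' @param records data.frame of model metadata.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
writeRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a metadata table written by \code{\link{writeRecords}}
#'
#' @param path CSV path.
#' @param requiredCols columns that must be present (schema check); extra
#'   columns are preserved with a warning.
#' @return data.frame.
#' @export
readRecords <- function(path, requiredCols = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(requiredCols)) {
    missing <- setdiff(requiredCols, names(df))
    if (length(missing))
      stop("schema mismatch: missing columns ",
           paste(missing, collapse = ", "))
    extra <- setdiff(names(df), requiredCols)
    if (length(extra))
      warning("unknown columns preserved: ", paste(extra, collapse = ", "))
  }
  df
}

#' Read a 2D image with acquisition metadata
#'
#' Supported containers: 8/16-bit PNG, TIFF, or a plain CSV pixel matrix,
#' each accompanied by a JSON sidecar (\code{<path>.json} by default)
#' providing \code{pixel_spacing_mm}, \code{intent}
#' (\code{"for_presentation"}/\code{"for_processing"}) and optionally
#' \code{breast_thickness_mm}, \code{tube_voltage_kV}, \code{system_id} and
#' \code{bit_depth}.  PNG/TIFF pixel fractions are rescaled to integer
#' values when a bit depth is declared.
#'
#' @param path image file (.png, .tif/.tiff or .csv).
#' @param sidecar JSON sidecar path (default \code{<path>.json}).
#' @param pixelSpacingMm overrides/supplies the pixel spacing when the
#'   sidecar lacks it.
#' @return an \linkS4class{Image2D}.
#' @export
readImage2D <- function(path, sidecar = paste0(path, ".json"),
                        pixelSpacingMm = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported image container: .", ext))
  if (length(dim(px)) == 3L) px <- px[, , 1]
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  spacing <- meta$pixel_spacing_mm
  if (is.null(spacing)) spacing <- pixelSpacingMm
  if (is.null(spacing))
    stop("pixel spacing missing: provide it in the sidecar or via ",
         "pixelSpacingMm")
  intent <- meta$intent
  if (is.null(intent))
    stop("presentation intent missing from the sidecar (set 'intent' to ",
         "'for_presentation' or 'for_processing')")
  bdRaw <- unlist(meta$bit_depth)
  bd <- if (length(bdRaw) >= 1L && is.numeric(bdRaw))
    as.integer(bdRaw[1]) else NA_integer_
  if (ext %in% c("png", "tif", "tiff")) {
    if (!is.null(meta$value_min) && !is.null(meta$value_max)) {
      px <- meta$value_min + px * (meta$value_max - meta$value_min)
    } else if (!is.na(bd)) {
      px <- round(px * (2^bd - 1))
    }
  }
  Image2D(px, spacing, intent = intent,
          systemId = if (is.null(meta$system_id)) "unknown" else meta$system_id,
          breastThickness = if (is.null(meta$breast_thickness_mm)) NA_real_
                            else meta$breast_thickness_mm,
          tubeVoltage = if (is.null(meta$tube_voltage_kV)) NA_real_
                        else meta$tube_voltage_kV,
          bitDepth = bd)
}

#' Write an image as raster plus JSON sidecar
#'
#' TIFF targets (\code{.tif}/\code{.tiff}) are written as 32-bit float
#' samples -- the lossless choice for floating-point images; PNG targets
#' are 8-bit.  Pixel values are rescaled to [0, 1] for storage and the
#' original value range is recorded in the sidecar so that
#' \code{\link{readImage2D}} restores the physical values.
#'
#' @param image an \linkS4class{Image2D}.
#' @param path output path (.tif/.tiff or .png).
#' @return the path, invisibly.
#' @export
writeImage2D <- function(image, path) {
  rng <- range(image@pixels)
  span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  px <- (image@pixels - rng[1]) / span
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = 32L)
  } else {
    png::writePNG(px, path)
  }
  meta <- list(pixel_spacing_mm = image@pixelSpacing, intent = image@intent,
               system_id = image@systemId,
               breast_thickness_mm = image@breastThickness,
               tube_voltage_kV = image@tubeVoltage,
               bit_depth = image@bitDepth,
               value_min = rng[1], value_max = rng[2])
  if (is.na(image@bitDepth)) meta$bit_depth <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a 2D cluster as a PNG mask plus JSON component statistics
#'
#' @param cluster a \linkS4class{Cluster2D}.
#' @param path PNG output path (the JSON goes to \code{<path>.json}).
#' @return the path, invisibly.
#' @export
writeClusterMask <- function(cluster, path) {
  png::writePNG(cluster@mask * 1, path)
  lab <- labelComponents(cluster@mask, full = TRUE)
  sizes <- if (max(lab)) tabulate(lab[lab > 0L]) else integer(0)
  jsonlite::write_json(
    list(origin_row = cluster@origin[1], origin_col = cluster@origin[2],
         n_calcs = cluster@nCalcs, component_px = sizes),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
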