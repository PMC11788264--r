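# Internal helpers: labelling, binary morphology, bounding boxes.

#' Label connected components of a binary array
#'
#' 8-connectivity in 2D, 26-connectivity in 3D (the most permissive
#' neighbourhoods), unless \code{full = FALSE} (4/6-connectivity).
#'
#' @param x logical/0-1 matrix or 3D array.
#' @param full use the full (diagonal-including) neighbourhood.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1 in column-major discovery order.
#' @export
labelComponents <- function(x, full = TRUE) {
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(2L, 3L))
    stop("x must be a matrix or a 3D array")
  lab <- cpp_label_components(as.logical(x != 0), as.integer(d), isTRUE(full))
  dim(lab) <- d
  lab
}

countComponents2D <- function(mask) {
  if (!any(mask)) return(0L)
  max(labelComponents(mask))
}

# Shift an array by integer offsets, padding with FALSE.
shiftArray <- function(x, off) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) {
      dst[[k]] <- seq.int(1 + o, d[k])
      src[[k]] <- seq.int(1, d[k] - o)
    } else {
      dst[[k]] <- seq.int(1, d[k] + o)
      src[[k]] <- seq.int(1 - o, d[k])
    }
  }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(x), src)))))
}

# Offsets of a cross (city-block radius 1) structuring element, centre excluded.
crossOffsets <- function(nd) {
  offs <- list()
  for (k in seq_len(nd)) {
    o <- rep(0L, nd)
    o[k] <- 1L
    offs <- c(offs, list(o), list(-o))
  }
  offs
}

# Binary erosion/dilation with a cross structuring element (3x3(x3), 6/4-conn).
erodeBinary <- function(x) {
  out <- x
  for (o in crossOffsets(length(dim(x)))) out <- out & shiftArray(x, o)
  out
}

dilateBinary <- function(x) {
  out <- x
  for (o in crossOffsets(length(dim(x)))) out <- out | shiftArray(x, o)
  out
}

openBinary <- function(x) dilateBinary(erodeBinary(x))
closeBinary <- function(x) erodeBinary(dilateBinary(x))

# Bounding box of TRUE entries: 2 x nd matrix (min row, max row) or NULL.
boundingBox <- function(x) {
  d <- dim(x)
  if (!any(x)) return(NULL)
  nd <- length(d)
  bb <- matrix(0L, 2L, nd)
  for (k in seq_len(nd)) {
    marg <- apply(x, k, any)
    idx <- which(marg)
    bb[1, k] <- idx[1]
    bb[2, k] <- idx[length(idx)]
  }
  bb
}

# Crop a logical array to its occupied bounding box (plus optional pad).
cropToBoundingBox <- function(x, pad = 0L) {
  bb <- boundingBox(x)
  if (is.null(bb)) return(x)
  d <- dim(x)
  idx <- lapply(seq_along(d), function(k)
    seq.int(max(1L, bb[1, k] - pad), min(d[k], bb[2, k] + pad)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Pad a logical array with `pad` empty cells on every face.
padArray <- function(x, pad = 1L) {
  d <- dim(x)
  out <- array(FALSE, d + 2L * pad)
  idx <- lapply(d, function(n) seq.int(pad + 1L, pad + n))
  do.call(`[<-`, c(list(out), idx, list(x)))
}

# mm -> voxel count, round half up, at least 1.
mmToVoxels <- function(mm, voxelSize) {
  max(1L, as.integer(floor(mm / voxelSize + 0.5)))
}

# Draw one uniform value from a range (or the point value if degenerate).
sampleRange <- function(range, n = 1L) {
  range <- as.numeric(range)
  if (length(range) == 1L) range <- c(range, range)
  if (range[1] > range[2]) stop("range minimum exceeds maximum")
  if (range[1] == range[2]) rep(range[1], n) else stats::runif(n, range[1], range[2])
}

# Extract plain-matrix pixel data from an EBImage Image.
ebMatrix <- function(img) {
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2L) m <- m[, , 1]
  matrix(as.numeric(m), nrow(m), ncol(m))
}

checkSeed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("seed must be a single finite number or NULL")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
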