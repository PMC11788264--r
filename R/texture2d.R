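# Texture-driven 2D cluster generation: radiomics cell voting, candidate
# masks from intensity + Frangi filtering, circularity/size filtering, and
# contrast-seeded region growth.

#' Segment the breast from the surrounding air
#'
#' Automatic (Otsu) threshold on presentation-polarity pixels (air dark),
#' retention of the largest 8-connected region, holes filled.
#'
#' @param pixels numeric matrix in presentation polarity, or an
#'   \linkS4class{Image2D} (inverted internally when its intent is
#'   for_processing).
#' @param threshold optional manual threshold overriding Otsu.
#' @return logical breast mask.
#' @export
segmentBreast <- function(pixels, threshold = NULL) {
  if (is(pixels, "Image2D")) pixels <- workingPixels(pixels)
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("cannot segment a constant image")
  norm <- (pixels - rng[1]) / (rng[2] - rng[1])
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bin <- norm > threshold
  if (!any(bin)) stop("breast segmentation produced an empty mask")
  lab <- labelComponents(bin, full = TRUE)
  counts <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(counts)
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0
  matrix(as.logical(mask), nrow(pixels), ncol(pixels))
}

#' Tile the breast into non-overlapping grid cells
#'
#' Cells of \code{cellPx} x \code{cellPx} pixels anchored at the image
#' origin, fully inside the image, whose breast-mask coverage exceeds
#' \code{coverage}; returned in row-major order.
#'
#' @param mask logical breast mask.
#' @param cellPx cell edge length in pixels (>= 16; default 200).
#' @param coverage minimum mask fraction inside a qualifying cell.
#' @return data.frame with columns row, col (1-based origins), size_px,
#'   coverage.
#' @export
tileBreast <- function(mask, cellPx = 200L, coverage = 0.9) {
  cellPx <- as.integer(cellPx)
  if (cellPx < 16L) stop("cellPx must be >= 16")
  if (cellPx > nrow(mask) || cellPx > ncol(mask))
    stop("cell size exceeds the image")
  rows <- seq.int(1L, nrow(mask) - cellPx + 1L, by = cellPx)
  cols <- seq.int(1L, ncol(mask) - cellPx + 1L, by = cellPx)
  out <- list()
  for (r in rows) for (co in cols) {
    cov <- mean(mask[r:(r + cellPx - 1L), co:(co + cellPx - 1L)])
    if (cov > coverage)
      out[[length(out) + 1L]] <- data.frame(row = r, col = co,
                                            size_px = cellPx, coverage = cov)
  }
  if (!length(out)) stop("no grid cell meets the breast-coverage requirement")
  do.call(rbind, out)
}

## ---- radiomics cell features -------------------------------------------

glcmMatrix <- function(x, levels = 32L) {
  rng <- range(x)
  q <- if (rng[1] == rng[2]) matrix(1L, nrow(x), ncol(x)) else
    matrix(pmin(levels, 1L + floor((x - rng[1]) / (rng[2] - rng[1]) * levels)),
           nrow(x), ncol(x))
  P <- matrix(0, levels, levels)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  nr <- nrow(q); nc <- ncol(q)
  for (o in offs) {
    r1 <- max(1L, 1L - o[1]):min(nr, nr - o[1])
    c1 <- max(1L, 1L - o[2]):min(nc, nc - o[2])
    a <- q[r1, c1]
    b <- q[r1 + o[1], c1 + o[2]]
    idx <- cbind(as.vector(a), as.vector(b))
    for (k in seq_len(nrow(idx))) {
      P[idx[k, 1], idx[k, 2]] <- P[idx[k, 1], idx[k, 2]] + 1
      P[idx[k, 2], idx[k, 1]] <- P[idx[k, 2], idx[k, 1]] + 1
    }
  }
  P / sum(P)
}

glcmFeatures <- function(x, levels = 32L) {
  P <- glcmMatrix(x, levels)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  nz <- P > 0
  corr <- if (sd_i > 0 && sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j) else 0
  c(glcm_contrast = sum((i - j)^2 * P),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_energy = sum(P^2),
    glcm_entropy = -sum(P[nz] * log2(P[nz])),
    glcm_correlation = corr)
}

firstOrderFeatures <- function(x) {
  v <- as.vector(x)
  m <- mean(v); s <- stats::sd(v)
  h <- tabulate(cut(v, breaks = 64L, labels = FALSE), nbins = 64L)
  p <- h / sum(h); p <- p[p > 0]
  qs <- stats::quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  c(fo_mean = m, fo_median = stats::median(v), fo_variance = stats::var(v),
    fo_skewness = if (s > 0) mean((v - m)^3) / s^3 else 0,
    fo_kurtosis = if (s > 0) mean((v - m)^4) / s^4 else 0,
    fo_energy = sum(v^2), fo_rms = sqrt(mean(v^2)),
    fo_entropy = -sum(p * log2(p)), fo_uniformity = sum(p^2),
    fo_min = min(v), fo_max = max(v), fo_range = diff(range(v)),
    fo_mad = stats::mad(v), fo_p10 = qs[1], fo_p90 = qs[4],
    fo_iqr = qs[3] - qs[2])
}

#' Radiomics features of one grid cell
#'
#' 16 first-order statistics plus 6 gray-level co-occurrence features
#' (32 levels, 4 symmetric unit offsets) -- the default 22-feature set used
#' for cell voting.
#'
#' @param cellPixels numeric matrix.
#' @return named numeric vector of 22 features.
#' @export
radiomicsFeatures <- function(cellPixels) {
  c(firstOrderFeatures(cellPixels), glcmFeatures(cellPixels))
}

#' Default feature-voting configuration
#'
#' One row per feature with the sort direction used in cell voting:
#' \code{decreasing = TRUE} means high values indicate dense or structured
#' tissue (preferred cluster locations).  Fully user-editable.
#'
#' @return data.frame with columns \code{name}, \code{decreasing}.
#' @export
defaultFeatureConfig <- function() {
  up <- c("fo_mean", "fo_median", "fo_variance", "fo_skewness", "fo_kurtosis",
          "fo_energy", "fo_rms", "fo_entropy", "fo_min", "fo_max", "fo_range",
          "fo_mad", "fo_p10", "fo_p90", "fo_iqr",
          "glcm_contrast", "glcm_dissimilarity", "glcm_entropy")
  down <- c("fo_uniformity", "glcm_homogeneity", "glcm_energy",
            "glcm_correlation")
  data.frame(name = c(up, down),
             decreasing = c(rep(TRUE, length(up)), rep(FALSE, length(down))),
             stringsAsFactors = FALSE)
}

#' Select the optimal grid cell by per-feature voting
#'
#' For every configured feature the cells are ranked (direction per
#' feature) and the top \code{topK} are collected; the cell appearing most
#' often across those per-feature lists wins.  Ties break by lowest mean
#' rank across all features, then by row-major cell order.
#'
#' @param pixels working (presentation-polarity) pixel matrix.
#' @param cells data.frame from \code{\link{tileBreast}}.
#' @param featureConfig data.frame(name, decreasing); defaults to the
#'   22-feature set of \code{\link{defaultFeatureConfig}}.
#' @param topK per-feature list length (default 10, shortened when fewer
#'   cells exist).
#' @return the winning cell as a one-row data.frame with a \code{votes}
#'   column; the full per-cell feature matrix is attached as attribute
#'   \code{"features"}.
#' @export
selectCell <- function(pixels, cells, featureConfig = defaultFeatureConfig(),
                       topK = 10L) {
  ncells <- nrow(cells)
  if (is.null(ncells) || ncells < 1L) stop("no cells to select from")
  feats <- t(vapply(seq_len(ncells), function(i) {
    r <- cells$row[i]; co <- cells$col[i]; s <- cells$size_px[i]
    radiomicsFeatures(pixels[r:(r + s - 1L), co:(co + s - 1L)])
  }, numeric(22L)))
  keep <- intersect(featureConfig$name, colnames(feats))
  votes <- integer(ncells)
  rankSum <- numeric(ncells)
  k <- min(topK, ncells)
  for (fn in keep) {
    dec <- featureConfig$decreasing[featureConfig$name == fn][1]
    v <- feats[, fn]
    rk <- rank(if (dec) -v else v, ties.method = "first")
    votes[rk <= k] <- votes[rk <= k] + 1L
    rankSum <- rankSum + rk
  }
  best <- which(votes == max(votes))
  if (length(best) > 1L) {
    mr <- rankSum[best]
    best <- best[mr == min(mr)]
    best <- best[1L]  # row-major order of `cells`
  }
  out <- cells[best, , drop = FALSE]
  out$votes <- votes[best]
  attr(out, "features") <- feats
  out
}

## ---- Frangi vesselness --------------------------------------------------

gaussKernels <- function(sigma) {
  r <- max(2L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  list(g = g, g1 = g1, g2 = g2)
}

conv2sep <- function(x, kr, kc) {
  f <- outer(kr, kc)
  ebMatrix(EBImage::filter2(EBImage::Image(x), f, boundary = "replicate"))
}

#' Frangi vesselness filter (2D, bright structures)
#'
#' Hessian-eigenvalue vesselness enhancing bright ridge-like and structured
#' regions, computed over several Gaussian scales (scale-normalized second
#' derivatives) and combined by the pixelwise maximum.
#'
#' @param pixels numeric matrix (presentation polarity: structures bright).
#' @param scales Gaussian scales (sigma, px); default \code{c(1, 2, 3)}.
#' @param beta blob/ridge discrimination parameter (default 0.5).
#' @param c2 structure-strength parameter; default half the maximum Hessian
#'   norm per scale.
#' @return non-negative response matrix.
#' @export
frangiFilter <- function(pixels, scales = c(1, 2, 3), beta = 0.5, c2 = NULL) {
  best <- matrix(0, nrow(pixels), ncol(pixels))
  for (s in scales) {
    k <- gaussKernels(s)
    Lxx <- s^2 * conv2sep(pixels, k$g2, k$g)
    Lyy <- s^2 * conv2sep(pixels, k$g, k$g2)
    Lxy <- s^2 * conv2sep(pixels, k$g1, k$g1)
    tr <- Lxx + Lyy
    disc <- sqrt(pmax(0, (Lxx - Lyy)^2 + 4 * Lxy^2))
    e1 <- (tr + disc) / 2
    e2 <- (tr - disc) / 2
    # order by magnitude: |l1| <= |l2|
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    cc <- if (is.null(c2)) sqrt(max(S2)) / 2 else c2
    if (cc <= 0) next
    Rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cc^2)))
    v[l2 > 0] <- 0  # bright structures have negative principal curvature
    best <- pmax(best, v)
  }
  best
}

#' Candidate-calcification mask of a grid cell
#'
#' Intersection of the above-median intensity mask with a thresholded
#' Frangi vesselness mask; every 8-connected component of the result is one
#' candidate calcification.
#'
#' @param cellPixels numeric matrix (presentation polarity).
#' @param frangiThreshold threshold on the Frangi response; default is the
#'   mean positive response.
#' @param scales,beta passed to \code{\link{frangiFilter}}.
#' @return logical candidate mask (possibly empty).
#' @export
buildCandidateMask <- function(cellPixels, frangiThreshold = NULL,
                               scales = c(1, 2, 3), beta = 0.5) {
  med <- stats::median(cellPixels)
  intens <- cellPixels > med
  fr <- frangiFilter(cellPixels, scales = scales, beta = beta)
  if (is.null(frangiThreshold)) {
    pos <- fr[fr > 0]
    frangiThreshold <- if (length(pos)) mean(pos) else Inf
  }
  intens & (fr > frangiThreshold)
}

#' Filter candidate calcifications by size and circularity
#'
#' For each 8-connected component the area A is its pixel count and the
#' radii (x, y) its bounding-box half-extents; circularity is
#' 4*pi*A / P^2 with perimeter P = 2*pi*max(x, y).  Components whose
#' physical extent (largest bounding-box side in mm) and circularity fall
#' inside the requested ranges are kept.
#'
#' @param mask logical candidate mask.
#' @param sizeRangeMm c(min, max) extent range, within 0.01-2.00 mm.
#' @param circRange c(min, max) circularity range, within 0.01-2.0.
#' @param pixelSpacingMm pixel pitch in mm.
#' @return list with \code{table} (one row per kept candidate: id, area_px,
#'   radius_x_px, radius_y_px, circularity, extent_mm, bounding box) and
#'   \code{labels} (integer matrix, kept candidates renumbered from 1).
#' @export
filterCandidates <- function(mask, sizeRangeMm, circRange, pixelSpacingMm) {
  if (any(sizeRangeMm < 0.01 - 1e-12 | sizeRangeMm > 2.00 + 1e-12))
    stop("size range must lie within 0.01-2.00 mm")
  if (any(circRange < 0.01 - 1e-12 | circRange > 2.0 + 1e-12))
    stop("circularity range must lie within 0.01-2.0")
  lab <- labelComponents(mask, full = TRUE)
  k <- max(lab)
  keptLabels <- matrix(0L, nrow(mask), ncol(mask))
  rows <- list()
  kept <- 0L
  for (i in seq_len(k)) {
    comp <- lab == i
    A <- sum(comp)
    bb <- boundingBox(comp)
    w <- bb[2, 1] - bb[1, 1] + 1L  # rows
    h <- bb[2, 2] - bb[1, 2] + 1L  # cols
    rx <- w / 2; ry <- h / 2
    P <- 2 * pi * max(rx, ry)
    circ <- 4 * pi * A / P^2
    ext <- max(w, h) * pixelSpacingMm
    if (ext >= sizeRangeMm[1] && ext <= sizeRangeMm[2] &&
        circ >= circRange[1] && circ <= circRange[2]) {
      kept <- kept + 1L
      keptLabels[comp] <- kept
      rows[[kept]] <- data.frame(id = kept, area_px = A, radius_x_px = rx,
                                 radius_y_px = ry, circularity = circ,
                                 extent_mm = ext, row_min = bb[1, 1],
                                 row_max = bb[2, 1], col_min = bb[1, 2],
                                 col_max = bb[2, 2])
    }
  }
  list(table = if (kept) do.call(rbind, rows) else
         data.frame(id = integer(0), area_px = integer(0),
                    radius_x_px = numeric(0), radius_y_px = numeric(0),
                    circularity = numeric(0), extent_mm = numeric(0),
                    row_min = integer(0), row_max = integer(0),
                    col_min = integer(0), col_max = integer(0)),
       labels = keptLabels)
}

#' Sub-cell contrast map of a grid cell
#'
#' Within an overlapping grid of \code{subcellPx} x \code{subcellPx}
#' sub-cells (stride \code{stridePx}, default half the sub-cell), computes
#' the double sum over 1-based pixel positions (i, j) inside the sub-cell
#' of (i - j)^2 * PV(i, j), evaluated verbatim.  For a uniform unit
#' sub-cell of side n the value is n^2 (n^2 - 1) / 6.
#'
#' @param cellPixels numeric matrix.
#' @param subcellPx sub-cell edge length (default 10).
#' @param stridePx overlap stride (default \code{subcellPx / 2}).
#' @return numeric matrix of contrast values with attributes \code{rows},
#'   \code{cols} (1-based sub-cell origins) and \code{subcellPx}.
#' @export
contrastMap <- function(cellPixels, subcellPx = 10L,
                        stridePx = max(1L, subcellPx %/% 2L)) {
  subcellPx <- as.integer(subcellPx)
  if (nrow(cellPixels) < subcellPx || ncol(cellPixels) < subcellPx)
    stop("cell is smaller than the sub-cell")
  K <- outer(seq_len(subcellPx), seq_len(subcellPx),
             function(i, j) (i - j)^2)
  r0 <- seq.int(1L, nrow(cellPixels) - subcellPx + 1L, by = stridePx)
  c0 <- seq.int(1L, ncol(cellPixels) - subcellPx + 1L, by = stridePx)
  out <- matrix(0, length(r0), length(c0))
  for (a in seq_along(r0)) for (b in seq_along(c0)) {
    pv <- cellPixels[r0[a]:(r0[a] + subcellPx - 1L),
                     c0[b]:(c0[b] + subcellPx - 1L)]
    out[a, b] <- sum(K * pv)
  }
  attr(out, "rows") <- r0
  attr(out, "cols") <- c0
  attr(out, "subcellPx") <- subcellPx
  out
}

#' Grow a cluster from candidate calcifications
#'
#' Seeds at the highest-contrast sub-cell that intersects at least one
#' (part of a) candidate, includes every candidate touching that region,
#' and then iteratively enlarges the search region around the included
#' calcifications (step: one sub-cell width by default), adding newly
#' touched candidates nearest-first, until \code{nTarget} is reached or the
#' candidates are exhausted.
#'
#' @param candidates result of \code{\link{filterCandidates}}.
#' @param cmap contrast map from \code{\link{contrastMap}} of the same cell.
#' @param nTarget requested number of calcifications (>= 1).
#' @param cellOrigin 1-based (row, col) of the cell in the source image.
#' @param stepPx region-growth step in pixels (default: sub-cell width).
#' @return a \linkS4class{Cluster2D} whose component count equals
#'   \code{min(nTarget, available candidates)}.
#' @export
growCluster <- function(candidates, cmap, nTarget, cellOrigin = c(1L, 1L),
                        stepPx = NULL) {
  if (nTarget < 1L) stop("nTarget must be >= 1")
  labels <- candidates$labels
  k <- max(labels)
  if (k == 0L) stop("no candidate calcifications to grow a cluster from")
  sub <- attr(cmap, "subcellPx")
  if (is.null(stepPx)) stepPx <- sub
  rows <- attr(cmap, "rows"); cols <- attr(cmap, "cols")

  # highest-contrast sub-cell containing at least part of a candidate
  ord <- order(-as.vector(cmap))  # ties: column-major position
  seed <- NULL
  for (idx in ord) {
    a <- (idx - 1L) %% nrow(cmap) + 1L
    b <- (idx - 1L) %/% nrow(cmap) + 1L
    rr <- rows[a]:(rows[a] + sub - 1L)
    cc <- cols[b]:(cols[b] + sub - 1L)
    if (any(labels[rr, cc] > 0L)) { seed <- list(rr = rr, cc = cc); break }
  }
  region <- matrix(FALSE, nrow(labels), ncol(labels))
  region[seed$rr, seed$cc] <- TRUE

  compCentroids <- t(vapply(seq_len(k), function(i) {
    w <- which(labels == i, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  seedCenter <- c(mean(seed$rr), mean(seed$cc))

  included <- logical(k)
  addNearestFirst <- function(cands, ref) {
    # add candidate components nearest to `ref` first, capped at nTarget
    if (!length(cands)) return(invisible(NULL))
    d <- sqrt(colSums((t(compCentroids[cands, , drop = FALSE]) - ref)^2))
    for (i in cands[order(d, cands)]) {
      if (sum(included) >= nTarget) break
      included[i] <<- TRUE
    }
    invisible(NULL)
  }
  touching <- function(reg) {
    hit <- unique(labels[reg & labels > 0L])
    setdiff(hit, which(included))
  }
  addNearestFirst(touching(region), seedCenter)

  while (sum(included) < nTarget && any(!included)) {
    base <- region | (labels > 0L &
                      matrix(labels %in% which(included), nrow(labels)))
    d <- ebMatrix(EBImage::distmap(EBImage::Image(1 - base)))
    remaining <- which(!included)
    minDist <- vapply(remaining, function(i) min(d[labels == i]), numeric(1))
    reach <- stepPx
    hit <- remaining[minDist <= reach]
    while (!length(hit) && reach < sum(dim(labels))) {
      reach <- reach + stepPx
      hit <- remaining[minDist <= reach]
    }
    if (!length(hit)) break
    center <- c(mean(which(base, arr.ind = TRUE)[, 1]),
                mean(which(base, arr.ind = TRUE)[, 2]))
    # nearest by distance to the current region
    for (i in hit[order(minDist[match(hit, remaining)], hit)]) {
      if (sum(included) >= nTarget) break
      included[i] <- TRUE
    }
    region <- d <= reach
  }

  mask <- matrix(labels %in% which(included) & labels > 0L, nrow(labels))
  Cluster2D(mask, origin = as.integer(cellOrigin))
}

workingPixels <- function(image) {
  px <- image@pixels
  if (image@intent == "for_processing") {
    rng <- range(px)
    px <- rng[1] + rng[2] - px  # invert so calcifications/structures are bright
  }
  px
}

#' Generate a texture-tailored 2D microcalcification cluster
#'
#' Full pipeline for one mammogram: polarity normalization (for_processing
#' images are inverted up front), breast segmentation, grid tiling,
#' radiomics cell voting (or a manual cell), candidate mask construction,
#' size/circularity filtering, sub-cell contrast mapping and region
#' growth.  The pipeline is deterministic for a fixed image and
#' configuration.
#'
#' @param image an \linkS4class{Image2D}.
#' @param nTarget requested number of calcifications.
#' @param sizeRangeMm candidate extent range (mm), within 0.01-2.00.
#' @param circRange candidate circularity range, within 0.01-2.0.
#' @param cellPx grid cell size in pixels.
#' @param coverage minimum breast coverage per cell.
#' @param featureConfig feature voting configuration.
#' @param manualCell optional c(row, col) cell origin bypassing the voting.
#' @param subcellPx,stridePx contrast sub-cell size and stride.
#' @param frangiScales,frangiBeta Frangi filter parameters.
#' @return a \linkS4class{Cluster2D} anchored in image coordinates.
#' @export
generateCluster2D <- function(image, nTarget, sizeRangeMm = c(0.05, 2.00),
                              circRange = c(0.01, 2.0), cellPx = 200L,
                              coverage = 0.9,
                              featureConfig = defaultFeatureConfig(),
                              manualCell = NULL, subcellPx = 10L,
                              stridePx = max(1L, subcellPx %/% 2L),
                              frangiScales = c(1, 2, 3), frangiBeta = 0.5) {
  stopifnot(is(image, "Image2D"))
  px <- workingPixels(image)
  if (is.null(manualCell)) {
    mask <- segmentBreast(px)
    cells <- tileBreast(mask, cellPx = cellPx, coverage = coverage)
    cell <- selectCell(px, cells, featureConfig = featureConfig)
  } else {
    cell <- data.frame(row = manualCell[1], col = manualCell[2],
                       size_px = cellPx)
  }
  r <- cell$row[1]; co <- cell$col[1]; s <- cell$size_px[1]
  cellPixels <- px[r:(r + s - 1L), co:(co + s - 1L)]
  cmask <- buildCandidateMask(cellPixels, scales = frangiScales,
                              beta = frangiBeta)
  cands <- filterCandidates(cmask, sizeRangeMm, circRange,
                            image@pixelSpacing)
  if (max(cands$labels) == 0L)
    stop("no candidate calcification passed the size/circularity filter")
  cmap <- contrastMap(cellPixels, subcellPx = subcellPx, stridePx = stridePx)
  growCluster(cands, cmap, nTarget, cellOrigin = c(r, co))
}
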