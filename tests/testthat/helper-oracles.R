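# Independent brute-force oracles used across the suite.  These deliberately
# re-derive expected values by enumeration or closed form, never by calling
# the implementation under test.

# Center-in-sphere voxelization oracle: counts voxel centres inside a sphere
# of diameter d centred in an n^3 grid of the given voxel size.
oracleSphereCount <- function(diameterMm, voxelSizeMm, gridN) {
  ctr <- gridN / 2
  cc <- ((seq_len(gridN) - 0.5) - ctr) * voxelSizeMm
  r <- diameterMm / 2
  sum(outer(outer(cc^2, cc^2, `+`), cc^2, `+`) <= r^2)
}

# Brute-force binary erosion/dilation with the 6-connected cross, by
# explicit per-voxel neighbourhood loops.
oracleErode <- function(g) {
  d <- dim(g)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!g[i, j, k]) next
    ok <- TRUE
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      p <- c(i, j, k) + o
      if (any(p < 1) || any(p > d) || !g[p[1], p[2], p[3]]) { ok <- FALSE; break }
    }
    out[i, j, k] <- ok
  }
  out
}

oracleDilate <- function(g) {
  d <- dim(g)
  out <- g
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (g[i, j, k]) next
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      p <- c(i, j, k) + o
      if (all(p >= 1) && all(p <= d) && g[p[1], p[2], p[3]]) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

# Exact array permutation for a +90 degree rotation about z.
oracleRot90z <- function(g) {
  aperm(g[, dim(g)[2]:1, , drop = FALSE], c(2, 1, 3))
}

# Sphericity evaluated independently (no shared code with the package).
oracleSphericity <- function(semi, volume) {
  p <- 1.6
  A <- 4 * pi * (((semi[1] * semi[2])^p + (semi[2] * semi[3])^p +
                    (semi[3] * semi[1])^p) / 3)^(1 / p)
  pi^(1 / 3) * (6 * volume)^(2 / 3) / A
}

# Per-ray projection oracle: voxel counts along the z axis via apply().
oracleProjectZ <- function(g) {
  apply(g, c(1, 2), sum)
}

# A flat-breast image fixture (half-disc of constant value on zero air).
flatBreastImage <- function(n = 240L, value = 500, spacing = 0.1,
                            radiusFrac = 0.95) {
  rowc <- matrix(seq_len(n), n, n)
  colc <- matrix(seq_len(n), n, n, byrow = TRUE)
  mask <- (colc - 1)^2 + (rowc - n / 2)^2 <= (radiusFrac * n)^2
  px <- matrix(0, n, n)
  px[mask] <- value
  list(pixels = px, mask = mask)
}
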