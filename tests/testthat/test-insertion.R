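# Insertion engine: ray-tracing, degradation, contrast calibration,
# intensity scaling, multiplicative insertion.

test_that("ray-tracing matches exp(-mu*T) on slabs and is ray-additive", {
  for (mu in c(0.2, 0.7, 1.3)) for (tmm in c(0.5, 1.0, 2.0)) {
    nz <- round(tmm / 0.05)
    slab <- VoxelModel3D(array(TRUE, c(4, 4, nz)), 0.05)
    tv <- templateValues(rayTrace(slab, mu))
    expect_lt(max(abs(tv - exp(-mu * tmm))), 1e-6)
  }
  # mu -> 0 limit: template approaches all-ones
  slab <- VoxelModel3D(array(TRUE, c(4, 4, 10)), 0.05)
  expect_lt(max(abs(templateValues(rayTrace(slab, 1e-9)) - 1)), 1e-6)

  # arbitrary model: per-ray voxel-count oracle via apply()
  set.seed(3)
  g <- array(stats::runif(12^3) > 0.6, c(12, 12, 12))
  m <- VoxelModel3D(g, 0.1)
  counts <- oracleProjectZ(g)
  expect_equal(templateValues(rayTrace(m, 0.8)),
               exp(-0.8 * counts * 0.1), tolerance = 1e-12)

  expect_error(rayTrace(VoxelModel3D(array(FALSE, c(3, 3, 3)), 0.1), 0.5),
               "empty")
  expect_error(rayTrace(m, -1), "muPerMm")
})

test_that("degradation: identity at zero, scatter formula, contrast monotonicity", {
  tv <- matrix(1, 15, 15); tv[6:10, 6:10] <- 0.5
  tpl <- Template2D(tv, 0.1)
  expect_identical(templateValues(degradeTemplate(tpl, 0, 0)), tv)

  sc <- degradeTemplate(tpl, 0, 0.5)  # s = 1: TV' = (TV + 1)/2
  expect_equal(templateValues(sc)[8, 8], 0.75)
  expect_equal(templateValues(sc)[1, 1], 1)

  bl <- degradeTemplate(tpl, blurSigmaMm = 0.1, scatterFraction = 0.3)
  expect_gte(min(templateValues(bl)), min(tv))
  expect_equal(templateValues(bl)[1, 1], 1)  # background exactly 1.0

  expect_error(degradeTemplate(tpl, -1, 0), "blurSigmaMm")
  expect_error(degradeTemplate(tpl, 0, 1), "scatterFraction")
})

test_that("Weber contrast follows its definition and sign convention", {
  expect_equal(weberContrast(200, 100), 1.0)
  expect_equal(weberContrast(100, 100), 0.0)
  expect_equal(weberContrast(50, 100), -0.5)
  expect_error(weberContrast(50, 0), "non-zero")
})

test_that("contrast calibration recovers exact and noisy linear relationships", {
  x <- c(-0.05, -0.1, -0.2, -0.35)
  cal <- fitContrastCalibration(x, -3.0 * x + 0.02, systemId = "synthA")
  expect_equal(cal@wContrast, -3.0, tolerance = 1e-12)
  expect_equal(cal@kContrast, 0.02, tolerance = 1e-12)

  set.seed(10)
  xn <- stats::runif(1000, -0.5, -0.01)
  yn <- -2.4 * xn + 0.05 + stats::rnorm(1000, sd = 0.02)
  caln <- fitContrastCalibration(xn, yn)
  se <- summary(stats::lm(yn ~ xn))$coefficients["xn", "Std. Error"]
  expect_lt(abs(caln@wContrast - (-2.4)), 3 * se)

  expect_error(fitContrastCalibration(-0.1, -0.3), "two")
  expect_error(fitContrastCalibration(c(-0.1, -0.1), c(0.2, 0.3)),
               "degenerate")
})

test_that("presentation correction maps calcification TVs above 1 and spares background", {
  cal <- ContrastCalibration(wContrast = -3, kContrast = 0.02)
  flat <- Template2D(matrix(1, 5, 5), 0.1)
  expect_identical(templateValues(toPresentation(flat, cal)),
                   matrix(1, 5, 5))

  tpl <- Template2D(matrix(c(1, 0.9, 0.8, 0.7), 2, 2), 0.1)
  pres <- toPresentation(tpl, cal)
  expect_equal(templateValues(pres)[2, 1], 1.32)  # 1 + (0.3 + 0.02)
  expect_equal(templatePolarity(pres), "for_presentation")
  v <- templateValues(pres)[templateValues(tpl) < 1]
  expect_true(all(v > 1))
  # monotone: deeper processing attenuation -> brighter presentation
  expect_true(all(diff(v) > 0))
  expect_error(toPresentation(pres, cal), "already")
})

test_that("scaling-weight regression recovers known coefficients", {
  set.seed(4)
  d <- stats::runif(500, 0, 10)
  th <- sample(c(30, 50, 70), 500, replace = TRUE)
  vo <- sample(c(26, 28, 31), 500, replace = TRUE)
  tv <- -0.05 * d + 0.002 * th - 0.004 * vo + 0.9
  w <- fitScalingWeights(d, tv, th, vo)
  expect_equal(w@wDist, -0.05, tolerance = 1e-10)
  expect_equal(w@wThick, 0.002, tolerance = 1e-10)
  expect_equal(w@wVolt, -0.004, tolerance = 1e-10)
  expect_equal(w@kIntensity, 0.9, tolerance = 1e-10)

  tvn <- tv + stats::rnorm(500, sd = 0.01)
  wn <- fitScalingWeights(d, tvn, th, vo)
  ses <- summary(stats::lm(tvn ~ d + th + vo))$coefficients[, "Std. Error"]
  expect_lt(abs(wn@wDist - (-0.05)), 3 * ses["d"])
  expect_lt(abs(wn@wThick - 0.002), 3 * ses["th"])

  # single thickness and voltage: rank-deficient
  expect_error(fitScalingWeights(d, tv, rep(50, 500), rep(28, 500)),
               "rank-deficient")
})

test_that("2D intensity scaling applies the fitted map over the distance transform", {
  w <- ScalingWeights(wDist = -0.06, wThick = 0.001, wVolt = -0.002,
                      kIntensity = 0.95)
  onepx <- matrix(FALSE, 7, 7); onepx[4, 4] <- TRUE
  tpl <- scale2DTemplate(Cluster2D(onepx), w, 50, 28, 0.05, smoothSigmaPx = 0)
  expect_equal(templateValues(tpl)[4, 4],
               -0.06 * 1 + 0.001 * 50 + -0.002 * 28 + 0.95)
  expect_true(all(templateValues(tpl)[!onepx] == 1))

  disk <- matrix(FALSE, 21, 21)
  disk[(row(disk) - 11)^2 + (col(disk) - 11)^2 <= 5^2] <- TRUE
  tpd <- scale2DTemplate(Cluster2D(disk), w, 50, 28, 0.05)
  tvd <- templateValues(tpd)
  expect_equal(which.min(tvd), which(row(tvd) == 11 & col(tvd) == 11))
  expect_true(all(tvd[!disk] == 1))  # background protected through smoothing

  expect_error(scale2DTemplate(Cluster2D(matrix(FALSE, 4, 4)), w, 50, 28,
                               0.05), "empty")
})

test_that("the scaling fit reproduces ray-traced sphere centres adequately", {
  ts <- sphereTrainingSet(voxelSizeMm = 0.05, muPerMm = 1.0,
                          thicknessMm = c(40, 60), voltageKV = c(26, 30),
                          tvModifier = function(tv, t, v)
                            tv + 5e-4 * (t - 50) - 1e-3 * (v - 28))
  w <- fitScalingWeights(ts$dist, ts$tv, ts$thickness, ts$voltage)
  # adequacy of the surrogate: a linear map in the distance value can only
  # approximate the exponential ray-trace, so the documented bounds are
  # loose by design: strong correlation, bounded worst-case residual, and
  # preservation of the diameter ordering of the centre TVs
  pred <- w@wDist * ts$dist + w@wThick * ts$thickness +
    w@wVolt * ts$voltage + w@kIntensity
  resid <- ts$tv - pred
  expect_gt(stats::cor(pred, ts$tv), 0.8)
  expect_lt(max(abs(resid)), 0.2)
  one <- ts[ts$thickness == 40 & ts$voltage == 26, ]
  centers <- vapply(split(one, one$diameter), function(s)
    w@wDist * max(s$dist) + w@wThick * 40 + w@wVolt * 26 + w@kIntensity,
    numeric(1))
  expect_true(all(diff(centers[order(as.numeric(names(centers)))]) < 0))
})

test_that("larger spheres attenuate more: minimum TV decreases with diameter", {
  mins <- vapply(seq(0.1, 1.0, by = 0.1), function(d)
    min(templateValues(rayTrace(makeSphereVolume(d, 0.01), 0.5))), numeric(1))
  expect_true(all(diff(mins) < 0))
})

test_that("insertion multiplies inside the footprint and is bit-exact outside", {
  img <- Image2D(matrix(1000, 40, 40), 0.1, intent = "for_processing")
  ones <- Template2D(matrix(1, 10, 10), 0.1)
  expect_identical(imagePixels(insertTemplate(img, ones, c(5, 5))),
                   imagePixels(img))

  half <- Template2D(matrix(0.5, 10, 10), 0.1)
  out <- insertTemplate(img, half, c(11, 11))
  expect_true(all(imagePixels(out)[11:20, 11:20] == 500))
  expect_true(all(imagePixels(out)[-(11:20), ] == 1000))

  # closing the loop with the Weber definition
  tv <- matrix(1, 21, 21)
  cc <- (row(tv) - 11)^2 + (col(tv) - 11)^2 <= 36
  tv[cc] <- 0.8
  out2 <- insertTemplate(img, Template2D(tv, 0.1), c(10, 10))
  po <- imagePixels(out2)
  fp <- po[10:30, 10:30]
  expect_equal(weberContrast(mean(fp[cc]), mean(po[po == 1000])), 0.8 - 1,
               tolerance = 1e-12)

  expect_error(insertTemplate(img, half, c(35, 35)), "beyond")
  pres <- Image2D(matrix(1000, 40, 40), 0.1, intent = "for_presentation")
  expect_error(insertTemplate(pres, half, c(5, 5)), "polarity")

  # integer images: rounded half up and clipped to bit depth
  imgInt <- Image2D(matrix(101, 20, 20), 0.1, intent = "for_processing",
                    bitDepth = 8L)
  tvq <- Template2D(matrix(0.305, 4, 4), 0.1)
  o <- insertTemplate(imgInt, tvq, c(1, 1))
  expect_equal(imagePixels(o)[1, 1], 31)  # floor(30.805 + 0.5)
  tvBig <- Template2D(matrix(3, 4, 4), 0.1)
  expect_equal(imagePixels(insertTemplate(imgInt, tvBig, c(1, 1)))[1, 1], 255)
})
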