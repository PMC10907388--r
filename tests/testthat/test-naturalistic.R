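# Receptive-field masks and mapping, movie feature traces, optical flow,
# and the five feature sensitivities.

test_that("the Gaussian center mask is truncated, max-normalized and unbiased", {
  w <- gaussianCenterMask(50, 2, c(51, 51))
  expect_equal(max(w), 1)
  expect_equal(w[26, 26], 1)  # center pixel
  g <- BipolarCoding:::pixelGrid(51, 51, 2)
  outside <- g$x^2 + g$y^2 > 50^2
  expect_true(all(w[outside] == 0))
  # weighted average of a uniform frame recovers the value
  expect_equal(sum(w * 0.37) / sum(w), 0.37)
  expect_error(gaussianCenterMask(1, 2, c(11, 11)), "below one pixel")
})

test_that("feature traces respond with GCaMP kinetics and honor the shift", {
  mv <- generateNaturalisticSurrogate(4, NULL, frameRate = 20, pixelSize = 4,
                                      fieldPx = c(40, 40), seed = 1)
  # constant movie: constant trace, unchanged by the area-normalized kernel
  mvC <- mv
  mvC@frames[] <- 0.25
  trC <- movieFeatureTrace(mvC, c(0, 0), "luminance_center", applyG = TRUE)
  expect_equal(trC, rep(0.25, length(trC)), tolerance = 1e-9)

  # luminance step rises with the kernel's time to peak
  mvS <- mv
  mvS@frames[] <- 0
  mvS@frames[, , 41:80] <- 0.5
  trS <- movieFeatureTrace(mvS, c(0, 0), "luminance_center", applyG = TRUE,
                           shiftMs = 0)
  d <- diff(trS[41:80])
  tPeakKernel <- 0.0495 * log(1 + 0.156 / 0.0495)
  expect_lt(abs(which.max(d) / 20 - tPeakKernel), 0.2)

  # shift contract: 200 ms at 20 fps = 4 samples
  tr0 <- movieFeatureTrace(mv, c(0, 0), "luminance_center", shiftMs = 0)
  tr200 <- movieFeatureTrace(mv, c(0, 0), "luminance_center", shiftMs = 200)
  expect_equal(tr200[5:80], tr0[1:76])

  expect_error(movieFeatureTrace(mv, c(500, 0)), "outside")
})

test_that("temporal kernels match quadrature of their Gaussian sums", {
  rate <- 60
  fb <- BipolarCoding:::bandPassKernel(rate)
  oracle <- integrate(function(t) dnorm(t, 0.08, 0.05) - 0.5 * dnorm(t, 0.12, 0.12),
                      0, 1)$value
  expect_equal(sum(fb), oracle, tolerance = 0.02)
  fl <- BipolarCoding:::lowPassKernel(rate)
  oracleL <- integrate(function(t) dnorm(t, 0.24, 0.10) - 0.001 * dnorm(t, 0.30, 0.24),
                       0, 1)$value
  expect_equal(sum(fl), oracleL, tolerance = 0.02)
})

test_that("contrast sensitivities recover the generative feature of a response", {
  seg <- data.frame(t0 = c(0.5, 6, 12), t1 = c(5, 11, 18),
                    vx = c(60, -40, 20), vy = c(0, 30, -50))
  mv <- generateNaturalisticSurrogate(20, seg, frameRate = 20, pixelSize = 4,
                                      fieldPx = c(160, 160), seed = 3)
  align <- function(kind) BipolarCoding:::alignToResponse(
    movieFeatureTrace(mv, c(0, 0), kind), 20, numeric(190))
  gc <- align("luminance_center")
  gcs <- align("center_minus_surround")
  set.seed(61)
  Rcs <- gcs + rnorm(190, 0, 0.1 * sd(gcs))
  expect_gt(spatialContrastSensitivity(mv, c(0, 0), Rcs), 0)
  Rlum <- gc + rnorm(190, 0, 0.1 * sd(gc))
  expect_lt(spatialContrastSensitivity(mv, c(0, 0), Rlum), 0)

  # exact center-minus-surround response: numerator correlation is 1
  S <- spatialContrastSensitivity(mv, c(0, 0), gcs)
  expect_equal(S, log(1 / cor(gc, gcs)^2), tolerance = 1e-6)

  # affine invariance in R
  expect_equal(spatialContrastSensitivity(mv, c(0, 0), 3 * Rcs + 2),
               spatialContrastSensitivity(mv, c(0, 0), Rcs))

  # temporal sensitivity: band-passed response gives T > 0
  sc <- movieFeatureTrace(mv, c(0, 0), "luminance_center", applyG = FALSE,
                          shiftMs = 0)
  fbTr <- BipolarCoding:::convolveCausal(sc, BipolarCoding:::bandPassKernel(20))
  g <- BipolarCoding:::gKernel(20)
  Rb <- BipolarCoding:::alignToResponse(
    BipolarCoding:::shiftTrace(BipolarCoding:::convolveSame(fbTr, g), 4),
    20, numeric(190))
  expect_gt(temporalContrastSensitivity(mv, c(0, 0), Rb), 0)

  # white-noise responses center T near zero
  Ts <- vapply(1:8, function(s) {
    set.seed(s)
    temporalContrastSensitivity(mv, c(0, 0), rnorm(190))
  }, numeric(1))
  expect_lt(abs(mean(Ts)), 0.5)
})

test_that("Horn-Schunck flow recovers translation and smooths with alpha", {
  mvT <- generateNaturalisticSurrogate(1, NULL, frameRate = 10, pixelSize = 1,
                                       fieldPx = c(60, 60), seed = 4)
  f1 <- frames(mvT)[, , 1]
  expect_equal(hornSchunckFlow(f1, f1)$u, matrix(0, 60, 60))

  f2 <- cbind(f1[, 1], f1[, 1:59])
  fl <- hornSchunckFlow(f1, f2, alpha = 3, nIter = 100)
  inner <- 5:55
  expect_equal(mean(fl$u[inner, inner]), 1, tolerance = 0.15)
  expect_equal(mean(fl$v[inner, inner]), 0, tolerance = 0.15)

  lap <- function(m) sum(diff(m)^2) + sum(diff(t(m))^2)
  e <- vapply(c(1, 3, 10), function(a) {
    fa <- hornSchunckFlow(f1, f2, alpha = a, nIter = 50)
    lap(fa$u) + lap(fa$v)
  }, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("coherent-motion statistic vanishes for rigid flow and drives M", {
  seg <- data.frame(t0 = 0.2, t1 = 1.8, vx = 10, vy = 0)
  mv <- generateNaturalisticSurrogate(2, seg, frameRate = 10, pixelSize = 2,
                                      fieldPx = c(40, 40), seed = 5)
  tr <- BipolarCoding:::coherentMotionTrace(mv, c(0, 0), maskDiameterUm = 60,
                                            nIter = 50)
  # rigid sub-pixel translation: mean |v| barely exceeds |mean v|
  expect_lt(max(abs(tr)), 0.15)

  # M = 0 when R is exactly g(O_a - O_v)
  g <- BipolarCoding:::gKernel(10)
  feat <- BipolarCoding:::shiftTrace(BipolarCoding:::convolveSame(tr, g), 2)
  R <- BipolarCoding:::alignToResponse(feat, 10, numeric(20))
  expect_equal(motionSensitivity(mv, c(0, 0), R, nIter = 50,
                                 maskDiameterUm = 60), 0, tolerance = 1e-6)

  # uncorrelated responses: M large over seeds
  Ms <- vapply(1:5, function(s) {
    set.seed(s)
    motionSensitivity(mv, c(0, 0), rnorm(20), nIter = 50,
                      maskDiameterUm = 60)
  }, numeric(1))
  expect_gt(median(Ms), 2)
})

test_that("in-center blend weight is recovered and floored", {
  seg <- data.frame(t0 = c(0.5, 6, 12), t1 = c(5, 11, 18),
                    vx = c(60, -40, 20), vy = c(0, 30, -50))
  mv <- generateNaturalisticSurrogate(20, seg, frameRate = 20, pixelSize = 4,
                                      fieldPx = c(80, 80), seed = 6)
  gc <- BipolarCoding:::alignToResponse(
    movieFeatureTrace(mv, c(0, 0), "luminance_center"), 20, numeric(190))
  gi <- BipolarCoding:::alignToResponse(
    movieFeatureTrace(mv, c(0, 0), "in_center"), 20, numeric(190))

  # response built purely from the center contrast: beta at the floor
  pure <- inCenterContrastSensitivity(mv, c(0, 0), gc)
  expect_equal(pure$beta, 0)
  expect_equal(pure$I, -3)

  # 0.5 blend recovered within 0.05
  Rb <- 0.5 * gi + 0.5 * gc
  rec <- inCenterContrastSensitivity(mv, c(0, 0), Rb)
  expect_equal(rec$beta, 0.5, tolerance = 0.05)

  # grid argmax agrees with a continuous optimizer
  opt <- optimize(function(b) -cor(b * gi + (1 - b) * gc, Rb), c(0, 1))
  expect_equal(rec$beta, opt$minimum, tolerance = 0.005)
})

test_that("receptive fields are mapped from white noise within the grid step", {
  cb <- generateCheckerboard(nUnique = 400, squareUm = 20, grid = c(12, 12),
                             pOn = 0.5, frameRate = 5, pixelSize = 4, seed = 7)
  simResp <- function(center) {
    w <- gaussianCenterMask(40, 4, dim(frames(cb))[1:2], center)
    tr <- BipolarCoding:::maskTrace(cb, w)
    g <- BipolarCoding:::gKernel(5)
    BipolarCoding:::shiftTrace(BipolarCoding:::convolveSame(tr, g), 1)
  }
  r1 <- mapReceptiveField(simResp(c(8, -4)), cb, shiftMs = 200)
  expect_lt(sqrt(sum((r1$center - c(8, -4))^2)), 2)
  expect_false(r1$flagged)

  r0 <- mapReceptiveField(simResp(c(0, 0)), cb, shiftMs = 200)
  expect_lt(sqrt(sum(r0$center^2)), 1)

  set.seed(71)
  rn <- mapReceptiveField(rnorm(800), cb, shiftMs = 200)
  expect_true(rn$flagged)
  expect_lt(rn$quality, 0.1)
})

test_that("luminance explained variance reports the reliability ceiling", {
  mv <- generateNaturalisticSurrogate(10, data.frame(t0 = 1, t1 = 9,
                                                     vx = 40, vy = 20),
                                      frameRate = 20, pixelSize = 4,
                                      fieldPx = c(40, 40), seed = 8)
  lum <- BipolarCoding:::alignToResponse(
    movieFeatureTrace(mv, c(0, 0), "luminance_center"), 20, numeric(95))
  res <- luminanceExplainedVariance(lum, mv)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  expect_true(is.na(res$ceiling))

  set.seed(81)
  reps <- rbind(lum + rnorm(95, 0, 0.5 * sd(lum)),
                lum + rnorm(95, 0, 0.5 * sd(lum)))
  res2 <- luminanceExplainedVariance(reps, mv)
  expect_true(res2$ceiling > 0.3 && res2$ceiling <= 1)
  expect_gt(res2$r2, 0.5)

  noise <- matrix(rnorm(95), 1)
  expect_lt(luminanceExplainedVariance(noise, mv)$r2, 0.15)
})

test_that("feature autocorrelation decays with distance, slower for luminance", {
  seg <- data.frame(t0 = c(0.5, 3), t1 = c(2.5, 5.5), vx = c(50, -30),
                    vy = c(20, -40))
  mv <- generateNaturalisticSurrogate(6, seg, frameRate = 15, pixelSize = 4,
                                      fieldPx = c(60, 60), seed = 9)
  lum <- featureSpatialAutocorrelation(mv, "luminance_center",
                                       gridHalfUm = 16, stepUm = 8)
  expect_gt(lum$medianCorr[1], 0.9)
  expect_lt(cor(lum$distance, lum$medianCorr, method = "spearman"), 0)

  inc <- featureSpatialAutocorrelation(mv, "in_center",
                                       gridHalfUm = 16, stepUm = 8)
  expect_gt(mean(lum$medianCorr), mean(inc$medianCorr))
})

test_that("visual angle conversion matches the printed projection extents", {
  expect_equal(visualAngleExtent(800, 1.98, roundDeg = TRUE), 49)
  expect_equal(visualAngleExtent(600, 1.98, roundDeg = TRUE), 37)
  expect_equal(visualAngleExtent(32.5, 1), 1)
})
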