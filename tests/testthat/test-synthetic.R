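# Stimulus generators and the model-cell / arbor simulators.

test_that("spot stimulus renders the protocol geometry and epoch structure", {
  mv <- fixSpotMovie()
  lg <- stimulusLog(mv)
  expect_equal(sum(grepl("_ON$", lg$condition)), 7 * 2)

  mv5 <- generateSpotStimulus(repeats = 5, pixelSize = 40, frameRate = 5)
  expect_equal(sum(grepl("_ON$", stimulusLog(mv5)$condition)), 35)

  # rendered disk size: 100 um spot at 2 um/px -> 50 px diameter disk
  m1 <- generateSpotStimulus(sizes = 100, repeats = 1, pixelSize = 2,
                             fieldUm = 200, frameRate = 10)
  lg1 <- stimulusLog(m1)
  on <- lg1[grepl("_ON$", lg1$condition), ]
  fr <- frames(m1)[, , round((on$onset + 0.5) * frameRate(m1))]
  expect_lt(abs(sum(fr > 0.4) - pi * 25^2) / (pi * 25^2), 0.05)

  # OFF phase: dark disk on background; gap frames at background
  off <- lg1[grepl("_OFF$", lg1$condition), ]
  fOff <- frames(m1)[, , round((off$onset + 0.5) * frameRate(m1))]
  expect_equal(min(fOff), -0.5)
  expect_equal(frames(m1)[1, 1, 1], 0)  # pre-stimulus gap, corner pixel

  expect_error(generateSpotStimulus(sizes = 100, onS = 0),
               "positive")
})

test_that("frequency stimulus carries pure sinusoidal epochs", {
  fv <- generateFreqStimulus(freqs = 1, diameters = 150, durS = 2,
                             frameRate = 52.5, repeats = 1, pixelSize = 10,
                             fieldUm = 160)
  lg <- stimulusLog(fv)
  ctr <- dim(frames(fv))[1] %/% 2
  tr <- frames(fv)[ctr, ctr, ]
  ep <- tr[round(lg$onset[1] * 52.5 + 1):round(lg$offset[1] * 52.5)]
  # exactly 2 cycles: F1 power at 1 Hz dominates 2 Hz by > 100x
  p1 <- dftPowerOracle(ep, 1, 52.5)
  p2 <- dftPowerOracle(ep, 2, 52.5)
  expect_gt(p1 / max(p2, 1e-300), 100)

  fv6 <- generateFreqStimulus(diameters = 150, repeats = 5, pixelSize = 80,
                              fieldUm = 160, frameRate = 52.5)
  expect_equal(nrow(stimulusLog(fv6)), 30)

  expect_error(generateFreqStimulus(freqs = 30, frameRate = 52.5,
                                    diameters = 150),
               "Nyquist")
})

test_that("checkerboard white noise is binary, binomial and seeded", {
  cb <- generateCheckerboard(nUnique = 300, grid = c(10, 10), seed = 3)
  expect_equal(dim(frames(cb))[3], 600)
  expect_setequal(unique(as.numeric(frames(cb))), c(-0.5, 0.5))
  expect_lt(abs(mean(frames(cb) > 0) - 0.5), 0.01)
  # repeated sequence
  expect_identical(frames(cb)[, , 1:300], frames(cb)[, , 301:600])
  cb2 <- generateCheckerboard(nUnique = 300, grid = c(10, 10), seed = 3)
  expect_identical(frames(cb), frames(cb2))
})

test_that("naturalistic surrogate translates rigidly with a power-law spectrum", {
  # static: frames essentially identical
  mv0 <- generateNaturalisticSurrogate(1, NULL, frameRate = 10,
                                       fieldPx = c(32, 32), seed = 1)
  expect_gt(cor(as.numeric(frames(mv0)[, , 1]),
                as.numeric(frames(mv0)[, , 9])), 0.99)

  # motion: displacement accumulates at vx/(px * fps) pixels per frame
  seg <- data.frame(t0 = 0.5, t1 = 2.5, vx = 100, vy = 0)
  mv <- generateNaturalisticSurrogate(3, seg, frameRate = 60, pixelSize = 2,
                                      fieldPx = c(48, 48), seed = 2)
  # 0.833 px/frame: integer-lag cross-correlation across 6 frames peaks at 5
  a <- frames(mv)[, , 60]; b <- frames(mv)[, , 66]
  lags <- -8:8
  cc <- vapply(lags, function(l)
    cor(as.numeric(a[, 12:36]), as.numeric(b[, 12:36 + l])), numeric(1))
  expect_equal(lags[which.max(cc)], 5)

  # white spatial spectrum when the exponent is 0
  mw <- generateNaturalisticSurrogate(0.5, NULL, spatialExponent = 0,
                                      frameRate = 10, fieldPx = c(64, 64),
                                      seed = 3)
  f <- frames(mw)[, , 1]
  P <- Mod(stats::fft(f))^2
  u <- c(0:31, -32:-1) / 64
  fr <- sqrt(outer(u^2, u^2, "+"))
  sel <- fr > 0.05 & fr < 0.45
  slope <- coef(lm(log(P[sel]) ~ log(fr[sel])))[2]
  expect_lt(abs(slope), 0.5)
  # and a steep spectrum for the 1/f^2 default
  f2 <- frames(generateNaturalisticSurrogate(0.5, NULL, frameRate = 10,
                                             fieldPx = c(64, 64),
                                             seed = 3))[, , 1]
  P2 <- Mod(stats::fft(f2))^2
  slope2 <- coef(lm(log(P2[sel]) ~ log(fr[sel])))[2]
  expect_lt(slope2, -1.2)

  expect_error(generateNaturalisticSurrogate(
    3, data.frame(t0 = c(0, 1), t1 = c(1.5, 2), vx = 1, vy = 1)),
    "overlap")
})

test_that("model cell responds through center-surround, adaptation and GCaMP stages", {
  # zero-contrast movie: constant baseline
  quiet <- newStim <- generateSpotStimulus(sizes = 100, repeats = 1,
                                           pixelSize = 20, frameRate = 10)
  quiet@frames[] <- 0
  cell <- cellParams(noiseSd = 0)
  r0 <- simulateCellResponse(cell, quiet)
  expect_equal(r0$values, rep(cell$baseline, length(r0$values)))

  # GCaMP low-pass: F1 at 8 Hz weaker than at 0.5 Hz
  fv <- generateFreqStimulus(freqs = c(0.5, 8), diameters = 150, repeats = 1,
                             frameRate = 52.5, pixelSize = 40, fieldUm = 320,
                             seed = 1)
  rs <- simulateCellResponse(cellParams(noiseSd = 0, transienceTau = Inf),
                             fv, samplingRate = 37.9)
  lg <- stimulusLog(fv)
  pw <- vapply(c(0.5, 8), function(fq) {
    row <- lg[grepl(sprintf("^freq_%g_", fq), lg$condition), ]
    tt <- (seq_along(rs$values) - 0.5) / 37.9
    idx <- which(tt >= row$onset & tt < row$offset)
    f1Power(rs$values[idx], fq, 37.9)
  }, numeric(1))
  expect_gt(pw[1], pw[2])

  # a 150 um spot outdrives an 800 um spot exactly when the surround acts
  m2 <- generateSpotStimulus(sizes = c(150, 800), repeats = 1,
                             pixelSize = 10, frameRate = 10, seed = 5)
  peakBySize <- function(sw) {
    r <- simulateCellResponse(cellParams(surroundWeight = sw, noiseSd = 0,
                                         transienceTau = Inf), m2)
    ep <- responseTable(epochTrace(r$values, r$rate, stimulusLog(m2)))
    vapply(c(150, 800), function(s) {
      d <- ep[ep$condition == sprintf("spot_%g_ON", s) & ep$time > 0, ]
      max(d$value)
    }, numeric(1))
  }
  p0 <- peakBySize(0)
  expect_lte(p0[1], p0[2] + 0.01 * abs(p0[2]))  # pixelization slack
  p5 <- peakBySize(0.5)
  expect_gt(p5[1], p5[2])

  expect_error(
    simulateCellResponse(cellParams(rfCenter = c(5000, 0)), m2),
    "outside")
})

test_that("surround calibrated to a 34% large/small spot ratio yields S near 0.66", {
  m2 <- generateSpotStimulus(sizes = c(50, 100, 150, 600, 800), repeats = 1,
                             pixelSize = 10, frameRate = 10, seed = 5)
  win <- function(sw) {
    r <- simulateCellResponse(cellParams(surroundWeight = sw, noiseSd = 0,
                                         transienceTau = Inf), m2)
    ep <- responseTable(epochTrace(r$values, r$rate, stimulusLog(m2)))
    vapply(c(150, 800), function(s) {
      d <- ep[ep$condition == sprintf("spot_%g_ON", s) &
                ep$time >= 0.34 & ep$time < 1.54, ]
      mean(d$value)
    }, numeric(1))
  }
  swStar <- uniroot(function(sw) { v <- win(sw); v[2] / v[1] - 0.34 },
                    c(0.3, 1.0), tol = 1e-3)$root
  r <- simulateCellResponse(cellParams(surroundWeight = swStar, noiseSd = 0,
                                       transienceTau = Inf), m2)
  map <- spotResponseMap(epochTrace(r$values, r$rate, stimulusLog(m2)), 1)
  expect_lt(abs(suppressWarnings(surroundStrength(map)) - 0.66), 0.05)
})

test_that("rendering is faithful, deterministic, and bounded by the field of view", {
  pos <- rbind(c(-6, 0, 0), c(6, 0, 0))
  tr <- rbind(sin(seq(0, 20, length.out = 200))^2,
              cos(seq(0, 15, length.out = 200))^2)
  s0 <- renderImageSeries(pos[1, , drop = FALSE], tr[1, , drop = FALSE],
                          pxSize = 1, blobSigmaUm = 2)
  d <- dim(seriesData(s0))
  blob <- matrix(seriesData(s0), d[1] * d[2], d[3])
  inside <- which(apply(seriesData(s0), 1:2, max) >
                    0.5 * max(seriesData(s0)))
  expect_equal(cor(colMeans(blob[inside, ]), tr[1, ]), 1, tolerance = 1e-12)

  s1 <- renderImageSeries(pos, tr, pxSize = 1, photonNoiseSd = 0.05, seed = 9)
  s2 <- renderImageSeries(pos, tr, pxSize = 1, photonNoiseSd = 0.05, seed = 9)
  expect_identical(seriesData(s1), seriesData(s2))

  expect_error(renderImageSeries(pos, tr, fovUm = c(4, 4)), "field of view")
})

test_that("end-to-end: rendered two-cell series segments into matching traces", {
  pos <- rbind(c(-6, 0, 0), c(6, 0, 0))
  tr <- rbind(sin(seq(0, 20, length.out = 300))^2,
              cos(seq(0, 15, length.out = 300))^2)
  ser <- renderImageSeries(pos, tr, pxSize = 1, photonNoiseSd = 0.02,
                           blobSigmaUm = 2, seed = 1)
  pp <- preprocessSeries(ser)
  rois <- segmentRois(pp$sdImage, pixelSize = 1)
  expect_equal(nrow(roiPeaks(rois)), 2)
  m <- matrix(seriesData(ser), prod(dim(roiLabels(rois))), 300)
  cors <- vapply(1:2, function(r) {
    tRec <- colMeans(m[which(roiLabels(rois) == r), , drop = FALSE])
    max(cor(tRec, tr[1, ]), cor(tRec, tr[2, ]))
  }, numeric(1))
  expect_true(all(cors > 0.9))
})

test_that("arbor generator produces the assumed correlation structure", {
  # homogeneous arbor: all pairwise correlations 1
  gInf <- generateArbor(10, diameterUm = 40, lengthConstant = Inf,
                        localNoiseSd = 0, seed = 1)
  cm <- cor(t(gInf$traces[, , 1]))
  expect_equal(max(abs(cm - 1)), 0, tolerance = 1e-9)

  # exp(-d/lambda) is e^-1 at d = lambda
  expect_equal(exp(-30 / 30), 0.3679, tolerance = 1e-4)

  # finite lambda: observed/expected consistency ratio follows exp(-d/lambda)
  ga <- generateArbor(60, diameterUm = 80, lengthConstant = 30,
                      localNoiseSd = 0.2, seed = 7)
  pc <- pairedConsistency(ga$traces)
  ut <- upper.tri(ga$pathDistances)
  ratio <- pmin(1, (pc$k / pc$q)[ut])
  d <- ga$pathDistances[ut]
  fit <- lm(log(pmax(ratio, 1e-3)) ~ d)
  expect_gt(summary(fit)$r.squared, 0.8)
  expect_equal(unname(-1 / coef(fit)[2]), 30, tolerance = 0.25)

  # noise-free signals decay monotonically with distance
  g0 <- generateArbor(40, diameterUm = 80, lengthConstant = 25,
                      localNoiseSd = 0, seed = 3)
  cm0 <- cor(t(g0$traces[, , 1]))
  expect_lt(cor(g0$pathDistances[upper.tri(cm0)], cm0[upper.tri(cm0)],
                method = "spearman"), -0.8)

  expect_error(generateArbor(10, lengthConstant = -5), "positive")
})

test_that("generators are pure functions of their seeds", {
  expect_identical(frames(generateSpotStimulus(sizes = 100, repeats = 1,
                                               pixelSize = 20, seed = 4)),
                   frames(generateSpotStimulus(sizes = 100, repeats = 1,
                                               pixelSize = 20, seed = 4)))
  a <- generateArbor(8, seed = 11)
  b <- generateArbor(8, seed = 11)
  expect_identical(a$traces, b$traces)
  expect_identical(arborNodes(a$arbor), arborNodes(b$arbor))
  m1 <- generateNaturalisticSurrogate(0.5, NULL, fieldPx = c(16, 16),
                                      frameRate = 10, seed = 6)
  m2 <- generateNaturalisticSurrogate(0.5, NULL, fieldPx = c(16, 16),
                                      frameRate = 10, seed = 6)
  expect_identical(frames(m1), frames(m2))
})
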