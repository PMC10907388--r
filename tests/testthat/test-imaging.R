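# Registration, median filtering/masking, ROI segmentation, epoching,
# repeat reliability and ROI consolidation.

test_that("rigid registration recovers integer shifts and handles degenerate frames", {
  set.seed(10)
  base <- matrix(0, 40, 40)
  base[15:20, 10:18] <- 1
  base <- base + matrix(rnorm(1600, 0, 0.01), 40)
  identicalSeries <- methods::new("ImageSeries",
    data = array(rep(base, 3), c(40, 40, 3)), frameRate = 10, pixelSize = 1)
  reg0 <- registerRigid(identicalSeries)
  expect_true(all(reg0$shifts == 0))

  # any integer shift inside the search radius is recovered exactly
  for (sh in list(c(3, -2), c(-5, 4), c(0, 7))) {
    fr <- BipolarCoding:::shiftFrame(base, sh[1], sh[2])
    ser <- methods::new("ImageSeries", data = array(c(base, fr), c(40, 40, 2)),
                        frameRate = 10, pixelSize = 1)
    reg <- registerRigid(ser)
    expect_equal(unname(reg$shifts[2, ]), -sh)
    # registered frame matches the reference away from the wrap margin
    expect_gt(cor(as.numeric(seriesData(reg$series)[10:30, 10:30, 2]),
                  as.numeric(base[10:30, 10:30])), 0.99)
  }

  zero <- methods::new("ImageSeries",
    data = array(c(base, matrix(0, 40, 40)), c(40, 40, 2)),
    frameRate = 10, pixelSize = 1)
  expect_warning(registerRigid(zero), "no structure")

  # shifts transfer to a paired channel
  fr <- BipolarCoding:::shiftFrame(base, 2, 2)
  ser <- methods::new("ImageSeries", data = array(c(base, fr), c(40, 40, 2)),
                      frameRate = 10, pixelSize = 1)
  reg <- registerRigid(ser)
  paired <- applyShifts(ser, reg$shifts)
  expect_identical(seriesData(paired), seriesData(reg$series))

  # axial-drift QC: a decorrelating frame fails the correlation floor
  qcGood <- registrationQc(reg$series)
  expect_true(qcGood$pass)
  drift <- methods::new("ImageSeries",
    data = array(c(base, matrix(rnorm(1600), 40)), c(40, 40, 2)),
    frameRate = 10, pixelSize = 1)
  qcBad <- registrationQc(drift)
  expect_false(qcBad$pass)
  expect_equal(qcBad$worstFrame, 2L)
})

test_that("median filter removes impulses and the SD mask keeps the top quartile", {
  arr <- array(0, c(12, 12, 10))
  arr[6, 6, 5] <- 100
  s <- methods::new("ImageSeries", data = arr, frameRate = 10, pixelSize = 1)
  p <- suppressWarnings(preprocessSeries(s))
  expect_equal(max(seriesData(p$series)), 0)

  expect_warning(preprocessSeries(s), "constant|empty")

  set.seed(4)
  arr2 <- array(rnorm(12 * 12 * 30), c(12, 12, 30))
  # give a known quarter of pixels much larger variance
  arr2[1:6, 1:6, ] <- arr2[1:6, 1:6, ] * 10
  p2 <- preprocessSeries(arr2 |>
    (\(a) methods::new("ImageSeries", data = a, frameRate = 10,
                       pixelSize = 1))())
  expect_equal(sum(p2$mask), ceiling(0.75 * 144), tolerance = 2)
  expect_true(all(p2$mask[1:6, 1:6]))
})

test_that("segmentation grows 4-connected ROIs from peaks and honors manual seeds", {
  g <- BipolarCoding:::pixelGrid(30, 30, 1)
  img <- exp(-((g$x + 6)^2 + g$y^2) / 8) + exp(-((g$x - 6)^2 + g$y^2) / 8)
  rm <- segmentRois(img, threshold = 0.05, pixelSize = 1)
  expect_equal(nrow(roiPeaks(rm)), 2)
  # labels partition the above-threshold mask
  expect_identical(roiLabels(rm) > 0, img >= 0.05)
  # each ROI is 4-connected
  for (r in 1:2) {
    px <- which(roiLabels(rm) == r, arr.ind = TRUE)
    gg <- igraph::make_empty_graph(n = nrow(px), directed = FALSE)
    dd <- as.matrix(dist(px))
    ee <- which(dd == 1 & upper.tri(dd), arr.ind = TRUE)
    gg <- igraph::add_edges(gg, t(ee))
    expect_equal(igraph::components(gg)$no, 1)
  }
  expect_equal(sum(roiAreas(rm)), sum(img >= 0.05))

  # flat image entirely below threshold: no ROIs
  rm0 <- segmentRois(matrix(0, 10, 10), threshold = 1)
  expect_equal(nrow(roiPeaks(rm0)), 0)
  expect_true(all(roiLabels(rm0) == 0))

  # manual seed on a flank snaps to the secondary maximum nearby
  img2 <- exp(-((g$x)^2 + g$y^2) / 20)
  img2[15, 21] <- img2[15, 21] + 0.3  # secondary bump on the flank
  rmM <- segmentRois(img2, threshold = 0.05,
                     manualSeeds = rbind(c(15, 22)), pixelSize = 1)
  expect_equal(nrow(roiPeaks(rmM)), 2)
  expect_true(any(roiPeaks(rmM)[, 1] == 15 & roiPeaks(rmM)[, 2] == 21))
})

test_that("epoching aligns, baseline-subtracts and truncates with a warning", {
  lg <- data.frame(condition = "stim", onset = c(2, 6), offset = c(4, 8))
  rate <- 10
  const <- epochTrace(rep(5, 100), rate, lg)
  expect_true(all(abs(responseTable(const)$value) < 1e-12))
  expect_equal(sort(unique(responseTable(const)$rep)), c(1, 2))

  step <- c(rep(0, 20), rep(1, 80))
  ep <- responseTable(epochTrace(step, rate, lg))
  post <- ep[ep$rep == 1 & ep$time >= 0, ]
  expect_equal(mean(post$value), 1)

  expect_warning(epochTrace(rep(1, 50), rate,
                            data.frame(condition = "s", onset = 4.5,
                                       offset = 7)),
                 "truncated")

  # synthetic cell: ON response peaks within 0.5 s of onset for a
  # transient cell
  mv <- fixSpotMovie()
  r <- simulateCellResponse(cellParams(transienceTau = 0.3, noiseSd = 0), mv)
  ep2 <- responseTable(epochTrace(r$values, r$rate, stimulusLog(mv)))
  on200 <- ep2[ep2$condition == "spot_200_ON" & ep2$rep == 1, ]
  expect_lt(on200$time[which.max(on200$value)], 0.5 + 0.35)
})

test_that("repeat reliability evaluates balanced half-splits", {
  tri <- matrix(rep(sin(1:100 / 5), 4), 4, 100, byrow = TRUE)
  expect_equal(repeatReliability(tri), 1)

  set.seed(11)
  wn <- matrix(rnorm(4 * 500), 4)
  expect_lt(repeatReliability(wn), 0.05)

  # 2 trials: exactly one split, equal to cor(t1, t2)^2
  two <- wn[1:2, ]
  expect_equal(repeatReliability(two), cor(two[1, ], two[2, ])^2)

  # invariant to trial order and affine rescaling
  tri5 <- matrix(rnorm(5 * 80), 5) + rep(sin(1:80 / 3), each = 5)
  r1 <- repeatReliability(tri5)
  expect_equal(repeatReliability(tri5[sample(5), ]), r1)
  expect_equal(repeatReliability(tri5 * 3 + 7), r1)

  expect_warning(repeatReliability(matrix(1, 2, 10)), "zero-variance")
  expect_error(repeatReliability(matrix(1, 1, 10)), "2 trials")
})

test_that("k-means/BIC consolidation picks the planted cluster count", {
  set.seed(12)
  base <- sin(1:80 / 4)
  same <- matrix(rep(base, 6), 6, byrow = TRUE)
  cr1 <- consolidateRois(same, kMax = 4)
  expect_equal(cr1$k, 1L)
  expect_equal(nrow(cr1$merged), 1)

  g1 <- matrix(rep(base, 10), 10, byrow = TRUE) + matrix(rnorm(800, 0, 0.1), 10)
  g2 <- matrix(rep(cos(1:80 / 2), 10), 10, byrow = TRUE) +
    matrix(rnorm(800, 0, 0.1), 10)
  cr2 <- consolidateRois(rbind(g1, g2), kMax = 6)
  expect_equal(cr2$k, 2L)
  expect_lt(cr2$bic[2], cr2$bic[1])
  expect_lt(cr2$bic[2], cr2$bic[3])
  # members of each cluster come from one planted group
  expect_equal(length(unique(cr2$assignment[1:10])), 1)
  expect_equal(length(unique(cr2$assignment[11:20])), 1)

  cr3 <- consolidateRois(matrix(base, 1), kMax = 5)
  expect_equal(cr3$k, 1L)

  # kMax above n is capped
  cr4 <- consolidateRois(rbind(g1[1:3, ]), kMax = 10)
  expect_lte(length(cr4$bic), 3)

  # plane constraint: same cluster, different planes stay separate
  cr5 <- consolidateRois(same, kMax = 2, plane = c(1, 1, 1, 2, 2, 2))
  expect_equal(nrow(cr5$merged), 2)
})
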