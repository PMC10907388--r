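# Synthetic-data generators: stimuli, model-cell responses, rendered image
# series and axon arbors with the statistical structure the downstream
# analyses assume. Every generator is a pure function of its arguments and
# seed.

newStimulusMovie <- function(frames, frameRate, pixelSize, log) {
  methods::new("StimulusMovie", frames = frames, frameRate = frameRate,
               pixelSize = pixelSize, log = log)
}

# Pixel-center coordinate grids (microns, origin at field center).
pixelGrid <- function(nr, nc, pixelSize) {
  list(
    x = matrix(((seq_len(nc)) - 0.5 - nc / 2) * pixelSize, nr, nc, byrow = TRUE),
    y = matrix(((seq_len(nr)) - 0.5 - nr / 2) * pixelSize, nr, nc)
  )
}

#' Generate a varying-size spot stimulus movie
#'
#' Spots of the given diameters are flashed ON (contrast +0.5) for `onS`
#' seconds then OFF (contrast -0.5 in the spot area) for `offS` seconds,
#' `repeats` times in a row per size, with sizes in a seeded pseudorandom
#' order and background gaps between size blocks. Defaults follow a
#' seven-size protocol (20-800 um diameters, 1.5 s ON / 1.5 s OFF, five
#' repeats per size).
#'
#' @param sizes spot diameters in microns.
#' @param onS,offS ON and OFF phase durations (s).
#' @param repeats consecutive ON-OFF cycles per size.
#' @param frameRate movie frame rate (Hz).
#' @param pixelSize microns per pixel.
#' @param fieldUm side length of the square stimulated field (um).
#' @param gapS background gap between size blocks (s); also precedes the
#'   first block so every epoch has a baseline window.
#' @param seed integer seed for the pseudorandom size order.
#' @return a [StimulusMovie-class]; the log holds one `_ON` and one `_OFF`
#'   epoch per cycle, conditions named `spot_<size>_ON` / `spot_<size>_OFF`.
#' @export
generateSpotStimulus <- function(sizes = c(20, 50, 100, 200, 400, 600, 800),
                                 onS = 1.5, offS = 1.5, repeats = 5,
                                 frameRate = 10, pixelSize = 10,
                                 fieldUm = max(sizes) * 1.1, gapS = 1.5,
                                 seed = 1) {
  stopifnot(all(sizes > 0), repeats >= 1)
  if (onS <= 0 || offS <= 0) stop("spot phase durations must be positive")
  order <- withSeed(seed, sample(seq_along(sizes)))
  np <- max(2L, round(fieldUm / pixelSize))
  g <- pixelGrid(np, np, pixelSize)
  r2 <- g$x^2 + g$y^2

  blockDur <- repeats * (onS + offS)
  total <- gapS + length(sizes) * (blockDur + gapS)
  nf <- round(total * frameRate)
  frames <- array(0, dim = c(np, np, nf))
  log <- NULL
  t0 <- gapS
  for (s in sizes[order]) {
    disk <- r2 <= (s / 2)^2
    for (r in seq_len(repeats)) {
      onA <- t0; onB <- t0 + onS; offB <- onB + offS
      fOn <- (floor(onA * frameRate) + 1):ceiling(onB * frameRate - 1e-9)
      fOff <- (floor(onB * frameRate) + 1):ceiling(offB * frameRate - 1e-9)
      frames[, , fOn] <- frames[, , fOn] + as.numeric(disk) * 0.5
      frames[, , fOff] <- frames[, , fOff] - as.numeric(disk) * 0.5
      log <- rbind(log,
        data.frame(condition = sprintf("spot_%g_ON", s), onset = onA,
                   offset = onB),
        data.frame(condition = sprintf("spot_%g_OFF", s), onset = onB,
                   offset = offB))
      t0 <- offB
    }
    t0 <- t0 + gapS
  }
  newStimulusMovie(frames, frameRate, pixelSize, log[order(log$onset), ])
}

#' Generate a frequency-modulated spot stimulus movie
#'
#' Spots are modulated sinusoidally over the full contrast range
#' (\[-0.5, 0.5\]) for `durS` seconds per epoch; frequencies appear
#' `repeats` times each in a seeded pseudorandom order, separately per spot
#' diameter, with background gaps between epochs.
#'
#' @param freqs modulation frequencies (Hz); all must be below the movie
#'   Nyquist frequency.
#' @param diameters spot diameters (um).
#' @param durS epoch duration (s).
#' @param frameRate movie frame rate (Hz).
#' @param repeats presentations per frequency.
#' @param pixelSize,fieldUm,gapS,seed see [generateSpotStimulus()].
#' @return a [StimulusMovie-class]; conditions named `freq_<f>_d<diam>`.
#' @export
generateFreqStimulus <- function(freqs = c(0.5, 1, 2, 4, 8, 16),
                                 diameters = c(150, 800), durS = 2,
                                 frameRate = 52.5, repeats = 5,
                                 pixelSize = 20,
                                 fieldUm = max(diameters) * 1.05,
                                 gapS = 1.5, seed = 1) {
  stopifnot(durS > 0, repeats >= 1)
  if (any(freqs >= frameRate / 2))
    stop("stimulus frequencies must be below the movie Nyquist frequency")
  np <- max(2L, round(fieldUm / pixelSize))
  g <- pixelGrid(np, np, pixelSize)
  r2 <- g$x^2 + g$y^2

  nEpoch <- length(freqs) * repeats * length(diameters)
  total <- gapS + nEpoch * (durS + gapS)
  nf <- round(total * frameRate)
  frames <- array(0, dim = c(np, np, nf))
  log <- NULL
  t0 <- gapS
  seq0 <- withSeed(seed, lapply(seq_along(diameters),
                                function(i) sample(rep(freqs, repeats))))
  for (di in seq_along(diameters)) {
    disk <- as.numeric(r2 <= (diameters[di] / 2)^2)
    for (f in seq0[[di]]) {
      fIdx <- (floor(t0 * frameRate) + 1):ceiling((t0 + durS) * frameRate - 1e-9)
      tRel <- (fIdx - 0.5) / frameRate - t0
      mod <- 0.5 * sin(2 * pi * f * tRel)
      for (j in seq_along(fIdx))
        frames[, , fIdx[j]] <- frames[, , fIdx[j]] + disk * mod[j]
      log <- rbind(log, data.frame(
        condition = sprintf("freq_%g_d%g", f, diameters[di]),
        onset = t0, offset = t0 + durS))
      t0 <- t0 + durS + gapS
    }
  }
  newStimulusMovie(frames, frameRate, pixelSize, log)
}

#' Generate a binary checkerboard white-noise stimulus
#'
#' A grid of squares whose contrasts are set ON (+0.5) with probability
#' `pOn` and OFF (-0.5) otherwise, independently per square and frame. The
#' unique frame sequence is shown twice (to allow response-quality
#' estimation); the log marks the two repeats.
#'
#' @param nUnique number of unique frames.
#' @param squareUm square side length (um).
#' @param grid c(rows, cols) of the square grid.
#' @param pOn probability a square is ON.
#' @param frameRate presentation rate (Hz).
#' @param pixelSize microns per rendered pixel (defaults to one pixel per
#'   square).
#' @param seed integer seed; the frame sequence is deterministic given it.
#' @return a [StimulusMovie-class] with `2 * nUnique` frames.
#' @export
generateCheckerboard <- function(nUnique = 900, squareUm = 20,
                                 grid = c(15, 20), pOn = 0.5, frameRate = 5,
                                 pixelSize = squareUm, seed = 1) {
  stopifnot(pOn > 0, pOn < 1, nUnique >= 1)
  sq <- max(1L, round(squareUm / pixelSize))
  vals <- withSeed(seed,
    array(ifelse(stats::runif(grid[1] * grid[2] * nUnique) < pOn, 0.5, -0.5),
          dim = c(grid[1], grid[2], nUnique)))
  up <- vals[rep(seq_len(grid[1]), each = sq),
             rep(seq_len(grid[2]), each = sq), , drop = FALSE]
  frames <- array(up[, , c(seq_len(nUnique), seq_len(nUnique))],
                  dim = c(dim(up)[1], dim(up)[2], 2 * nUnique))
  dur <- nUnique / frameRate
  log <- data.frame(
    condition = c("checkerboard_rep1", "checkerboard_rep2"),
    onset = c(0, dur), offset = c(dur, 2 * dur))
  newStimulusMovie(frames, frameRate, pixelSize, log)
}

#' Generate a naturalistic surrogate movie
#'
#' A spatially correlated (power-law spectrum) random luminance field,
#' translated rigidly during the given motion segments and static elsewhere.
#' Translation is exact (Fourier phase shift on the periodic field), so
#' sub-pixel velocities are rendered faithfully. Luminance is rescaled to
#' the \[-0.5, 0.5\] contrast range.
#'
#' @param durationS movie duration (s).
#' @param motionSegments data.frame with columns `t0`, `t1` (s) and `vx`,
#'   `vy` (um/s); segments must not overlap. NULL = static movie.
#' @param spatialExponent exponent of the spatial power spectrum
#'   (power ~ f^-exponent); 2 approximates natural images, 0 is white.
#' @param frameRate frames per second.
#' @param pixelSize microns per pixel.
#' @param fieldPx c(rows, cols) of the rendered frame.
#' @param seed integer seed.
#' @return a [StimulusMovie-class]; the log records one epoch per motion
#'   segment (`motion`) and the static stretches (`static`).
#' @export
generateNaturalisticSurrogate <- function(durationS, motionSegments = NULL,
                                          spatialExponent = 2,
                                          frameRate = 60, pixelSize = 2,
                                          fieldPx = c(64, 64), seed = 1) {
  stopifnot(durationS > 0, frameRate > 0)
  seg <- motionSegments
  if (!is.null(seg) && nrow(seg)) {
    if (any(seg$t0 < 0) || any(seg$t1 > durationS) || any(seg$t1 <= seg$t0))
      stop("motion segments must lie within the movie duration")
    o <- order(seg$t0)
    if (nrow(seg) > 1 && any(seg$t0[o][-1] < seg$t1[o][-nrow(seg)] - 1e-9))
      stop("motion segments must not overlap")
  }
  nr <- fieldPx[1]; nc <- fieldPx[2]
  nf <- max(2L, round(durationS * frameRate))

  u <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
  v <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
  fu <- matrix(u, nr, nc)
  fv <- matrix(v, nr, nc, byrow = TRUE)
  fr <- sqrt(fu^2 + fv^2)
  amp <- ifelse(fr > 0, fr^(-spatialExponent / 2), 0)
  phase <- withSeed(seed, matrix(stats::runif(nr * nc, 0, 2 * pi), nr, nc))
  F0 <- amp * exp(1i * phase)

  # cumulative displacement (um) at each frame time
  tf <- (seq_len(nf) - 0.5) / frameRate
  dx <- numeric(nf); dy <- numeric(nf)
  if (!is.null(seg) && nrow(seg)) {
    velAt <- function(t, comp) {
      out <- numeric(length(t))
      for (k in seq_len(nrow(seg)))
        out[t >= seg$t0[k] & t < seg$t1[k]] <- seg[[comp]][k]
      out
    }
    dt <- 1 / frameRate
    dx <- cumsum(velAt(tf, "vx")) * dt
    dy <- cumsum(velAt(tf, "vy")) * dt
  }

  base <- Re(stats::fft(F0, inverse = TRUE)) / (nr * nc)
  lo <- min(base); hi <- max(base)
  frames <- array(0, dim = c(nr, nc, nf))
  for (i in seq_len(nf)) {
    sr <- dy[i] / pixelSize  # rows move with y
    sc <- dx[i] / pixelSize
    if (sr == 0 && sc == 0) f <- base
    else f <- Re(stats::fft(F0 * exp(-2i * pi * (fu * sr + fv * sc)),
                            inverse = TRUE)) / (nr * nc)
    frames[, , i] <- pmin(0.5, pmax(-0.5, (f - lo) / (hi - lo) - 0.5))
  }
  log <- if (!is.null(seg) && nrow(seg)) {
    data.frame(condition = "motion", onset = seg$t0, offset = seg$t1)
  } else {
    data.frame(condition = "static", onset = 0, offset = durationS)
  }
  newStimulusMovie(frames, frameRate, pixelSize, log)
}

#' Model-cell parameters
#'
#' Bundles the parameters of the linear-nonlinear model bipolar cell used by
#' [simulateCellResponse()]: a Gaussian-weighted receptive-field center (SD =
#' `centerRadius / 2`) minus `surroundWeight` times a uniform annular
#' surround, an adaptation (high-pass) stage with time constant
#' `transienceTau` (Inf = fully sustained), rectification, GCaMP6f kernel
#' convolution, and additive AR(1) noise with lag-1 coefficient `noisePhi`
#' and marginal standard deviation `noiseSd`.
#'
#' @param typeLabel cell-type label (free text; canonical ON types are
#'   BC5o, BC5i, BC5t, XBC, BC6, BC7, BC8/9).
#' @param centerRadius,surroundRadius receptive-field radii (um);
#'   surround must exceed center.
#' @param surroundWeight relative surround gain (>= 0).
#' @param transienceTau adaptation time constant (s).
#' @param motionGain gain on a motion-energy drive (mean absolute temporal
#'   gradient in the center), giving motion-sensitive responses.
#' @param baseline resting fluorescence (a.u.).
#' @param noisePhi,noiseSd AR(1) noise parameters.
#' @param rfCenter receptive-field center (x, y) in um from field center.
#' @param iplDepth stratification depth, fraction of the IPL in \[0, 1\].
#' @return a `CellParams` list.
#' @export
cellParams <- function(typeLabel = "BC6", centerRadius = 25,
                       surroundRadius = 300, surroundWeight = 0.5,
                       transienceTau = 1, motionGain = 0, baseline = 1,
                       noisePhi = 0.5, noiseSd = 0, rfCenter = c(0, 0),
                       iplDepth = 0.7) {
  stopifnot(surroundRadius > centerRadius, surroundWeight >= 0,
            iplDepth >= 0, iplDepth <= 1, abs(noisePhi) < 1, noiseSd >= 0)
  structure(list(typeLabel = typeLabel, centerRadius = centerRadius,
                 surroundRadius = surroundRadius,
                 surroundWeight = surroundWeight,
                 transienceTau = transienceTau, motionGain = motionGain,
                 baseline = baseline, noisePhi = noisePhi, noiseSd = noiseSd,
                 rfCenter = rfCenter, iplDepth = iplDepth),
            class = "CellParams")
}

#' Default parameters for the seven ON bipolar cell types
#'
#' A parameter table capturing the qualitative organization of ON bipolar
#' cells into two laminar blocks: the upper block (BC5o, BC5i, BC5t, XBC)
#' shares strong surround suppression but spans transient-to-sustained
#' kinetics, while the lower block (BC6, BC7, BC8/9) shares sustained
#' kinetics but spans weak-to-inverting surround strengths; types stratify
#' at increasing IPL depths.
#'
#' @return data.frame, one row per type, with [cellParams()] fields.
#' @export
defaultCellTypes <- function() {
  data.frame(
    typeLabel = c("BC5o", "BC5i", "BC5t", "XBC", "BC6", "BC7", "BC8/9"),
    block = c("upper", "upper", "upper", "upper", "lower", "lower", "lower"),
    centerRadius = 25,
    surroundRadius = 300,
    surroundWeight = c(0.70, 0.70, 0.70, 0.70, 0.40, 1.10, 0.20),
    transienceTau = c(0.45, 0.90, 4.00, 0.15, 2.50, 2.50, 2.50),
    motionGain = c(0.7, 0.7, 0.7, 1.0, 0.3, 0.3, 0.3),
    baseline = 1,
    noisePhi = 0.5,
    noiseSd = 0.05,
    iplDepth = c(0.50, 0.55, 0.60, 0.63, 0.72, 0.80, 0.90),
    stringsAsFactors = FALSE
  )
}

#' Simulate a population of typed model cells on a spot stimulus
#'
#' Draws `nPerType` cells of each of the seven default ON bipolar cell
#' types ([defaultCellTypes()]), simulates their responses to a
#' varying-size spot movie and returns, per cell, the concatenated
#' repeat-averaged ON-epoch response vector (the feature vector used for
#' functional distances and classification), plus type labels and
#' jittered IPL depths.
#'
#' @param nPerType cells per type.
#' @param movie a spot [StimulusMovie-class]; default
#'   `generateSpotStimulus(pixelSize = 20, repeats = 2)`.
#' @param samplingRate acquisition rate (Hz).
#' @param noiseSd AR(1) noise SD of each simulated cell.
#' @param depthJitter SD of per-cell IPL-depth jitter.
#' @param seed integer seed.
#' @return list with `responses` (cells x features matrix), `types`,
#'   `depths`, `block` (per cell) and `movie`.
#' @export
simulateTypePopulation <- function(nPerType = 6, movie = NULL,
                                   samplingRate = 9.5, noiseSd = 0.05,
                                   depthJitter = 0.02, seed = 1) {
  if (is.null(movie))
    movie <- generateSpotStimulus(pixelSize = 20, frameRate = 10, repeats = 2)
  ct <- defaultCellTypes()
  lg <- movie@log
  withSeed(seed, {
    rows <- rep(seq_len(nrow(ct)), each = nPerType)
    responses <- NULL
    depths <- numeric(length(rows))
    for (k in seq_along(rows)) {
      i <- rows[k]
      cell <- cellParams(typeLabel = ct$typeLabel[i],
                         centerRadius = ct$centerRadius[i],
                         surroundRadius = ct$surroundRadius[i],
                         surroundWeight = ct$surroundWeight[i],
                         transienceTau = ct$transienceTau[i],
                         motionGain = 0, baseline = ct$baseline[i],
                         noisePhi = ct$noisePhi[i], noiseSd = noiseSd,
                         iplDepth = ct$iplDepth[i])
      r <- simulateCellResponse(cell, movie, samplingRate,
                                seed = sample.int(.Machine$integer.max, 1))
      ep <- epochOneTrace(r$values, r$rate, lg)
      ep <- ep[grepl("_ON$", ep$condition), ]
      ep$size <- as.numeric(sub("^spot_([0-9.]+)_ON$", "\\1", ep$condition))
      grp <- split(ep, list(ep$size, ep$rep), drop = TRUE)
      len <- min(vapply(grp, nrow, integer(1)))
      sizes <- sort(unique(ep$size))
      vec <- unlist(lapply(sizes, function(s) {
        gs <- grp[vapply(grp, function(g) g$size[1] == s, logical(1))]
        rowMeans(vapply(gs, function(g)
          g$value[order(g$time)][seq_len(len)], numeric(len)))
      }))
      responses <- rbind(responses, vec)
      depths[k] <- min(1, max(0, ct$iplDepth[i] +
                                stats::rnorm(1, 0, depthJitter)))
    }
    list(responses = responses, types = ct$typeLabel[rows],
         depths = depths, block = ct$block[rows], movie = movie)
  })
}

#' Simulate a model cell's calcium response to a stimulus movie
#'
#' Applies the linear center-surround drive, adaptation, rectification,
#' GCaMP6f kernel and AR(1) noise described in [cellParams()], then
#' resamples to the acquisition rate by box averaging.
#'
#' @param cell a [cellParams()] object.
#' @param movie a [StimulusMovie-class].
#' @param samplingRate acquisition rate of the returned trace (Hz).
#' @param seed seed for the noise; NULL leaves the RNG alone.
#' @param kernel GCaMP kernel from [gcampKernel()], sampled at the movie
#'   frame rate.
#' @return list with `values` (trace), `rate`, and `time` (s).
#' @export
simulateCellResponse <- function(cell, movie, samplingRate = 9.5, seed = NULL,
                                 kernel = NULL) {
  stopifnot(inherits(cell, "CellParams"), methods::is(movie, "StimulusMovie"))
  d <- dim(movie@frames)
  px <- movie@pixelSize
  ext <- c(d[2], d[1]) * px / 2
  if (abs(cell$rfCenter[1]) > ext[1] || abs(cell$rfCenter[2]) > ext[2])
    stop("receptive-field center lies outside the movie extent")
  g <- pixelGrid(d[1], d[2], px)
  r2 <- (g$x - cell$rfCenter[1])^2 + (g$y - cell$rfCenter[2])^2
  wc <- exp(-r2 / (2 * (cell$centerRadius / 2)^2))
  wc <- wc / sum(wc)
  ws <- as.numeric(r2 > cell$centerRadius^2 & r2 <= cell$surroundRadius^2)
  if (sum(ws) > 0) ws <- ws / sum(ws)
  mat <- matrix(movie@frames, d[1] * d[2], d[3])
  drive <- as.numeric(crossprod(as.numeric(wc), mat)) -
    cell$surroundWeight * as.numeric(crossprod(as.numeric(ws), mat))
  if (cell$motionGain != 0) {
    cmask <- as.numeric(r2 <= cell$centerRadius^2)
    cmask <- cmask / max(1, sum(cmask))
    dframes <- abs(mat[, c(1, seq_len(d[3] - 1))] - mat)
    drive <- drive + cell$motionGain * as.numeric(crossprod(cmask, dframes))
  }
  lp <- expLowpass(drive, cell$transienceTau, movie@frameRate, init = drive[1])
  rectified <- pmax(drive - lp, 0)
  if (is.null(kernel)) kernel <- gcampKernel(rate = movie@frameRate)
  conv <- convolveCausal(rectified, kernel$values)
  trace <- binToRate(conv, movie@frameRate, samplingRate) + cell$baseline
  if (cell$noiseSd > 0) {
    n <- length(trace)
    innov <- cell$noiseSd * sqrt(1 - cell$noisePhi^2)
    noise <- withSeed(seed, as.numeric(stats::filter(
      stats::rnorm(n, 0, innov), cell$noisePhi, method = "recursive",
      init = stats::rnorm(1, 0, cell$noiseSd))))
    trace <- trace + noise
  }
  list(values = trace, rate = samplingRate,
       time = (seq_along(trace) - 0.5) / samplingRate)
}

#' Render per-ROI response traces into an image time series
#'
#' Each ROI is drawn as a 2-D Gaussian blob at its skeleton (x, y) location
#' with intensity scaled by its trace, plus i.i.d. Gaussian noise.
#'
#' @param arbor an [ArborModel-class] (ROI positions) or an n x 2 matrix of
#'   (x, y) centers in um.
#' @param responses numeric matrix, one row per ROI, columns = frames; all
#'   ROIs share the time base.
#' @param frameRate acquisition rate (Hz) recorded in the output.
#' @param pxSize microns per pixel.
#' @param photonNoiseSd SD of i.i.d. additive noise.
#' @param blobSigmaUm Gaussian blob SD (um).
#' @param fovUm optional c(width, height) field of view centered on the ROI
#'   centroid; ROIs outside it are an error. Default fits all ROIs.
#' @param seed seed for the noise.
#' @return an [ImageSeries-class].
#' @export
renderImageSeries <- function(arbor, responses, frameRate = 9.5, pxSize = 1,
                              photonNoiseSd = 0, blobSigmaUm = 1.5,
                              fovUm = NULL, seed = NULL) {
  pos <- if (methods::is(arbor, "ArborModel"))
    arbor@nodes[arbor@roiNodes, 1:2, drop = FALSE] else as.matrix(arbor)
  pos <- pos[, 1:2, drop = FALSE]
  stopifnot(nrow(pos) == nrow(responses))
  ctr <- colMeans(pos)
  margin <- 4 * blobSigmaUm
  if (is.null(fovUm)) {
    fovUm <- c(diff(range(pos[, 1])) + 2 * margin,
               diff(range(pos[, 2])) + 2 * margin)
  } else {
    off <- abs(sweep(pos, 2, ctr))
    if (any(off[, 1] > fovUm[1] / 2 | off[, 2] > fovUm[2] / 2))
      stop("ROI outside the requested field of view")
  }
  nc <- max(2L, ceiling(fovUm[1] / pxSize))
  nr <- max(2L, ceiling(fovUm[2] / pxSize))
  g <- pixelGrid(nr, nc, pxSize)
  B <- vapply(seq_len(nrow(pos)), function(i) {
    w <- exp(-((g$x - (pos[i, 1] - ctr[1]))^2 +
               (g$y - (pos[i, 2] - ctr[2]))^2) / (2 * blobSigmaUm^2))
    as.numeric(w)
  }, numeric(nr * nc))
  dat <- B %*% responses
  if (photonNoiseSd > 0)
    dat <- dat + withSeed(seed,
      matrix(stats::rnorm(length(dat), 0, photonNoiseSd), nrow(dat)))
  methods::new("ImageSeries", data = array(dat, c(nr, nc, ncol(responses))),
               frameRate = frameRate, pixelSize = pxSize,
               channel = "fluorescence")
}

#' Generate a model axon arbor with distance-correlated ROI responses
#'
#' Builds a random planar tree skeleton of the given equivalent diameter,
#' places ROIs on its nodes, and draws per-ROI signals whose pairwise
#' correlations decay with path distance d as exp(-d / (2 * lambda)), so
#' that the paired-consistency model (observed consistency k =
#' exp(-d / lambda) times expected consistency q) holds with length
#' constant `lengthConstant`. `lengthConstant = Inf` yields a perfectly
#' homogeneous arbor (all ROIs share one signal). Two (or `nRepeats`)
#' repeats are generated with independent local noise.
#'
#' @param nRois number of ROIs (>= 2).
#' @param diameterUm equivalent diameter of the arbor territory (um).
#' @param lengthConstant um; Inf allowed.
#' @param sharedSignal response trace shared across the arbor; default is a
#'   smoothed noise trace of length `signalLength`.
#' @param localNoiseSd SD of per-repeat independent noise (signals have
#'   unit variance).
#' @param seed integer seed.
#' @param nNodes skeleton nodes (>= nRois).
#' @param nRepeats repeats to generate.
#' @param signalLength samples in the default shared signal.
#' @return list with `arbor` ([ArborModel-class]), `traces` (array
#'   nRois x time x repeat), `pathDistances` (ROI pair matrix, um) and
#'   `signals` (noise-free per-ROI signals).
#' @export
generateArbor <- function(nRois, diameterUm = 60, lengthConstant = 30,
                          sharedSignal = NULL, localNoiseSd = 0.2, seed = 1,
                          nNodes = max(3 * nRois, 40), nRepeats = 2,
                          signalLength = 500) {
  stopifnot(nRois >= 2)
  if (!is.infinite(lengthConstant) && lengthConstant <= 0)
    stop("lengthConstant must be positive or Inf")
  withSeed(seed, {
    # uniform points in a disk, connected by their Euclidean MST
    R <- diameterUm / 2
    th <- stats::runif(nNodes, 0, 2 * pi)
    rr <- R * sqrt(stats::runif(nNodes))
    nodes <- cbind(x = rr * cos(th), y = rr * sin(th),
                   z = stats::rnorm(nNodes, 0, 1))
    dmat <- as.matrix(stats::dist(nodes))
    gFull <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                                 weighted = TRUE)
    gTree <- igraph::mst(gFull)
    edges <- igraph::as_edgelist(gTree, names = FALSE)
    storage.mode(edges) <- "integer"
    elen <- dmat[edges]
    roiNodes <- sort(sample(nNodes, nRois))

    gW <- igraph::make_empty_graph(n = nNodes, directed = FALSE)
    gW <- igraph::add_edges(gW, t(edges))
    igraph::E(gW)$weight <- sqrt(rowSums(
      (nodes[edges[, 1], ] - nodes[edges[, 2], ])^2))
    D <- igraph::distances(gW, v = roiNodes, to = roiNodes)

    if (is.null(sharedSignal))
      sharedSignal <- as.numeric(stats::filter(
        stats::rnorm(signalLength), rep(1 / 5, 5), sides = 2))
    sharedSignal[is.na(sharedSignal)] <- 0
    s0 <- as.numeric(scale(sharedSignal))
    T <- length(s0)

    if (is.infinite(lengthConstant)) {
      S <- matrix(rep(s0, each = nRois), nRois, T)
    } else {
      C <- exp(-D / (2 * lengthConstant))
      L <- t(chol(C + diag(1e-9, nRois)))
      B <- rbind(s0, matrix(stats::rnorm((nRois - 1) * T), nRois - 1, T))
      B[-1, ] <- t(scale(t(B[-1, , drop = FALSE])))
      S <- L %*% B
    }
    traces <- array(0, dim = c(nRois, T, nRepeats))
    for (r in seq_len(nRepeats))
      traces[, , r] <- S + matrix(stats::rnorm(nRois * T, 0, localNoiseSd),
                                  nRois, T)
    arbor <- methods::new("ArborModel", nodes = nodes, edges = edges,
                          roiNodes = as.integer(roiNodes),
                          diameter = diameterUm,
                          lengthConstant = lengthConstant)
    list(arbor = arbor, traces = traces, pathDistances = D, signals = S)
  })
}
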