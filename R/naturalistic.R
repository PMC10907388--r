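# Receptive-field mapping from white noise and the feature sensitivities of
# naturalistic movies: spatial contrast, temporal contrast, coherent motion
# (Horn-Schunck optical flow), in-center contrast, and local luminance.

#' Truncated Gaussian receptive-field weight mask
#'
#' Bivariate normal weights centered at `center` (um from the frame
#' center), with covariance 2*pi*r times the identity (um^2, r the radius),
#' zeroed beyond the radius and normalized to a maximum of 1.
#'
#' @param radiusUm receptive-field radius (um); must cover >= 1 pixel.
#' @param pixelSize microns per pixel.
#' @param dim c(rows, cols) of the target frame.
#' @param center (x, y) offset of the mask center in um.
#' @param sigma2 covariance scale (um^2); default `2 * pi * radiusUm`.
#' @return weight matrix (rows x cols).
#' @export
gaussianCenterMask <- function(radiusUm, pixelSize, dim, center = c(0, 0),
                               sigma2 = 2 * pi * radiusUm) {
  if (radiusUm < pixelSize) stop("mask radius below one pixel")
  g <- pixelGrid(dim[1], dim[2], pixelSize)
  r2 <- (g$x - center[1])^2 + (g$y - center[2])^2
  w <- exp(-r2 / (2 * sigma2))
  w[r2 > radiusUm^2] <- 0
  mx <- max(w)
  if (mx == 0) stop("mask does not cover the frame")
  w / mx
}

# g-kernel: the 2 s GCaMP6f response function centered in a 4 s window,
# area-normalized so steady-state gain is 1.
gKernel <- function(rate, kernel = NULL) {
  if (is.null(kernel)) kernel <- gcampKernel(rate = rate, duration = 2)
  pad <- round(rate)
  k <- c(rep(0, pad), kernel$values, rep(0, pad))
  k / sum(k)
}

# Weighted-mask frame trace: dot product of each frame with the weights,
# divided by the weight sum.
maskTrace <- function(movie, w) {
  d <- dim(movie@frames)
  as.numeric(matrix(w, 1) %*% matrix(movie@frames, d[1] * d[2], d[3])) / sum(w)
}

#' Feature trace of a movie under a receptive-field mask
#'
#' Per-frame weighted average of the movie contrast under a Gaussian
#' center mask (`luminance_center`, 100 um diameter), a center-minus-
#' surround pair (600 um surround), or the in-center contrast
#' (`in_center`: the SD across the four center quadrants, each weighted by
#' the Gaussian mask times a linear radial ramp). Optionally convolved
#' with the 4 s g kernel (2 s GCaMP6f response function at its center,
#' area-normalized) and delayed by `shiftMs` to align with the delayed
#' responses.
#'
#' @param movie a [StimulusMovie-class].
#' @param rf receptive-field center (x, y) in um from the frame center.
#' @param kind one of `"luminance_center"`, `"center_minus_surround"`,
#'   `"in_center"`.
#' @param applyG convolve with the g kernel.
#' @param shiftMs shift toward later times (ms).
#' @param centerRadius,surroundRadius mask radii (um).
#' @return numeric trace at the movie frame rate.
#' @export
movieFeatureTrace <- function(movie, rf = c(0, 0),
                              kind = c("luminance_center",
                                       "center_minus_surround", "in_center"),
                              applyG = TRUE, shiftMs = 200,
                              centerRadius = 50, surroundRadius = 300) {
  kind <- match.arg(kind)
  d <- dim(movie@frames)
  px <- movie@pixelSize
  ext <- c(d[2], d[1]) * px / 2
  if (abs(rf[1]) > ext[1] || abs(rf[2]) > ext[2])
    stop("receptive field outside the movie")
  wc <- gaussianCenterMask(centerRadius, px, d[1:2], rf)
  tr <- switch(kind,
    luminance_center = maskTrace(movie, wc),
    center_minus_surround = {
      ws <- gaussianCenterMask(surroundRadius, px, d[1:2], rf,
                               sigma2 = 2 * pi * surroundRadius)
      maskTrace(movie, wc) - maskTrace(movie, ws)
    },
    in_center = {
      g <- pixelGrid(d[1], d[2], px)
      dx <- g$x - rf[1]; dy <- g$y - rf[2]
      ramp <- pmin(1, sqrt(dx^2 + dy^2) / centerRadius)
      mat <- matrix(movie@frames, d[1] * d[2], d[3])
      quadTr <- vapply(list(dx >= 0 & dy >= 0, dx >= 0 & dy < 0,
                            dx < 0 & dy >= 0, dx < 0 & dy < 0),
                       function(q) {
        wq <- wc * ramp * q
        s <- sum(wq)
        if (s == 0) rep(0, d[3])
        else as.numeric(matrix(wq, 1) %*% mat) / s
      }, numeric(d[3]))
      apply(quadTr, 1, stats::sd)
    })
  if (applyG) tr <- convolveSame(tr, gKernel(movie@frameRate))
  if (shiftMs != 0) tr <- shiftTrace(tr, round(shiftMs / 1000 * movie@frameRate))
  tr
}

# Align a movie-rate feature trace with a response trace by box-averaging
# into the response sampling bins.
alignToResponse <- function(trace, movieRate, R) {
  n <- length(trace)
  m <- length(R)
  if (n == m) return(trace)
  if (m > n)  # response sampled faster than the movie: interpolate
    return(stats::approx(seq_len(n) / n, trace, xout = seq_len(m) / m,
                         rule = 2)$y)
  idx <- pmin(m, ceiling(seq_len(n) * m / n))
  as.numeric(tapply(trace, factor(idx, levels = seq_len(m)), mean))
}

logCorrRatio <- function(num, den, R) {
  cn <- safeCor(num, R); cd <- safeCor(den, R)
  if (is.na(cn) || is.na(cd) || cn == 0 || cd == 0) {
    warning("zero correlation; sensitivity undefined")
    return(NA_real_)
  }
  log(cn^2 / cd^2)
}

#' Spatial contrast sensitivity
#'
#' S = log(Corr(g(S_c - S_s), R)^2 / Corr(g(S_c), R)^2): positive when the
#' response tracks center-minus-surround contrast better than local
#' luminance alone (natural log).
#'
#' @param movie a [StimulusMovie-class].
#' @param rf receptive-field center (x, y), um.
#' @param R response trace (any rate; feature traces are box-averaged onto
#'   its sampling grid).
#' @param shiftMs response-delay shift applied to the contrast traces (ms).
#' @return S; NA with a warning when either correlation vanishes.
#' @export
spatialContrastSensitivity <- function(movie, rf, R, shiftMs = 200) {
  cs <- movieFeatureTrace(movie, rf, "center_minus_surround", TRUE, shiftMs)
  lc <- movieFeatureTrace(movie, rf, "luminance_center", TRUE, shiftMs)
  logCorrRatio(alignToResponse(cs, movie@frameRate, R),
               alignToResponse(lc, movie@frameRate, R), R)
}

# Band-pass and low-pass temporal kernels: weighted sums of Gaussian
# membership functions on a 1 s window, discretized at `rate`.
temporalKernel <- function(rate, means, sds, weights, windowS = 1) {
  t <- seq(0, windowS, by = 1 / rate)
  k <- numeric(length(t))
  for (i in seq_along(means))
    k <- k + weights[i] * stats::dnorm(t, means[i], sds[i])
  k / rate  # quadrature scaling
}

bandPassKernel <- function(rate) {
  temporalKernel(rate, means = c(0.08, 0.12), sds = c(0.05, 0.12),
                 weights = c(1, -0.5))
}

lowPassKernel <- function(rate) {
  temporalKernel(rate, means = c(0.24, 0.30), sds = c(0.10, 0.24),
                 weights = c(1, -0.001))
}

#' Temporal contrast sensitivity
#'
#' T = log(Corr(g(f_b(S_c)), R)^2 / Corr(g(f_b(S_c) - f_l(S_c)), R)^2),
#' where f_b is a band-pass (difference-of-Gaussians: mean 0.08 s SD
#' 0.05 s weight 1; mean 0.12 s SD 0.12 s weight -0.5) and f_l a low-pass
#' kernel (mean 0.24 s SD 0.1 s weight 1; mean 0.3 s SD 0.24 s weight
#' -0.001), both on a 1 s window. Positive T: band-pass (transient)
#' temporal structure drives the response.
#'
#' @inheritParams spatialContrastSensitivity
#' @return T; NA with a warning when either correlation vanishes.
#' @export
temporalContrastSensitivity <- function(movie, rf, R, shiftMs = 200) {
  sc <- movieFeatureTrace(movie, rf, "luminance_center", applyG = FALSE,
                          shiftMs = 0)
  rate <- movie@frameRate
  fb <- convolveCausal(sc, bandPassKernel(rate))
  fl <- convolveCausal(sc, lowPassKernel(rate))
  g <- gKernel(rate)
  lag <- round(shiftMs / 1000 * rate)
  num <- shiftTrace(convolveSame(fb, g), lag)
  den <- shiftTrace(convolveSame(fb - fl, g), lag)
  logCorrRatio(alignToResponse(num, rate, R),
               alignToResponse(den, rate, R), R)
}

#' Horn-Schunck optical flow between two frames
#'
#' Classic iterative solution of the brightness-constancy plus global
#' smoothness objective; returns per-pixel 2-D flow (u along columns/x, v
#' along rows/y, in pixels per frame).
#'
#' @param frame1,frame2 numeric matrices of equal size.
#' @param alpha smoothness (regularization) parameter.
#' @param nIter iterations.
#' @return list with `u` and `v` matrices.
#' @export
hornSchunckFlow <- function(frame1, frame2, alpha = 3, nIter = 100) {
  stopifnot(all(dim(frame1) == dim(frame2)))
  # rescale jointly to a 0-255 intensity range so the conventional
  # smoothness values weight the data term as in 8-bit implementations
  rg <- range(frame1, frame2)
  if (diff(rg) > 0) {
    sc <- 255 / diff(rg)
    frame1 <- (frame1 - rg[1]) * sc
    frame2 <- (frame2 - rg[1]) * sc
  }
  nr <- nrow(frame1); nc <- ncol(frame1)
  shift <- function(m, dr, dc) {
    m[pmin(pmax(seq_len(nr) - dr, 1), nr),
      pmin(pmax(seq_len(nc) - dc, 1), nc)]
  }
  avg <- function(m) {
    (shift(m, -1, 0) + shift(m, 1, 0) + shift(m, 0, -1) + shift(m, 0, 1)) / 6 +
      (shift(m, -1, -1) + shift(m, -1, 1) + shift(m, 1, -1) +
         shift(m, 1, 1)) / 12
  }
  # Horn-Schunck derivative stencils (averaged over the two frames)
  Ex <- (shift(frame1, 0, -1) - frame1 + shift(frame2, 0, -1) - frame2 +
         shift(shift(frame1, -1, 0), 0, -1) - shift(frame1, -1, 0) +
         shift(shift(frame2, -1, 0), 0, -1) - shift(frame2, -1, 0)) / 4
  Ey <- (shift(frame1, -1, 0) - frame1 + shift(frame2, -1, 0) - frame2 +
         shift(shift(frame1, 0, -1), -1, 0) - shift(frame1, 0, -1) +
         shift(shift(frame2, 0, -1), -1, 0) - shift(frame2, 0, -1)) / 4
  Et <- (frame2 - frame1 + shift(frame2, 0, -1) - shift(frame1, 0, -1) +
         shift(frame2, -1, 0) - shift(frame1, -1, 0) +
         shift(shift(frame2, -1, 0), 0, -1) -
           shift(shift(frame1, -1, 0), 0, -1)) / 4
  u <- matrix(0, nr, nc); v <- matrix(0, nr, nc)
  denom <- alpha^2 + Ex^2 + Ey^2
  for (i in seq_len(nIter)) {
    ub <- avg(u); vb <- avg(v)
    t <- (Ex * ub + Ey * vb + Et) / denom
    u <- ub - Ex * t
    v <- vb - Ey * t
  }
  list(u = u, v = v)
}

# Coherent-motion statistic O_a - O_v per frame transition: mean vector
# magnitude minus the magnitude of the mean vector inside a binary disk
# mask. Zero for rigid coherent flow, positive for incoherent flow.
coherentMotionTrace <- function(movie, rf, maskDiameterUm = 200, alpha = 3,
                                nIter = 100, normalizeOv = TRUE) {
  d <- dim(movie@frames)
  g <- pixelGrid(d[1], d[2], movie@pixelSize)
  disk <- (g$x - rf[1])^2 + (g$y - rf[2])^2 <= (maskDiameterUm / 2)^2
  npx <- sum(disk)
  if (npx == 0) stop("motion mask does not cover any pixel")
  out <- numeric(d[3])
  for (f in 2:d[3]) {
    fl <- hornSchunckFlow(movie@frames[, , f - 1], movie@frames[, , f],
                          alpha, nIter)
    mag <- sqrt(fl$u[disk]^2 + fl$v[disk]^2)
    Oa <- mean(mag)
    sv <- c(sum(fl$u[disk]), sum(fl$v[disk]))
    Ov <- if (normalizeOv) sqrt(sum((sv / npx)^2)) else sqrt(sum(sv^2))
    out[f] <- Oa - Ov
  }
  out[1] <- out[2]
  out
}

#' Coherent motion sensitivity
#'
#' M = log(1 / Corr(g(O_a - O_v), R)^2), where O_a is the mean optical-flow
#' vector magnitude and O_v the magnitude of the mean flow vector within a
#' 200 um disk on the receptive field (Horn-Schunck flow, smoothness 3).
#' O_a - O_v vanishes for coherent rigid motion and grows with incoherent
#' local motion; small M means the response tracks this statistic closely.
#'
#' @inheritParams spatialContrastSensitivity
#' @param maskDiameterUm binary mask diameter (um).
#' @param alpha,nIter Horn-Schunck parameters.
#' @param normalizeOv use |mean vector| for O_v (dimensionally matched to
#'   O_a); FALSE uses the raw vector-sum magnitude.
#' @return M (natural log); +Inf with a warning when the correlation is 0.
#' @export
motionSensitivity <- function(movie, rf, R, shiftMs = 200,
                              maskDiameterUm = 200, alpha = 3, nIter = 100,
                              normalizeOv = TRUE) {
  tr <- coherentMotionTrace(movie, rf, maskDiameterUm, alpha, nIter,
                            normalizeOv)
  rate <- movie@frameRate
  lag <- round(shiftMs / 1000 * rate)
  feat <- shiftTrace(convolveSame(tr, gKernel(rate)), lag)
  r <- safeCor(alignToResponse(feat, rate, R), R)
  if (is.na(r) || r == 0) {
    warning("zero correlation; motion sensitivity infinite")
    return(Inf)
  }
  log(1 / r^2)
}

#' In-center contrast sensitivity
#'
#' Finds the blend weight beta maximizing
#' Corr(beta * g(S_cin) + (1 - beta) * g(S_c), R) by an exhaustive grid
#' search, and reports I = log10(beta) with beta floored at 1e-3. S_cin is
#' the in-center contrast (quadrant decomposition with a linear radial
#' ramp, see [movieFeatureTrace()]).
#'
#' @inheritParams spatialContrastSensitivity
#' @param betaStep grid resolution for beta in \[0, 1\].
#' @param betaFloor smallest reportable beta.
#' @return list with `I`, `beta`, `corr` and `atBoundary` (flag).
#' @export
inCenterContrastSensitivity <- function(movie, rf, R, shiftMs = 200,
                                        betaStep = 0.001, betaFloor = 1e-3) {
  gc <- alignToResponse(
    movieFeatureTrace(movie, rf, "luminance_center", TRUE, shiftMs),
    movie@frameRate, R)
  gi <- alignToResponse(
    movieFeatureTrace(movie, rf, "in_center", TRUE, shiftMs),
    movie@frameRate, R)
  betas <- seq(0, 1, by = betaStep)
  cors <- vapply(betas, function(b) {
    r <- safeCor(b * gi + (1 - b) * gc, R)
    if (is.na(r)) -Inf else r
  }, numeric(1))
  best <- which.max(cors)
  beta <- betas[best]
  atBoundary <- best == 1L || best == length(betas)
  list(I = log10(max(beta, betaFloor)), beta = beta, corr = cors[best],
       atBoundary = atBoundary)
}

#' Map a receptive field from checkerboard white noise
#'
#' Correlates the response with the g-filtered local luminance (Gaussian-
#' weighted disks) at a grid of candidate positions, then refines the
#' correlation-map peak by separable cubic-spline interpolation. Cells
#' whose peak squared correlation stays below `qualityFloor` are flagged.
#'
#' @param R response trace.
#' @param movie the checkerboard [StimulusMovie-class].
#' @param gridHalfUm half-extent of the search grid (um).
#' @param stepUm grid spacing (um).
#' @param diskUm correlation-disk diameter (um).
#' @param shiftMs response-delay shift (ms).
#' @param refineUm spline-refinement resolution (um).
#' @param qualityFloor minimum acceptable squared correlation.
#' @return list with `center` (x, y um), `quality` (max squared
#'   correlation), `map` (grid correlation matrix), `flagged`,
#'   `onBorder`.
#' @export
mapReceptiveField <- function(R, movie, gridHalfUm = 40, stepUm = 4,
                              diskUm = 80, shiftMs = 200, refineUm = 0.5,
                              qualityFloor = 0.1) {
  stopifnot(nrow(movie@log) >= 1)
  d <- dim(movie@frames)
  px <- movie@pixelSize
  xs <- seq(-gridHalfUm, gridHalfUm, by = stepUm)
  ys <- seq(-gridHalfUm, gridHalfUm, by = stepUm)
  mat <- matrix(movie@frames, d[1] * d[2], d[3])
  rate <- movie@frameRate
  g <- gKernel(rate)
  lag <- round(shiftMs / 1000 * rate)
  cmap <- matrix(NA_real_, length(ys), length(xs))
  for (ix in seq_along(xs)) {
    for (iy in seq_along(ys)) {
      w <- gaussianCenterMask(diskUm / 2, px, d[1:2], c(xs[ix], ys[iy]))
      tr <- as.numeric(matrix(w, 1) %*% mat) / sum(w)
      feat <- shiftTrace(convolveSame(tr, g), lag)
      r <- safeCor(alignToResponse(feat, rate, R), R)
      cmap[iy, ix] <- if (is.na(r)) 0 else r
    }
  }
  peak <- which(cmap == max(cmap), arr.ind = TRUE)[1, ]
  onBorder <- peak[1] %in% c(1, length(ys)) || peak[2] %in% c(1, length(xs))
  if (!onBorder) {
    fx <- seq(-gridHalfUm, gridHalfUm, by = refineUm)
    fy <- seq(-gridHalfUm, gridHalfUm, by = refineUm)
    fine <- t(vapply(seq_along(ys), function(iy)
      stats::spline(xs, cmap[iy, ], xout = fx)$y, numeric(length(fx))))
    fine2 <- vapply(seq_along(fx), function(ix)
      stats::spline(ys, fine[, ix], xout = fy)$y, numeric(length(fy)))
    pk <- which(fine2 == max(fine2), arr.ind = TRUE)[1, ]
    center <- c(fx[pk[2]], fy[pk[1]])
    quality <- max(fine2)^2
  } else {
    center <- c(xs[peak[2]], ys[peak[1]])
    quality <- cmap[peak[1], peak[2]]^2
  }
  list(center = center, quality = quality, map = cmap,
       flagged = quality < qualityFloor, onBorder = onBorder)
}

#' Explained variance of responses by local luminance
#'
#' R^2 between the (mean) response and the g-filtered, delay-shifted local
#' luminance, reported alongside the repeat-reliability ceiling (which the
#' luminance R^2 cannot meaningfully exceed).
#'
#' @param R matrix (repeats x samples) or a single trace.
#' @param movie the naturalistic [StimulusMovie-class].
#' @param rf receptive-field center (x, y), um.
#' @param shiftMs response-delay shift (ms).
#' @return list with `r2` and `ceiling` (NA for a single repeat).
#' @export
luminanceExplainedVariance <- function(R, movie, rf = c(0, 0),
                                       shiftMs = 200) {
  if (is.null(dim(R))) R <- matrix(R, nrow = 1)
  meanR <- colMeans(R)
  lum <- alignToResponse(
    movieFeatureTrace(movie, rf, "luminance_center", TRUE, shiftMs),
    movie@frameRate, meanR)
  r <- safeCor(lum, meanR)
  r2 <- if (is.na(r)) NA_real_ else r^2
  ceiling <- if (nrow(R) >= 2) repeatReliability(R) else NA_real_
  list(r2 = r2, ceiling = ceiling)
}

#' Spatial autocorrelation of a visual feature
#'
#' Computes the feature trace at a grid of receptive-field offsets and the
#' median inter-position correlation as a function of position distance
#' (2 um bins).
#'
#' @param movie a [StimulusMovie-class].
#' @param kind feature kind, see [movieFeatureTrace()].
#' @param gridHalfUm,stepUm offset grid geometry (um).
#' @param binWidthUm distance bin width (um).
#' @param shiftMs,applyG passed to [movieFeatureTrace()].
#' @return data.frame with `distance` (bin centers, um) and `medianCorr`;
#'   empty bins omitted.
#' @export
featureSpatialAutocorrelation <- function(movie, kind = "luminance_center",
                                          gridHalfUm = 40, stepUm = 4,
                                          binWidthUm = 2, applyG = TRUE,
                                          shiftMs = 200) {
  xs <- seq(-gridHalfUm, gridHalfUm, by = stepUm)
  pos <- expand.grid(x = xs, y = xs)
  traces <- vapply(seq_len(nrow(pos)), function(i)
    movieFeatureTrace(movie, c(pos$x[i], pos$y[i]), kind, applyG, shiftMs),
    numeric(dim(movie@frames)[3]))
  cm <- suppressWarnings(stats::cor(traces))
  dd <- as.matrix(stats::dist(pos))
  ut <- upper.tri(dd)
  bins <- floor(dd[ut] / binWidthUm)
  med <- tapply(cm[ut], bins, stats::median, na.rm = TRUE)
  data.frame(distance = (as.numeric(names(med)) + 0.5) * binWidthUm,
             medianCorr = as.numeric(med))
}

#' Visual-angle extent of a projected image
#'
#' Converts a pixel extent on the retina to degrees of visual angle
#' (32.5 um per degree on the mouse retina).
#'
#' @param pixels extent in pixels.
#' @param umPerPx microns per pixel.
#' @param umPerDeg microns per degree of visual angle.
#' @param roundDeg round to the nearest degree.
#' @return extent in degrees.
#' @export
visualAngleExtent <- function(pixels, umPerPx, umPerDeg = 32.5,
                              roundDeg = FALSE) {
  stopifnot(pixels > 0, umPerPx > 0, umPerDeg > 0)
  deg <- pixels * umPerPx / umPerDeg
  if (roundDeg) round(deg) else deg
}
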