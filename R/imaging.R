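# Preprocessing and segmentation of calcium image series: rigid
# registration, 3-D median filtering with an SD-based pixel mask,
# peak-seeded region growing into ROIs, epoching, repeat reliability and
# k-means/BIC consolidation of redundant ROIs.

# Integer circular shift of a matrix, then zero-fill the wrapped margin.
shiftFrame <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rSrc <- intersect(seq_len(nr) - dr, seq_len(nr))
  cSrc <- intersect(seq_len(nc) - dc, seq_len(nc))
  if (length(rSrc) && length(cSrc))
    out[rSrc + dr, cSrc + dc] <- m[rSrc, cSrc]
  out
}

#' Rigid (integer-translation) registration of an image series
#'
#' Estimates, per frame, the integer-pixel translation maximizing the
#' cross-correlation with a reference frame (computed in the Fourier
#' domain), and applies the correcting shift. The estimated shifts can be
#' re-applied to a paired channel via [applyShifts()].
#'
#' @param series an [ImageSeries-class] with >= 2 frames.
#' @param reference index of the reference frame.
#' @param maxShift search radius in pixels (default a quarter of the
#'   smaller image dimension).
#' @return list with `series` (registered [ImageSeries-class]) and
#'   `shifts` (frames x 2 matrix of applied (row, col) corrections).
#' @export
registerRigid <- function(series, reference = 1, maxShift = NULL) {
  stopifnot(methods::is(series, "ImageSeries"))
  d <- dim(series@data)
  if (d[3] < 2) stop("need at least 2 frames to register")
  if (is.null(maxShift)) maxShift <- floor(min(d[1:2]) / 4)
  ref <- series@data[, , reference]
  Fr <- stats::fft(ref - mean(ref))
  shifts <- matrix(0L, d[3], 2, dimnames = list(NULL, c("row", "col")))
  out <- series@data
  lagOf <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  for (f in seq_len(d[3])) {
    fr <- series@data[, , f]
    if (all(fr == fr[1])) {
      warning(sprintf("frame %d has no structure; shift set to 0", f))
      next
    }
    cc <- Re(stats::fft(Fr * Conj(stats::fft(fr - mean(fr))),
                        inverse = TRUE))
    rl <- lagOf(row(cc), d[1]); cl <- lagOf(col(cc), d[2])
    cc[abs(rl) > maxShift | abs(cl) > maxShift] <- -Inf
    k <- which.max(cc)
    dr <- lagOf((k - 1) %% d[1] + 1, d[1])
    dc <- lagOf((k - 1) %/% d[1] + 1, d[2])
    shifts[f, ] <- c(dr, dc)
    if (dr != 0 || dc != 0) out[, , f] <- shiftFrame(fr, dr, dc)
  }
  reg <- series
  reg@data <- out
  list(series = reg, shifts = shifts)
}

#' Apply per-frame integer shifts to a (paired-channel) series
#'
#' @param series an [ImageSeries-class].
#' @param shifts frames x 2 matrix of (row, col) shifts, as returned by
#'   [registerRigid()].
#' @return the shifted [ImageSeries-class].
#' @export
applyShifts <- function(series, shifts) {
  stopifnot(methods::is(series, "ImageSeries"),
            nrow(shifts) == dim(series@data)[3])
  out <- series@data
  for (f in seq_len(nrow(shifts)))
    if (any(shifts[f, ] != 0))
      out[, , f] <- shiftFrame(series@data[, , f], shifts[f, 1], shifts[f, 2])
  series@data <- out
  series
}

#' Registration quality control against axial drift
#'
#' Series with z-axis displacement cannot be fixed by in-plane translation;
#' their frames progressively decorrelate from the reference. This check
#' computes the per-frame correlation with the reference frame after
#' registration and flags the series when any frame falls below the floor.
#'
#' @param series a registered [ImageSeries-class].
#' @param reference reference frame index.
#' @param floor minimum acceptable frame-to-reference correlation.
#' @return list with `frameCorrelation` (per frame), `pass` (logical) and
#'   `worstFrame`.
#' @export
registrationQc <- function(series, reference = 1, floor = 0.5) {
  stopifnot(methods::is(series, "ImageSeries"))
  d <- dim(series@data)
  ref <- as.numeric(series@data[, , reference])
  cc <- vapply(seq_len(d[3]), function(f) {
    r <- safeCor(as.numeric(series@data[, , f]), ref)
    if (is.na(r)) 0 else r
  }, numeric(1))
  list(frameCorrelation = cc, pass = all(cc >= floor),
       worstFrame = which.min(cc))
}

#' Median-filter an image series and mask pixels by temporal variability
#'
#' Applies a 3 x 3 x 3 median filter (reflect padding) against acquisition
#' noise, then masks in the pixels whose temporal standard deviation lies in
#' the top `percentile` percent.
#'
#' @param series an [ImageSeries-class] with >= 3 frames.
#' @param percentile percent of pixels to retain (by temporal SD).
#' @return list with `series` (filtered), `mask` (logical matrix) and
#'   `sdImage` (temporal SD of the filtered series).
#' @export
preprocessSeries <- function(series, percentile = 75) {
  stopifnot(methods::is(series, "ImageSeries"))
  d <- dim(series@data)
  if (d[3] < 3) stop("need at least 3 frames")
  filt <- array(.median3d(as.numeric(series@data), as.integer(d)), dim = d)
  m <- matrix(filt, d[1] * d[2], d[3])
  sdImg <- matrix(apply(m, 1, stats::sd), d[1], d[2])
  if (all(sdImg == 0)) {
    warning("constant series: empty pixel mask")
    mask <- matrix(FALSE, d[1], d[2])
  } else {
    thr <- stats::quantile(sdImg, (100 - percentile) / 100)
    mask <- sdImg >= thr
  }
  out <- series
  out@data <- filt
  list(series = out, mask = mask, sdImage = sdImg)
}

# 12 nearest pixel offsets around a location (distance 1, sqrt 2 and 2).
.twelveNearest <- cbind(
  dr = c(-1, 1, 0, 0, -1, -1, 1, 1, -2, 2, 0, 0),
  dc = c(0, 0, -1, 1, -1, 1, -1, 1, 0, 0, -2, 2))

#' Segment an SD image into ROIs by peak-seeded region growing
#'
#' Local maxima of the temporal-SD image above a threshold become ROI
#' peaks; optional manual seeds are snapped to the peak position among
#' their 12 nearest pixels. Each above-threshold pixel is then assigned to
#' its nearest peak by geodesic (within-mask, 4-connected) distance, which
#' guarantees a continuous connection between every pixel and its peak;
#' equidistant pixels go to the lower peak index. Below-threshold pixels
#' are labeled 0 and excluded from analysis.
#'
#' @param sdImage numeric matrix (temporal SD per pixel).
#' @param threshold inclusion threshold; default the 75th percentile of all
#'   pixel values.
#' @param manualSeeds optional n x 2 matrix of (row, col) seed locations.
#' @param pixelSize microns per pixel (for ROI areas).
#' @return an [ROIMap-class].
#' @export
segmentRois <- function(sdImage, threshold = NULL, manualSeeds = NULL,
                        pixelSize = 1) {
  nr <- nrow(sdImage); nc <- ncol(sdImage)
  if (is.null(threshold)) threshold <- stats::quantile(sdImage, 0.75)
  mask <- sdImage >= threshold

  # strict local maxima over the 8-neighborhood, inside the mask
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sdImage
  isMax <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
    isMax <- isMax & (sdImage > nb | (sdImage == nb & (dr > 0 | (dr == 0 & dc > 0))))
  }
  peaks <- which(isMax, arr.ind = TRUE)

  if (!is.null(manualSeeds) && nrow(manualSeeds)) {
    for (i in seq_len(nrow(manualSeeds))) {
      rc <- round(manualSeeds[i, ])
      cand <- rbind(c(0L, 0L), .twelveNearest)
      cand <- cbind(rc[1] + cand[, 1], rc[2] + cand[, 2])
      cand <- cand[cand[, 1] >= 1 & cand[, 1] <= nr &
                   cand[, 2] >= 1 & cand[, 2] <= nc, , drop = FALSE]
      best <- cand[which.max(sdImage[cand]), ]
      if (!any(peaks[, 1] == best[1] & peaks[, 2] == best[2]))
        peaks <- rbind(peaks, matrix(best, 1, 2,
                                     dimnames = list(NULL, c("row", "col"))))
    }
  }
  if (!nrow(peaks)) {
    return(methods::new("ROIMap", labels = matrix(0L, nr, nc),
                        peaks = matrix(integer(), 0, 2), areas = numeric()))
  }
  peaks <- peaks[order(peaks[, 1], peaks[, 2]), , drop = FALSE]

  # synchronized multi-source BFS: label = peak whose geodesic wavefront
  # arrives first; simultaneous arrivals resolve to the lower peak index
  lab <- matrix(0L, nr, nc)
  lab[cbind(peaks[, 1], peaks[, 2])] <- seq_len(nrow(peaks))
  repeat {
    padL <- matrix(0L, nr + 2, nc + 2)
    padL[2:(nr + 1), 2:(nc + 1)] <- lab
    best <- matrix(Inf, nr, nc)
    for (off in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nb <- padL[2:(nr + 1) + off[1], 2:(nc + 1) + off[2]]
      nb[nb == 0L] <- Inf
      best <- pmin(best, nb)
    }
    newly <- mask & lab == 0L & is.finite(best)
    if (!any(newly)) break
    lab[newly] <- as.integer(best[newly])
  }
  counts <- tabulate(lab[lab > 0], nbins = nrow(peaks))
  methods::new("ROIMap", labels = lab,
               peaks = matrix(as.integer(peaks), ncol = 2,
                              dimnames = list(NULL, c("row", "col"))),
               areas = counts * pixelSize^2)
}

# Cut one trace into baseline-subtracted epochs per the stimulus log.
epochOneTrace <- function(trace, rate, stimLog, baselineS = 0.5,
                          subtractBaseline = TRUE, warnTruncate = TRUE) {
  t <- (seq_along(trace) - 0.5) / rate
  out <- NULL
  repIdx <- stats::ave(seq_len(nrow(stimLog)), stimLog$condition,
                       FUN = seq_along)
  for (i in seq_len(nrow(stimLog))) {
    on <- stimLog$onset[i]; off <- stimLog$offset[i]
    idx <- which(t >= on - baselineS & t < off)
    if (!length(idx)) next
    if (off > utils::tail(t, 1) + 0.5 / rate && warnTruncate)
      warning("epoch extends past series end; truncated")
    val <- trace[idx]
    tt <- t[idx] - on
    if (subtractBaseline) {
      b <- val[tt < 0]
      if (length(b)) val <- val - mean(b)
    }
    out <- rbind(out, data.frame(condition = stimLog$condition[i],
                                 rep = repIdx[i], time = tt, value = val))
  }
  out
}

#' Epoch a single response trace
#'
#' Convenience wrapper cutting one trace (e.g. a simulated cell response)
#' into baseline-subtracted epochs per the stimulus log, as
#' [extractEpochedTraces()] does for every ROI of an image series.
#'
#' @param trace numeric response trace.
#' @param rate sampling rate (Hz).
#' @param stimLog data.frame (condition, onset, offset), seconds.
#' @param baselineS baseline window before onset (s).
#' @param subtractBaseline subtract the pre-onset mean.
#' @return an [EpochedResponses-class] with a single ROI (id 1).
#' @export
epochTrace <- function(trace, rate, stimLog, baselineS = 0.5,
                       subtractBaseline = TRUE) {
  ep <- epochOneTrace(trace, rate, stimLog, baselineS, subtractBaseline)
  if (is.null(ep))
    ep <- data.frame(condition = character(), rep = integer(),
                     time = numeric(), value = numeric())
  methods::new("EpochedResponses", data = cbind(roi = 1L, ep),
               samplingRate = rate)
}

#' Extract epoched, baseline-subtracted ROI traces
#'
#' ROI traces are the per-frame means over each ROI's (masked) pixels; the
#' traces are cut per stimulus-log entry and the mean of the `baselineS`
#' seconds preceding onset is subtracted.
#'
#' @param series a registered, filtered [ImageSeries-class].
#' @param roiMap an [ROIMap-class].
#' @param stimLog data.frame (condition, onset, offset), seconds.
#' @param baselineS baseline window before onset (s).
#' @param mask optional logical matrix restricting eligible pixels.
#' @param subtractBaseline set FALSE for stimuli analyzed without baseline
#'   correction.
#' @return an [EpochedResponses-class].
#' @export
extractEpochedTraces <- function(series, roiMap, stimLog, baselineS = 0.5,
                                 mask = NULL, subtractBaseline = TRUE) {
  stopifnot(methods::is(series, "ImageSeries"), methods::is(roiMap, "ROIMap"))
  d <- dim(series@data)
  lab <- roiMap@labels
  if (!is.null(mask)) lab[!mask] <- 0L
  m <- matrix(series@data, d[1] * d[2], d[3])
  nRoi <- if (length(roiMap@peaks)) nrow(roiMap@peaks) else 0L
  all <- NULL
  for (r in seq_len(nRoi)) {
    px <- which(lab == r)
    if (!length(px)) next
    trace <- colMeans(m[px, , drop = FALSE])
    ep <- epochOneTrace(trace, series@frameRate, stimLog, baselineS,
                        subtractBaseline)
    if (!is.null(ep)) all <- rbind(all, cbind(roi = r, ep))
  }
  if (is.null(all))
    all <- data.frame(roi = integer(), condition = character(),
                      rep = integer(), time = numeric(), value = numeric())
  methods::new("EpochedResponses", data = all,
               samplingRate = series@frameRate)
}

#' Repeat reliability of a set of trials
#'
#' Median squared correlation between the mean traces of the two halves of
#' every balanced half-split of the trials (with an odd trial count the
#' halves differ by one trial). With two trials there is exactly one split.
#'
#' @param trials matrix (trials x samples) or list of equal-length traces.
#' @return median R^2 across splits; splits with a zero-variance
#'   half-average contribute 0 with a warning.
#' @export
repeatReliability <- function(trials) {
  if (is.list(trials)) trials <- do.call(rbind, trials)
  n <- nrow(trials)
  if (n < 2) stop("need at least 2 trials")
  h <- floor(n / 2)
  subsets <- utils::combn(n, h)
  if (n %% 2 == 0)  # each split appears twice (as a set and its complement)
    subsets <- subsets[, subsets[1, ] == 1, drop = FALSE]
  r2 <- apply(subsets, 2, function(s) {
    a <- colMeans(trials[s, , drop = FALSE])
    b <- colMeans(trials[-s, , drop = FALSE])
    r <- safeCor(a, b)
    if (is.na(r)) {
      warning("zero-variance half-average; split scored 0")
      0
    } else r^2
  })
  stats::median(r2)
}

#' Consolidate redundant ROIs by k-means clustering with BIC selection
#'
#' ROIs are clustered on their response correlations (k-means on row
#' z-scored traces, whose squared Euclidean metric is proportional to
#' correlation distance); the number of clusters minimizes
#' BIC = n ln(RSS / n) + k ln(n), where RSS is the summed correlation
#' distance of each ROI to its cluster centroid. ROIs sharing a cluster
#' (and imaging plane, when given) are merged by averaging their traces.
#'
#' @param responses matrix (ROIs x samples).
#' @param kMax largest cluster count considered (capped at the ROI count).
#' @param plane optional integer vector of imaging-plane ids; merging only
#'   occurs within a plane.
#' @param nstart k-means restarts.
#' @param seed seed for the k-means initialization.
#' @return list with `k`, `assignment`, `bic` (value per candidate k),
#'   `merged` (matrix of merged traces) and `mergedGroups` (list of member
#'   ROIs per merged trace).
#' @export
consolidateRois <- function(responses, kMax = 10, plane = NULL, nstart = 50,
                            seed = 1) {
  n <- nrow(responses)
  stopifnot(n >= 1)
  kMax <- min(kMax, n)
  if (n == 1 || stats::sd(as.numeric(responses)) == 0) {
    return(list(k = 1L, assignment = rep(1L, n), bic = NA_real_,
                merged = responses, mergedGroups = list(seq_len(n))))
  }
  z <- t(apply(responses, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  kMax <- min(kMax, nrow(unique(z)))
  bic <- rep(NA_real_, kMax)
  fits <- vector("list", kMax)
  for (k in seq_len(kMax)) {
    fit <- if (k == n) {
      list(cluster = seq_len(n), centers = z)  # every ROI its own cluster
    } else {
      withSeed(seed + k, stats::kmeans(z, centers = k, nstart = nstart,
                                       iter.max = 100))
    }
    rss <- sum(vapply(seq_len(n), function(i) {
      ctr <- fit$centers[fit$cluster[i], ]
      r <- safeCor(responses[i, ], ctr)
      if (is.na(r)) 1 else 1 - r
    }, numeric(1)))
    bic[k] <- n * log(max(rss, 1e-12) / n) + k * log(n)
    fits[[k]] <- fit
  }
  k <- which.min(bic)
  assignment <- fits[[k]]$cluster
  groupKey <- if (is.null(plane)) assignment
              else paste(assignment, plane, sep = "_")
  groups <- split(seq_len(n), groupKey)
  merged <- t(vapply(groups, function(g)
    colMeans(responses[g, , drop = FALSE]), numeric(ncol(responses))))
  list(k = as.integer(k), assignment = assignment, bic = bic,
       merged = merged, mergedGroups = unname(groups))
}
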