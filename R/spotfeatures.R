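# Spot-response statistics: surround strength, response transience, and the
# trial-based peak-amplitude analysis probing for regenerative (all-or-none)
# events.

#' Build a spot-response map from epoched responses
#'
#' Collects one ROI's ON-phase responses across spot sizes, averages over
#' repeats, and normalizes all traces to the single peak amplitude across
#' the full epochs (baseline subtraction having been applied upstream).
#'
#' @param epochs an [EpochedResponses-class] from a varying-size spot
#'   stimulus (conditions `spot_<size>_ON`).
#' @param roi ROI id to extract.
#' @return list with `sizes` (ascending, um), `time`, `mean` (sizes x
#'   samples matrix), `trials` (list of trials x samples matrices per
#'   size), `rate`; class `SpotResponseMap`.
#' @export
spotResponseMap <- function(epochs, roi = 1) {
  stopifnot(methods::is(epochs, "EpochedResponses"))
  d <- epochs@data
  d <- d[d$roi == roi & grepl("^spot_.*_ON$", d$condition), ]
  if (!nrow(d)) stop("no ON spot epochs for this ROI")
  sizes <- sort(unique(as.numeric(sub("^spot_([0-9.]+)_ON$", "\\1",
                                      d$condition))))
  # common time base: intersection of sample times across epochs
  rate <- epochs@samplingRate
  d$ti <- round(d$time * rate - 0.5)
  tIdx <- sort(Reduce(intersect, split(d$ti, paste(d$condition, d$rep))))
  time <- (tIdx + 0.5) / rate
  trials <- list()
  meanMat <- matrix(0, length(sizes), length(tIdx))
  for (i in seq_along(sizes)) {
    ds <- d[d$condition == sprintf("spot_%g_ON", sizes[i]), ]
    reps <- sort(unique(ds$rep))
    tr <- t(vapply(reps, function(r) {
      dr <- ds[ds$rep == r, ]
      dr$value[match(tIdx, dr$ti)]
    }, numeric(length(tIdx))))
    trials[[i]] <- tr
    meanMat[i, ] <- colMeans(tr)
  }
  peak <- max(abs(meanMat))
  if (peak > 0) {
    sgn <- sign(meanMat[which.max(abs(meanMat))])
    meanMat <- meanMat / (peak * sgn)
    trials <- lapply(trials, function(tr) tr / (peak * sgn))
  }
  structure(list(sizes = sizes, time = time, mean = meanMat,
                 trials = trials, rate = rate),
            class = "SpotResponseMap")
}

# Window-mean of the normalized mean traces over the requested sizes;
# missing sizes substitute the nearest available one with a warning.
windowMeanOverSizes <- function(map, sizes, t0, t1) {
  idx <- windowIndex(map$time, t0, t1)
  if (!length(idx)) stop("response window outside the epoch")
  vals <- vapply(sizes, function(s) {
    i <- which(map$sizes == s)
    if (!length(i)) {
      i <- which.min(abs(map$sizes - s))
      warning(sprintf("spot size %g um missing; using nearest (%g um)",
                      s, map$sizes[i]))
    }
    mean(map$mean[i, idx])
  }, numeric(1))
  mean(vals)
}

#' Surround strength of a spot-response map
#'
#' S = (r_c - r_s) / r_c, where r_c is the mean response to 50 and 100 um
#' spots (receptive-field center) and r_s the mean response to 600 and
#' 800 um spots (center plus surround), both averaged over the 0.34-1.54 s
#' window after spot onset. S = 0 means no surround suppression; S > 1
#' indicates response inversion for large spots.
#'
#' @param map a [spotResponseMap()].
#' @param centerSizes,surroundSizes spot diameters (um) entering r_c / r_s.
#' @param window response window \[t0, t1) in seconds after onset.
#' @return S; NA with a warning when r_c <= 0.
#' @export
surroundStrength <- function(map, centerSizes = c(50, 100),
                             surroundSizes = c(600, 800),
                             window = c(0.34, 1.54)) {
  rc <- windowMeanOverSizes(map, centerSizes, window[1], window[2])
  rs <- windowMeanOverSizes(map, surroundSizes, window[1], window[2])
  if (rc <= 0) {
    warning("center response r_c <= 0; surround strength undefined")
    return(NA_real_)
  }
  (rc - rs) / rc
}

#' Response transience of a spot-response map
#'
#' T = (r_e - r_l) / r_e, with r_e the early (0.23-0.67 s) and r_l the late
#' (1.21-1.65 s) window mean over 50, 100 and 200 um spots. T = 1 is fully
#' transient, T = 0 fully sustained.
#'
#' @param map a [spotResponseMap()].
#' @param sizes spot diameters (um) averaged over.
#' @param earlyWindow,lateWindow windows \[t0, t1) in seconds after onset.
#' @return T; NA with a warning when r_e <= 0.
#' @export
transience <- function(map, sizes = c(50, 100, 200),
                       earlyWindow = c(0.23, 0.67),
                       lateWindow = c(1.21, 1.65)) {
  re <- windowMeanOverSizes(map, sizes, earlyWindow[1], earlyWindow[2])
  rl <- windowMeanOverSizes(map, sizes, lateWindow[1], lateWindow[2])
  if (re <= 0) {
    warning("early response r_e <= 0; transience undefined")
    return(NA_real_)
  }
  (re - rl) / re
}

# Local maxima with a simple prominence criterion: height above the higher
# of the two flanking minima.
findPeaks <- function(x, minProminence = 0) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(diff(sign(diff(x))) < 0) + 1
  keep <- vapply(cand, function(i) {
    left <- min(x[1:i]); right <- min(x[i:n])
    x[i] - max(left, right) >= minProminence
  }, logical(1))
  cand[keep]
}

#' Score multimodality of an amplitude distribution
#'
#' Gaussian-mixture model comparison (1 vs up to `maxG` components) by BIC;
#' a clearly multimodal (all-or-none) amplitude distribution selects more
#' than one component.
#'
#' @param amps numeric amplitudes.
#' @param maxG largest number of mixture components considered.
#' @return list with `G` (selected components) and `bic` (per G).
#' @export
amplitudeMultimodality <- function(amps, maxG = 3) {
  b <- mclust::mclustBIC(amps, G = 1:maxG, modelNames = "V", verbose = FALSE)
  bic <- b[, 1]
  list(G = as.integer(which.max(bic)), bic = bic)
}

#' Trial-based peak amplitude analysis across spot sizes
#'
#' For each spot size whose repeat reliability clears the floor, detects
#' local maxima within the detection window of every ON trial (prominence
#' at least `promFactor` times the pre-stimulus noise SD) and pools the
#' peak amplitudes. A continuous (unimodal) amplitude distribution argues
#' for graded signaling; a multimodal one for all-or-none (spike) events.
#'
#' @param map a [spotResponseMap()].
#' @param sizes spot sizes (um) to include.
#' @param window detection window \[t0, t1) seconds after onset.
#' @param reliabilityFloor minimum repeat reliability (R^2) per size.
#' @param promFactor prominence threshold in pre-stimulus noise SDs.
#' @return list with `amplitudes` (pooled peak heights), `bySize`,
#'   `reliability` (per size), `excluded` (sizes dropped) and `nPeaks`.
#' @export
peakAmplitudeAnalysis <- function(map, sizes = c(20, 50, 100, 200, 400),
                                  window = c(0.1, 1.5),
                                  reliabilityFloor = 0.5, promFactor = 3) {
  stopifnot(inherits(map, "SpotResponseMap"))
  idx <- windowIndex(map$time, window[1], window[2])
  pre <- which(map$time < 0)
  amps <- list()
  rel <- c()
  excluded <- c()
  for (s in sizes) {
    i <- which(map$sizes == s)
    if (!length(i)) next
    tr <- map$trials[[i]]
    r <- repeatReliability(tr)
    rel[as.character(s)] <- r
    if (r < reliabilityFloor) {
      excluded <- c(excluded, s)
      next
    }
    noiseSd <- if (length(pre)) stats::sd(as.numeric(tr[, pre])) else 0
    pk <- lapply(seq_len(nrow(tr)), function(j) {
      x <- tr[j, idx]
      p <- findPeaks(x, minProminence = promFactor * noiseSd)
      x[p]
    })
    amps[[as.character(s)]] <- unlist(pk)
  }
  pooled <- unlist(amps, use.names = FALSE)
  if (!length(pooled))
    warning("no trials passed the reliability floor, or no peaks detected")
  list(amplitudes = pooled, bySize = amps, reliability = rel,
       excluded = excluded, nPeaks = length(pooled))
}
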