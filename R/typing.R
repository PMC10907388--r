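# Functional distances, permutation tests with FDR control, and the
# reference-based cell-type classifier combining a gamma-distribution
# functional likelihood with an IPL-depth prior, plus leave-one-out
# validation and combined-probability outlier exclusion.

#' Correlation distance between two response traces
#'
#' d = 1 - Pearson correlation, so d is 0 for identical shapes, 1 for
#' uncorrelated ones and 2 for sign-inverted ones.
#'
#' @param a,b equal-length numeric vectors with non-zero variance.
#' @return d in \[0, 2\]; NA with a warning on zero variance.
#' @export
correlationDistance <- function(a, b) {
  r <- safeCor(a, b)
  if (is.na(r)) {
    warning("zero-variance trace; correlation distance undefined")
    return(NA_real_)
  }
  1 - r
}

#' Pairwise correlation-distance matrix
#'
#' @param responses matrix (units x samples).
#' @return symmetric units x units matrix of 1 - correlation.
#' @export
correlationDistanceMatrix <- function(responses) {
  1 - stats::cor(t(responses))
}

#' Permutation test of pairwise group distances with BH adjustment
#'
#' For every pair of groups the observed distance (correlation distance
#' between the two group-mean responses) is compared with its distribution
#' under label exchange within the pair (Monte-Carlo, `nIter` iterations);
#' the two-sided p-value is the fraction of permuted distances at least as
#' far from the permutation mean as the observed one. P-values are adjusted
#' across pairs by the Benjamini-Hochberg procedure.
#'
#' @param responses matrix (units x samples).
#' @param labels group label per unit.
#' @param nIter Monte-Carlo iterations.
#' @param seed integer seed.
#' @param alternative `"two.sided"` (deviation from the permutation mean in
#'   either direction) or `"greater"` (observed distance larger than
#'   permuted).
#' @return data.frame with columns `groupA`, `groupB`, `distance`, `p`,
#'   `q` (BH-adjusted). Pairs involving a singleton group are skipped with
#'   a warning.
#' @export
permutationGroupDistance <- function(responses, labels, nIter = 5000,
                                     seed = 1,
                                     alternative = c("two.sided",
                                                     "greater")) {
  alternative <- match.arg(alternative)
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least 2 groups")
  res <- NULL
  withSeed(seed, {
    for (i in seq_along(groups)[-length(groups)]) {
      for (j in (i + 1):length(groups)) {
        ia <- which(labels == groups[i]); ib <- which(labels == groups[j])
        if (length(ia) < 2 || length(ib) < 2) {
          warning(sprintf("pair %s-%s skipped: group of size 1",
                          groups[i], groups[j]))
          next
        }
        dObs <- correlationDistance(colMeans(responses[ia, , drop = FALSE]),
                                    colMeans(responses[ib, , drop = FALSE]))
        both <- c(ia, ib)
        na <- length(ia)
        dPerm <- vapply(seq_len(nIter), function(k) {
          s <- sample(both)
          correlationDistance(
            colMeans(responses[s[seq_len(na)], , drop = FALSE]),
            colMeans(responses[s[-seq_len(na)], , drop = FALSE]))
        }, numeric(1))
        p <- if (alternative == "greater") {
          (1 + sum(dPerm >= dObs)) / (nIter + 1)
        } else {
          mu <- mean(dPerm)
          (1 + sum(abs(dPerm - mu) >= abs(dObs - mu))) / (nIter + 1)
        }
        res <- rbind(res, data.frame(groupA = groups[i], groupB = groups[j],
                                     distance = dObs, p = p))
      }
    }
  })
  if (is.null(res)) stop("no testable group pairs")
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Assemble a reference set of identified cells
#'
#' @param responses matrix (cells x samples) of epoched spot responses.
#' @param types type label per cell (>= 2 types).
#' @param depths IPL depth per cell, fraction in \[0, 1\].
#' @return list with `responses`, `types` (character), `depths`; class
#'   `ReferenceSet`.
#' @export
referenceSet <- function(responses, types, depths) {
  types <- as.character(types)
  stopifnot(nrow(responses) == length(types),
            length(types) == length(depths),
            length(unique(types)) >= 2,
            all(depths >= 0 & depths <= 1))
  structure(list(responses = responses, types = types, depths = depths),
            class = "ReferenceSet")
}

#' Per-type IPL depth profiles
#'
#' Normalizes per-type axon density profiles over IPL depth so that at
#' every depth the probabilities across types sum to one (a depth prior for
#' classification). Profiles may be smoothed by a centered moving average.
#'
#' @param density matrix (depth grid x types) of non-negative densities.
#' @param depths depth grid, fractions of the IPL in \[0, 1\].
#' @param types type labels (column names).
#' @param smoothPoints moving-average window (samples); 0 or 1 disables.
#' @return list with `prob` (row-normalized matrix), `density`, `depths`,
#'   `types`; class `DepthProfiles`.
#' @export
depthProfiles <- function(density, depths, types = colnames(density),
                          smoothPoints = 21) {
  density <- as.matrix(density)
  stopifnot(nrow(density) == length(depths), all(density >= 0))
  if (is.null(types)) types <- paste0("type", seq_len(ncol(density)))
  if (smoothPoints > 1) {
    k <- rep(1 / smoothPoints, smoothPoints)
    density <- apply(density, 2, function(x) {
      xp <- c(rep(x[1], smoothPoints), x, rep(x[length(x)], smoothPoints))
      convolveSame(xp, k)[(smoothPoints + 1):(smoothPoints + length(x))]
    })
  }
  rs <- rowSums(density)
  prob <- density / ifelse(rs > 0, rs, 1)
  structure(list(prob = prob, density = density, depths = depths,
                 types = types), class = "DepthProfiles")
}

#' Synthetic per-type IPL depth profiles
#'
#' Gaussian stratification bumps centered on each type's depth from
#' [defaultCellTypes()]; a synthetic stand-in for connectomic skeleton
#' densities.
#'
#' @param sd bump SD in IPL-depth units.
#' @param nGrid depth-grid resolution.
#' @param smoothPoints see [depthProfiles()].
#' @return a [depthProfiles()] object.
#' @export
makeSyntheticDepthProfiles <- function(sd = 0.05, nGrid = 101,
                                       smoothPoints = 21) {
  ct <- defaultCellTypes()
  depths <- seq(0, 1, length.out = nGrid)
  dens <- vapply(ct$iplDepth, function(mu) stats::dnorm(depths, mu, sd),
                 numeric(nGrid))
  colnames(dens) <- ct$typeLabel
  depthProfiles(dens, depths, ct$typeLabel, smoothPoints)
}

# Functional distance of a response to a type: median correlation distance
# to that type's exemplars (robust variant of the nearest-exemplar rule).
typeDistance <- function(response, reference, type,
                         rule = c("median", "nearest"), exclude = integer()) {
  rule <- match.arg(rule)
  idx <- setdiff(which(reference$types == type), exclude)
  d <- vapply(idx, function(i)
    correlationDistance(response, reference$responses[i, ]), numeric(1))
  if (rule == "median") stats::median(d, na.rm = TRUE)
  else min(d, na.rm = TRUE)
}

#' Fit the gamma probability metric for functional distances
#'
#' Collects, for every reference cell, its functional distance to the
#' nearest type (computed against the remaining cells), fits a gamma
#' distribution by maximum likelihood, and returns a scorer translating a
#' distance into a probability via the gamma survival function (distance 0
#' maps to probability 1; larger distances to smaller probabilities).
#'
#' @param reference a [referenceSet()].
#' @param rule exemplar-aggregation rule, see Details of [classifyRoi()].
#' @return list with `shape`, `rate`, `scorer` (function distance ->
#'   probability) and the fitted `distances`.
#' @export
fitFunctionalProbability <- function(reference, rule = "median") {
  n <- nrow(reference$responses)
  types <- unique(reference$types)
  d <- vapply(seq_len(n), function(i) {
    min(vapply(types, function(tp)
      typeDistance(reference$responses[i, ], reference, tp,
                   rule = rule, exclude = i), numeric(1)), na.rm = TRUE)
  }, numeric(1))
  d <- d[is.finite(d) & d > 0]
  if (length(d) < 4)
    stop("too few positive distances to fit the gamma model")
  if (length(d) < 20)
    warning("fewer than 20 distances; gamma fit may be unstable")
  fit <- MASS::fitdistr(d, "gamma")
  shape <- fit$estimate[["shape"]]
  rate <- fit$estimate[["rate"]]
  scorer <- function(distance)
    stats::pgamma(pmax(distance, 0), shape = shape, rate = rate,
                  lower.tail = FALSE)
  list(shape = shape, rate = rate, scorer = scorer, distances = d)
}

# Depth prior for one depth across types; depths outside the grid use the
# nearest defined depth with a warning.
depthProbability <- function(profiles, depth) {
  if (depth < min(profiles$depths) || depth > max(profiles$depths)) {
    warning("depth outside profile support; using nearest defined depth")
    depth <- max(min(depth, max(profiles$depths)), min(profiles$depths))
  }
  i <- which.min(abs(profiles$depths - depth))
  p <- profiles$prob[i, ]
  names(p) <- profiles$types
  p
}

#' Classify one ROI by combined functional and depth probability
#'
#' For each candidate type the functional probability (gamma survival of
#' the functional distance to that type) is multiplied by the depth prior
#' at the ROI's IPL depth; the ROI is assigned the arg-max type. Ties break
#' deterministically to the lower type index (flagged).
#'
#' @param response the ROI's epoched spot-response vector.
#' @param depth the ROI's IPL depth in \[0, 1\].
#' @param reference a [referenceSet()].
#' @param profiles a [depthProfiles()]; ignored when `useDepth = FALSE`.
#' @param scorer scorer from [fitFunctionalProbability()].
#' @param useDepth include the depth prior.
#' @param rule "median" (default) scores a type by the median correlation
#'   distance to its exemplars; "nearest" uses the minimum.
#' @return data.frame row: `type`, `funcProb`, `depthProb`,
#'   `combinedProb`, `tie`.
#' @export
classifyRoi <- function(response, depth, reference, profiles = NULL,
                        scorer, useDepth = TRUE, rule = "median") {
  types <- unique(reference$types)
  dFun <- vapply(types, function(tp)
    typeDistance(response, reference, tp, rule = rule), numeric(1))
  pFun <- scorer(dFun)
  pDepth <- if (useDepth) {
    dp <- depthProbability(profiles, depth)
    dp[match(types, names(dp))]
  } else rep(1, length(types))
  comb <- pFun * pDepth
  best <- which(comb == max(comb))
  tie <- length(best) > 1
  best <- best[1]
  data.frame(type = types[best], funcProb = pFun[best],
             depthProb = unname(pDepth[best]), combinedProb = comb[best],
             tie = tie, stringsAsFactors = FALSE)
}

#' Classify a batch of ROIs and flag outliers
#'
#' Applies [classifyRoi()] to each ROI, then fits a gamma distribution to
#' the combined probabilities and flags ROIs in its lower
#' `outlierQuantile` tail as outliers (no type assigned), excluding
#' poorly matching ROIs from augmentation.
#'
#' @param responses matrix (ROIs x samples).
#' @param depths IPL depth per ROI.
#' @param reference a [referenceSet()].
#' @param profiles a [depthProfiles()].
#' @param useDepth include the depth prior.
#' @param rule see [classifyRoi()].
#' @param outlierQuantile lower tail of the fitted gamma treated as
#'   outlying.
#' @return data.frame with one row per ROI: assignment columns plus
#'   `outlier`.
#' @export
classifyRois <- function(responses, depths, reference, profiles = NULL,
                         useDepth = TRUE, rule = "median",
                         outlierQuantile = 0.05) {
  fit <- fitFunctionalProbability(reference, rule = rule)
  out <- do.call(rbind, lapply(seq_len(nrow(responses)), function(i)
    classifyRoi(responses[i, ], depths[i], reference, profiles,
                fit$scorer, useDepth, rule)))
  cp <- out$combinedProb
  pos <- cp[cp > 0]
  out$outlier <- FALSE
  if (length(pos) >= 20) {
    gfit <- try(MASS::fitdistr(pos, "gamma"), silent = TRUE)
    if (!inherits(gfit, "try-error")) {
      cut <- stats::qgamma(outlierQuantile,
                           shape = gfit$estimate[["shape"]],
                           rate = gfit$estimate[["rate"]])
      out$outlier <- cp < cut
    }
  }
  out$type[out$outlier] <- NA_character_
  out
}

#' Leave-one-out validation of the type classifier
#'
#' Each reference cell is classified against the remaining cells (types
#' with a single exemplar are excluded with a warning); reports the
#' confusion matrix and per-type accuracy, with or without the depth
#' prior.
#'
#' @param reference a [referenceSet()].
#' @param profiles a [depthProfiles()].
#' @param useDepth include the depth prior.
#' @param rule see [classifyRoi()].
#' @return list with `confusion` (true x assigned counts), `accuracy`
#'   (per type), `overall`.
#' @export
looValidate <- function(reference, profiles = NULL, useDepth = TRUE,
                        rule = "median") {
  counts <- table(reference$types)
  keepTypes <- names(counts)[counts >= 2]
  if (length(keepTypes) < length(counts))
    warning("types with a single exemplar excluded from leave-one-out")
  keep <- which(reference$types %in% keepTypes)
  types <- sort(unique(reference$types[keep]))
  pred <- character(length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    rest <- referenceSet(reference$responses[-i, , drop = FALSE],
                         reference$types[-i], reference$depths[-i])
    fit <- fitFunctionalProbability(rest, rule = rule)
    pred[k] <- classifyRoi(reference$responses[i, ], reference$depths[i],
                           rest, profiles, fit$scorer, useDepth, rule)$type
  }
  truth <- reference$types[keep]
  confusion <- table(factor(truth, levels = types),
                     factor(pred, levels = types))
  acc <- diag(confusion) / rowSums(confusion)
  list(confusion = confusion, accuracy = acc,
       overall = mean(pred == truth))
}

#' Pairwise correlation of IPL stratification profiles
#'
#' Pearson correlation between per-type stratification profiles on a
#' shared depth grid, summarized as within- versus between-block mean
#' correlation when a block assignment is given.
#'
#' @param density matrix (depth grid x types).
#' @param blocks optional block label per type.
#' @return list with `corMatrix` and, when blocks are given,
#'   `withinMean` and `betweenMean`. Flat profiles are flagged NA.
#' @export
stratificationBlockAnalysis <- function(density, blocks = NULL) {
  flat <- apply(density, 2, stats::sd) == 0
  if (any(flat)) warning("flat stratification profile(s) flagged NA")
  cm <- suppressWarnings(stats::cor(density))
  cm[flat, ] <- NA; cm[, flat] <- NA
  out <- list(corMatrix = cm)
  if (!is.null(blocks)) {
    same <- outer(blocks, blocks, "==")
    ut <- upper.tri(cm)
    out$withinMean <- mean(cm[ut & same], na.rm = TRUE)
    out$betweenMean <- mean(cm[ut & !same], na.rm = TRUE)
  }
  out
}
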