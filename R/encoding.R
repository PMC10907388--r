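# Population encoding space: masked correlation-distance matrices, weighted
# nonmetric MDS (SMACOF majorization with isotonic regression), explained
# variance per coordinate, Jensen-Shannon batch-effect testing, and
# feature-axis angular analysis.

#' Masked pairwise correlation-distance matrix
#'
#' Computes 1 - correlation between all unit pairs and builds a binary
#' weight mask: any distance deviating by more than `nSd` standard
#' deviations from the mean of all pairwise distances receives zero weight
#' (and is ignored by the embedding and R^2 computations). Zero-variance
#' units are dropped with a warning.
#'
#' @param responses matrix (units x samples), >= 3 units.
#' @param nSd masking threshold in SDs.
#' @return list with `d` (distance matrix), `w` (binary weight matrix,
#'   zero diagonal), `maskedFraction`, `kept` (row indices used); class
#'   `DistanceMatrix`.
#' @export
maskedDistanceMatrix <- function(responses, nSd = 3) {
  v <- apply(responses, 1, stats::sd)
  kept <- which(v > 0)
  if (length(kept) < nrow(responses))
    warning(sprintf("%d zero-variance unit(s) dropped",
                    nrow(responses) - length(kept)))
  if (length(kept) < 3) stop("need at least 3 units with variance")
  d <- correlationDistanceMatrix(responses[kept, , drop = FALSE])
  ut <- upper.tri(d)
  mu <- mean(d[ut]); s <- stats::sd(d[ut])
  w <- matrix(1, nrow(d), ncol(d))
  if (s > 0) w[abs(d - mu) > nSd * s] <- 0
  w <- w * t(w)  # symmetry (d is symmetric, so this is a no-op safeguard)
  diag(w) <- 0
  structure(list(d = d, w = w, maskedFraction = mean(w[ut] == 0),
                 kept = kept), class = "DistanceMatrix")
}

#' Triangle-inequality violation rate of a distance matrix
#'
#' Fraction of unit pairs whose distance exceeds some two-leg path through
#' a third unit (correlation distances need not be metric; the nonmetric
#' embedding tolerates this, but the rate is worth logging).
#'
#' @param d symmetric distance matrix.
#' @return fraction of pairs violating the triangle inequality.
#' @export
triangleViolationRate <- function(d) {
  n <- nrow(d)
  viol <- matrix(FALSE, n, n)
  for (k in seq_len(n))
    viol <- viol | d > outer(d[, k], d[k, ], "+") + 1e-12
  mean(viol[upper.tri(viol)])
}

# Guttman transform machinery for binary-weighted SMACOF.
smacofFit <- function(delta, w, X0, maxIter, tol = 1e-6) {
  n <- nrow(X0)
  pairs <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  dl <- delta[pairs]
  ord <- order(dl)
  W <- w
  V <- diag(rowSums(W)) - W
  Vp <- solve(V + 1 / n) - 1 / n
  X <- X0
  confDist <- function(X) {
    dx <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
    sqrt(rowSums(dx^2))
  }
  stress <- Inf
  for (it in seq_len(maxIter)) {
    dv <- confDist(X)
    fit <- stats::isoreg(dv[ord])$yf
    dhat <- numeric(length(dv))
    dhat[ord] <- fit
    num <- sum((dv - dhat)^2)
    den <- sum(dv^2)
    newStress <- sqrt(num / max(den, 1e-300))
    # Guttman transform with target disparities dhat
    B <- matrix(0, n, n)
    ratio <- ifelse(dv > 1e-12, dhat / dv, 0)
    B[pairs] <- -ratio
    B[pairs[, c(2, 1), drop = FALSE]] <- -ratio
    diag(B) <- -rowSums(B)
    Xn <- Vp %*% (B %*% X)
    if (is.finite(stress) && stress - newStress < tol && it > 1) {
      X <- Xn; stress <- newStress
      return(list(X = X, stress = stress, iter = it, converged = TRUE))
    }
    X <- Xn
    stress <- newStress
  }
  list(X = X, stress = stress, iter = maxIter, converged = FALSE)
}

#' Weighted nonmetric multidimensional scaling
#'
#' Embeds a masked distance matrix into `dims` dimensions by nonmetric
#' SMACOF: alternating monotone (isotonic) regression of configuration
#' distances on the rank-ordered dissimilarities and Guttman-transform
#' updates, with zero-weight pairs excluded from both. Initialized from
#' classical MDS plus random restarts (best final stress kept), and the
#' returned coordinates are reordered by single-coordinate explained
#' variance.
#'
#' @param D a [maskedDistanceMatrix()] (or a plain symmetric matrix, which
#'   is used unmasked).
#' @param dims embedding dimensionality.
#' @param maxIter iteration cap per restart; non-convergence returns the
#'   final configuration with a warning.
#' @param nRestarts random restarts in addition to the classical-MDS start.
#' @param seed integer seed.
#' @return an [EncodingSpace-class].
#' @export
nonmetricMds <- function(D, dims = 16, maxIter = 2000, nRestarts = 4,
                         seed = 1) {
  if (!inherits(D, "DistanceMatrix")) {
    d <- as.matrix(D)
    w <- matrix(1, nrow(d), ncol(d)); diag(w) <- 0
    D <- structure(list(d = d, w = w, maskedFraction = 0,
                        kept = seq_len(nrow(d))), class = "DistanceMatrix")
  }
  n <- nrow(D$d)
  dims <- min(dims, n - 1)
  inits <- list()
  cm <- try(stats::cmdscale(D$d, k = dims), silent = TRUE)
  if (!inherits(cm, "try-error") && ncol(cm) == dims) inits[[1]] <- cm
  withSeed(seed, {
    for (r in seq_len(nRestarts))
      inits[[length(inits) + 1]] <- matrix(stats::rnorm(n * dims), n, dims)
  })
  best <- NULL
  for (X0 in inits) {
    fit <- smacofFit(D$d, D$w, X0, maxIter)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (!best$converged)
    warning(sprintf("MDS did not converge in %d iterations (stress %.4g)",
                    maxIter, best$stress))
  X <- best$X
  r2 <- vapply(seq_len(dims), function(j)
    coordinateExplainedVariance(D, X, j), numeric(1))
  o <- order(r2, decreasing = TRUE)
  methods::new("EncodingSpace", coords = X[, o, drop = FALSE],
               stress = best$stress, explainedR2 = r2[o])
}

#' Explained variance of a coordinate subset
#'
#' Squared correlation between the (masked) response distances and the
#' Euclidean distances computed from the selected embedding coordinates;
#' masked pairs are excluded from both.
#'
#' @param D a [maskedDistanceMatrix()] or plain distance matrix.
#' @param coords embedding coordinates (units x dims).
#' @param subset coordinate indices to use.
#' @return R^2.
#' @export
coordinateExplainedVariance <- function(D, coords, subset) {
  if (!inherits(D, "DistanceMatrix")) {
    d <- as.matrix(D)
    w <- matrix(1, nrow(d), ncol(d)); diag(w) <- 0
    D <- list(d = d, w = w)
  }
  stopifnot(length(subset) >= 1)
  dd <- as.matrix(stats::dist(coords[, subset, drop = FALSE]))
  sel <- upper.tri(D$d) & D$w > 0
  if (!any(sel)) stop("all pairs masked; explained variance undefined")
  r <- safeCor(D$d[sel], dd[sel])
  if (is.na(r)) return(NA_real_)
  r^2
}

#' Jensen-Shannon divergence between two 2-D point sets
#'
#' Kernel density estimates of both sets on a shared grid (bandwidth by a
#' normal-reference rule on the pooled points), then the discrete JSD
#' JSD(P||Q) = KL(P||M)/2 + KL(Q||M)/2 with M = (P+Q)/2, natural
#' logarithm. Bounded by \[0, ln 2\].
#'
#' @param A,B matrices (points x 2), >= 5 points each.
#' @param bandwidth optional c(hx, hy); default normal-reference rule on
#'   the pooled points.
#' @param gridN grid resolution per axis.
#' @return the JSD (nats).
#' @export
jsd2d <- function(A, B, bandwidth = NULL, gridN = 101) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == 2, ncol(B) == 2, nrow(A) >= 5, nrow(B) >= 5)
  pool <- rbind(A, B)
  if (any(apply(A, 2, stats::sd) == 0) && any(apply(B, 2, stats::sd) == 0) &&
      all(apply(pool, 2, stats::sd) == 0))
    stop("degenerate (all-identical) point sets")
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(pool[, 1]),
                   MASS::bandwidth.nrd(pool[, 2]))
    if (any(bandwidth <= 0)) stop("degenerate point set: zero bandwidth")
  }
  lims <- c(range(pool[, 1]) + c(-1, 1) * bandwidth[1],
            range(pool[, 2]) + c(-1, 1) * bandwidth[2])
  kP <- MASS::kde2d(A[, 1], A[, 2], h = bandwidth, n = gridN, lims = lims)
  kQ <- MASS::kde2d(B[, 1], B[, 2], h = bandwidth, n = gridN, lims = lims)
  P <- kP$z / sum(kP$z)
  Q <- kQ$z / sum(kQ$z)
  M <- (P + Q) / 2
  kl <- function(p, m) {
    i <- p > 0
    sum(p[i] * log(p[i] / m[i]))
  }
  0.5 * kl(P, M) + 0.5 * kl(Q, M)
}

#' Batch-effect test on the encoding space via JSD
#'
#' Compares the JSD between point sets split along recording-batch
#' membership with the JSD between random splits of the pooled points.
#' The p-value is the one-sided fraction of random-split JSDs at least as
#' large as the median batch-split JSD; a large p is consistent with the
#' null hypothesis that batch effects did not shape the distribution.
#'
#' @param coords matrix (points x 2), typically the first two principal
#'   coordinates.
#' @param batchLabels recording-batch label per point (>= 4 batches).
#' @param nBatchSplits combinations of batch memberships sampled.
#' @param nRandom random resamples of all points.
#' @param gridN KDE grid resolution passed to [jsd2d()].
#' @param seed integer seed.
#' @return list with `p`, `batchJSD`, `randomJSD`, `medianBatchJSD`.
#' @export
batchEffectTest <- function(coords, batchLabels, nBatchSplits = 2000,
                            nRandom = 20000, gridN = 51, seed = 1) {
  coords <- as.matrix(coords)
  batches <- unique(batchLabels)
  if (length(batches) < 4) stop("need at least 4 batches")
  withSeed(seed, {
    bw <- c(MASS::bandwidth.nrd(coords[, 1]), MASS::bandwidth.nrd(coords[, 2]))
    splitSizes <- integer(nBatchSplits)
    batchJSD <- numeric(nBatchSplits)
    for (i in seq_len(nBatchSplits)) {
      # resample splits that empty (or nearly empty) one side
      repeat {
        side <- stats::runif(length(batches)) < 0.5
        if (!any(side) || all(side)) next
        ia <- which(batchLabels %in% batches[side])
        if (length(ia) >= 5 && nrow(coords) - length(ia) >= 5) break
      }
      splitSizes[i] <- length(ia)
      batchJSD[i] <- jsd2d(coords[ia, , drop = FALSE],
                           coords[-ia, , drop = FALSE],
                           bandwidth = bw, gridN = gridN)
    }
    randomJSD <- numeric(nRandom)
    n <- nrow(coords)
    for (i in seq_len(nRandom)) {
      sz <- splitSizes[sample.int(nBatchSplits, 1)]
      ia <- sample.int(n, sz)
      randomJSD[i] <- jsd2d(coords[ia, , drop = FALSE],
                            coords[-ia, , drop = FALSE],
                            bandwidth = bw, gridN = gridN)
    }
    med <- stats::median(batchJSD)
    list(p = mean(randomJSD >= med), batchJSD = batchJSD,
         randomJSD = randomJSD, medianBatchJSD = med)
  })
}

#' Feature-encoding axis in the embedding
#'
#' The vector (1/n) * sum over ordered unit pairs (i, j) of
#' (w_i - w_j) (v_i - v_j), where v are embedding coordinates and w the
#' feature values: the direction along which the feature organizes the
#' encoding space.
#'
#' @param coords matrix (units x dims), typically the first 3 principal
#'   coordinates.
#' @param feature numeric feature value per unit.
#' @return the axis vector (length = ncol(coords)); the zero vector with a
#'   warning for a constant feature.
#' @export
featureAxis <- function(coords, feature) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(feature), all(is.finite(feature)))
  n <- nrow(coords)
  if (stats::sd(feature) == 0) {
    warning("constant feature: zero axis vector")
    return(numeric(ncol(coords)))
  }
  2 * (n * colSums(coords * feature) - sum(feature) * colSums(coords)) / n
}

#' Angle between two vectors
#'
#' theta = acos(a . b / (|a| |b|)), reported in degrees in \[0, 180\].
#'
#' @param a,b non-zero numeric vectors of equal length.
#' @return angle in degrees; NA with a warning for a zero vector.
#' @export
vectorAngle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("zero vector: angle undefined")
    return(NA_real_)
  }
  acos(pmin(1, pmax(-1, sum(a * b) / (na * nb)))) * 180 / pi
}

#' Angular spread of feature axes over pair subsamples
#'
#' Recomputes the feature axis from `nIter` random subsamples of `nPairs`
#' unit pairs and measures each subsample axis's angle to the full-data
#' axis; a concentrated distribution (most angles within 20 degrees) means
#' the feature robustly organizes the space.
#'
#' @param coords embedding coordinates (units x dims).
#' @param feature feature value per unit.
#' @param nPairs pairs per subsample (capped at the available pair count
#'   with a warning).
#' @param nIter subsamples.
#' @param seed integer seed.
#' @return list with `angles` (degrees per subsample), `fracWithin20` and
#'   `fullAxis`.
#' @export
angleSubsampleDistribution <- function(coords, feature, nPairs = 90,
                                       nIter = 1000, seed = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (nPairs > nrow(pairs)) {
    warning("nPairs exceeds available pairs; capped")
    nPairs <- nrow(pairs)
  }
  full <- featureAxis(coords, feature)
  withSeed(seed, {
    angles <- vapply(seq_len(nIter), function(k) {
      s <- pairs[sample.int(nrow(pairs), nPairs), , drop = FALSE]
      dv <- coords[s[, 1], , drop = FALSE] - coords[s[, 2], , drop = FALSE]
      dw <- feature[s[, 1]] - feature[s[, 2]]
      vectorAngle(colSums(dv * dw), full)
    }, numeric(1))
    list(angles = angles, fracWithin20 = mean(angles <= 20, na.rm = TRUE),
         fullAxis = full)
  })
}
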