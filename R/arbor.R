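# Axon-arbor analysis: linking ROIs to skeletons, path distances along the
# arbor, paired response consistencies, and length-constant estimation.

#' Link ROI centroids to their nearest skeleton points
#'
#' Each centroid is attached to its nearest point on the skeleton, with
#' candidate points sampled along every edge in 0.1 um increments, and a
#' weighted graph is built containing the skeleton, the attachment points
#' (splitting their edges, in order, when several attach to one edge) and
#' the ROI nodes (link edge = centroid-to-skeleton distance).
#'
#' @param centroids matrix (n x 3) of ROI centroids (um).
#' @param arbor an [ArborModel-class], or a list with `nodes` (m x 3) and
#'   `edges` (e x 2).
#' @param stepUm sampling increment along edges (um).
#' @return list with `graph` (weighted igraph), `roiVertices` (vertex ids
#'   of the ROIs), `linkLengths` (um); class `PathGraph`.
#' @export
linkRoisToSkeleton <- function(centroids, arbor, stepUm = 0.1) {
  nodes <- if (methods::is(arbor, "ArborModel")) arbor@nodes else arbor$nodes
  edges <- if (methods::is(arbor, "ArborModel")) arbor@edges else arbor$edges
  centroids <- matrix(as.numeric(centroids), ncol = 3)
  nE <- nrow(edges)
  g0 <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g0 <- igraph::add_edges(g0, t(edges))
  comps <- igraph::components(g0)
  if (comps$no > 1)
    stop(sprintf("skeleton is disconnected (%d components of sizes %s)",
                 comps$no, paste(comps$csize, collapse = ", ")))
  # nearest sampled point on any edge, per centroid
  nearest <- data.frame(edge = integer(nrow(centroids)),
                        s = numeric(nrow(centroids)),
                        dist = rep(Inf, nrow(centroids)))
  edgeLen <- numeric(nE)
  for (e in seq_len(nE)) {
    a <- nodes[edges[e, 1], ]; b <- nodes[edges[e, 2], ]
    len <- sqrt(sum((b - a)^2))
    edgeLen[e] <- len
    ss <- seq(0, len, by = stepUm)
    if (ss[length(ss)] < len) ss <- c(ss, len)
    pts <- outer(ss / max(len, 1e-12), b - a) + rep(a, each = length(ss))
    for (i in seq_len(nrow(centroids))) {
      d2 <- rowSums((pts - rep(centroids[i, ], each = length(ss)))^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) < nearest$dist[i]) {
        nearest$dist[i] <- sqrt(d2[j])
        nearest$edge[i] <- e
        nearest$s[i] <- ss[j]
      }
    }
  }
  # rebuild the graph: skeleton edges, with attachment points chained in
  # arclength order on their host edges
  vCount <- nrow(nodes)
  edgeList <- NULL
  weights <- NULL
  attachV <- integer(nrow(centroids))
  for (e in seq_len(nE)) {
    hosts <- which(nearest$edge == e)
    if (!length(hosts)) {
      edgeList <- rbind(edgeList, edges[e, ])
      weights <- c(weights, edgeLen[e])
      next
    }
    o <- hosts[order(nearest$s[hosts])]
    prevV <- edges[e, 1]; prevS <- 0
    for (i in o) {
      vCount <- vCount + 1L
      attachV[i] <- vCount
      edgeList <- rbind(edgeList, c(prevV, vCount))
      weights <- c(weights, nearest$s[i] - prevS)
      prevV <- vCount; prevS <- nearest$s[i]
    }
    edgeList <- rbind(edgeList, c(prevV, edges[e, 2]))
    weights <- c(weights, edgeLen[e] - prevS)
  }
  roiV <- integer(nrow(centroids))
  for (i in seq_len(nrow(centroids))) {
    vCount <- vCount + 1L
    roiV[i] <- vCount
    edgeList <- rbind(edgeList, c(attachV[i], vCount))
    weights <- c(weights, nearest$dist[i])
  }
  g <- igraph::make_empty_graph(n = vCount, directed = FALSE)
  g <- igraph::add_edges(g, t(edgeList))
  igraph::E(g)$weight <- pmax(weights, 0)
  structure(list(graph = g, roiVertices = roiV,
                 linkLengths = nearest$dist), class = "PathGraph")
}

#' Pairwise ROI distances along the skeleton and in space
#'
#' All-pairs shortest paths between ROI vertices over the weighted
#' skeleton graph, with straight-line (Euclidean) distances alongside.
#'
#' @param pathGraph a [linkRoisToSkeleton()] result.
#' @param centroids the ROI centroids used to build it (for the Euclidean
#'   distances); optional.
#' @return list with `path` (um matrix) and `euclid` (um matrix or NULL).
#' @export
pairwisePathDistances <- function(pathGraph, centroids = NULL) {
  stopifnot(inherits(pathGraph, "PathGraph"))
  path <- igraph::distances(pathGraph$graph, v = pathGraph$roiVertices,
                            to = pathGraph$roiVertices)
  dimnames(path) <- NULL
  euclid <- if (!is.null(centroids))
    as.matrix(stats::dist(matrix(as.numeric(centroids), ncol = 3))) else NULL
  list(path = path, euclid = euclid)
}

# Correlations between two repeats of two ROIs, averaged across repeat
# pairs when more than two repeats exist.
repPairCor <- function(x, y, pairs) {
  mean(vapply(seq_len(nrow(pairs)), function(k)
    safeCor(x[pairs[k, 1], ], y[pairs[k, 2], ]), numeric(1)))
}

#' Expected and observed paired response consistency
#'
#' For ROIs i and j with repeated responses R_(i,1), R_(i,2), ...:
#' q_ij = |Corr(R_i1, R_i2) * Corr(R_j1, R_j2)| (expected consistency from
#' each ROI's own repeat reliability) and
#' k_ij = |Corr(R_i1, R_j2) * Corr(R_j1, R_i2)| (observed cross-ROI
#' consistency). With more than two repeats, correlations are averaged
#' over all ordered repeat pairs. When traces come as a list of
#' per-movie-clip arrays, q and k are computed per clip and averaged.
#'
#' @param traces array (roi x time x repeat), or a list of such arrays
#'   (one per movie clip).
#' @return list with matrices `q` and `k` (values in \[0, 1\]); pairs with
#'   a zero-variance repeat are NA.
#' @export
pairedConsistency <- function(traces) {
  if (is.list(traces)) {
    per <- lapply(traces, pairedConsistency)
    q <- Reduce(`+`, lapply(per, `[[`, "q")) / length(per)
    k <- Reduce(`+`, lapply(per, `[[`, "k")) / length(per)
    return(list(q = q, k = k))
  }
  stopifnot(length(dim(traces)) == 3, dim(traces)[3] >= 2)
  n <- dim(traces)[1]
  nr <- dim(traces)[3]
  rp <- t(utils::combn(nr, 2))
  q <- matrix(NA_real_, n, n)
  k <- matrix(NA_real_, n, n)
  reps <- lapply(seq_len(n), function(i)
    matrix(traces[i, , ], ncol = dim(traces)[2], byrow = TRUE))
  selfR <- vapply(seq_len(n), function(i)
    repPairCor(reps[[i]], reps[[i]], rp), numeric(1))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { q[i, j] <- k[i, j] <- abs(selfR[i]^2); next }
      cij <- repPairCor(reps[[i]], reps[[j]], rp)
      cji <- repPairCor(reps[[j]], reps[[i]], rp)
      q[i, j] <- abs(selfR[i] * selfR[j])
      k[i, j] <- abs(cij * cji)
    }
  }
  list(q = q, k = k)
}

#' Estimate the axonal length constant from paired consistencies
#'
#' Models the distance decay of response correlation as
#' r(d, lambda) = exp(-d / lambda) and picks the lambda maximizing
#' Corr(r_lambda * q, k) over a (log-spaced) grid including Inf
#' (r identically 1, i.e. a homogeneous arbor). A lambda exceeding the
#' arbor's equivalent diameter means responses are homogeneous at the
#' arbor scale.
#'
#' @param pathD matrix of pairwise ROI path distances (um).
#' @param q,k consistency matrices from [pairedConsistency()].
#' @param lambdaGrid candidate length constants (um); default 60 log-spaced
#'   values in \[1, 1000\] plus Inf.
#' @param diameter optional arbor equivalent diameter (um) for the
#'   homogeneity verdict.
#' @return list with `lambda` (argmax), `profile` (correlation per grid
#'   value), `grid`, `flat` (flag: profile uninformative) and
#'   `homogeneous` (lambda > diameter, when given).
#' @export
estimateLengthConstant <- function(pathD, q, k, lambdaGrid = NULL,
                                   diameter = NULL) {
  if (is.null(lambdaGrid))
    lambdaGrid <- c(exp(seq(log(1), log(1000), length.out = 60)), Inf)
  ut <- upper.tri(pathD)
  sel <- ut & is.finite(q) & is.finite(k)
  if (sum(sel) < 10) stop("need at least 10 ROI pairs with valid q and k")
  d <- pathD[sel]; qv <- q[sel]; kv <- k[sel]
  profile <- vapply(lambdaGrid, function(l) {
    r <- if (is.infinite(l)) rep(1, length(d)) else exp(-d / l)
    cr <- safeCor(r * qv, kv)
    if (is.na(cr)) -Inf else cr
  }, numeric(1))
  flat <- !any(is.finite(profile)) ||
    (max(profile[is.finite(profile)]) -
       min(profile[is.finite(profile)])) < 1e-6
  lambda <- if (flat) Inf else lambdaGrid[which.max(profile)]
  out <- list(lambda = lambda, profile = profile, grid = lambdaGrid,
              flat = flat)
  if (flat) warning("flat correlation profile; length constant unbounded")
  if (!is.null(diameter)) out$homogeneous <- lambda > diameter
  out
}
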