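# Plain-text interchange: SWC skeletons, trace tables, stimulus logs, and
# (optionally, via the tiff package) image stacks.

#' Write an arbor skeleton to an SWC file
#'
#' Standard SWC (id, type, x, y, z, radius, parent); the tree is rooted at
#' node 1 and ROI-bearing nodes get type 5 (fork/custom marker retained on
#' read via the returned node table).
#'
#' @param arbor an [ArborModel-class].
#' @param path output file.
#' @param radius node radius written for every node (um).
#' @export
writeSWC <- function(arbor, path, radius = 0.5) {
  stopifnot(methods::is(arbor, "ArborModel"))
  n <- nrow(arbor@nodes)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(arbor@edges))
  parent <- rep(-1L, n)
  bfs <- igraph::bfs(g, root = 1, father = TRUE)
  f <- as.integer(bfs$father)
  parent[!is.na(f) & f > 0] <- f[!is.na(f) & f > 0]
  type <- ifelse(seq_len(n) %in% arbor@roiNodes, 5L, 3L)
  df <- data.frame(id = seq_len(n), type = type,
                   x = arbor@nodes[, 1], y = arbor@nodes[, 2],
                   z = arbor@nodes[, 3], radius = radius, parent = parent)
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an SWC skeleton file
#'
#' @param path SWC file (7 whitespace-separated columns; `#` comments).
#' @param diameter equivalent diameter to record (um); default the maximum
#'   pairwise node extent.
#' @param lengthConstant length constant to record (um).
#' @return an [ArborModel-class]; nodes with SWC type 5 become ROI nodes.
#' @export
readSWC <- function(path, diameter = NULL, lengthConstant = Inf) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  df <- df[order(df$id), ]
  idMap <- match(df$parent, df$id)
  edges <- cbind(which(!is.na(idMap)), idMap[!is.na(idMap)])
  nodes <- as.matrix(df[, c("x", "y", "z")])
  dimnames(nodes) <- NULL
  if (is.null(diameter))
    diameter <- max(stats::dist(nodes[, 1:2]))
  methods::new("ArborModel", nodes = nodes,
               edges = matrix(as.integer(edges), ncol = 2),
               roiNodes = as.integer(which(df$type == 5)),
               diameter = as.numeric(diameter),
               lengthConstant = lengthConstant)
}

#' Write epoched responses to CSV
#'
#' @param epochs an [EpochedResponses-class].
#' @param path output file.
#' @export
writeResponsesCsv <- function(epochs, path) {
  stopifnot(methods::is(epochs, "EpochedResponses"))
  utils::write.csv(epochs@data, path, row.names = FALSE)
  invisible(path)
}

#' Read epoched responses from CSV
#'
#' @param path CSV written by [writeResponsesCsv()].
#' @param samplingRate acquisition rate (Hz).
#' @return an [EpochedResponses-class].
#' @export
readResponsesCsv <- function(path, samplingRate) {
  methods::new("EpochedResponses", data = utils::read.csv(path),
               samplingRate = samplingRate)
}

#' Write a stimulus movie's sidecar metadata as JSON
#'
#' Records frame rate, pixel size, dimensions and the epoch log; pairs
#' with a multi-page TIFF of the frames (see [writeMovieTiff()]).
#'
#' @param movie a [StimulusMovie-class].
#' @param path output JSON file.
#' @export
writeMovieSidecar <- function(movie, path) {
  stopifnot(methods::is(movie, "StimulusMovie"))
  jsonlite::write_json(
    list(frameRate = movie@frameRate, pixelSize = movie@pixelSize,
         dim = dim(movie@frames), log = movie@log),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write stimulus-movie frames as a multi-page TIFF
#'
#' Requires the `tiff` package; frames are rescaled from the
#' \[-0.5, 0.5\] contrast range to \[0, 1\].
#'
#' @param movie a [StimulusMovie-class].
#' @param path output TIFF file.
#' @export
writeMovieTiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF stacks")
  d <- dim(movie@frames)
  pages <- lapply(seq_len(d[3]), function(i)
    pmin(1, pmax(0, movie@frames[, , i] + 0.5)))
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Read an image time series from a multi-page TIFF
#'
#' Requires the `tiff` package.
#'
#' @param path TIFF file.
#' @param frameRate,pixelSize acquisition metadata.
#' @param channel series channel label.
#' @return an [ImageSeries-class].
#' @export
readSeriesTiff <- function(path, frameRate, pixelSize,
                           channel = "fluorescence") {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  methods::new("ImageSeries", data = arr, frameRate = frameRate,
               pixelSize = pixelSize, channel = channel)
}
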