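#' @import methods
NULL

#' StimulusMovie: a rendered visual stimulus with its presentation log
#'
#' Luminance movie in contrast units (values in \[-0.5, 0.5\]) together with
#' the acquisition geometry and a log of stimulus epochs. Frames are stored as
#' an array indexed \[row, col, frame\].
#'
#' @slot frames numeric array (rows x cols x frames), contrast units.
#' @slot frameRate frames per second (Hz).
#' @slot pixelSize microns per pixel.
#' @slot log data.frame with columns `condition` (character), `onset`,
#'   `offset` (seconds), one row per stimulus epoch; epochs non-overlapping.
#'
#' @export
setClass("StimulusMovie",
  representation(
    frames = "array",
    frameRate = "numeric",
    pixelSize = "numeric",
    log = "data.frame"
  )
)

setValidity("StimulusMovie", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a rows x cols x frames array")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  lg <- object@log
  if (nrow(lg)) {
    if (!all(c("condition", "onset", "offset") %in% names(lg)))
      msg <- c(msg, "log needs columns condition, onset, offset")
    else {
      if (any(lg$offset < lg$onset)) msg <- c(msg, "log offsets before onsets")
      dur <- dim(object@frames)[3] / object@frameRate
      if (any(lg$onset < -1e-9) || any(lg$offset > dur + 1 / object@frameRate))
        msg <- c(msg, "log entries outside movie duration")
      o <- order(lg$onset)
      if (any(lg$onset[o][-1] < lg$offset[o][-nrow(lg)] - 1e-9))
        msg <- c(msg, "log entries overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ImageSeries: a registered calcium (or transmitted-light) image time series
#'
#' @slot data numeric array (rows x cols x frames), arbitrary intensity units.
#' @slot frameRate acquisition rate (Hz).
#' @slot pixelSize microns per pixel.
#' @slot channel "fluorescence" or "transmitted".
#'
#' @export
setClass("ImageSeries",
  representation(
    data = "array",
    frameRate = "numeric",
    pixelSize = "numeric",
    channel = "character"
  ),
  prototype(channel = "fluorescence")
)

setValidity("ImageSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a rows x cols x frames array")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (!object@channel %in% c("fluorescence", "transmitted"))
    msg <- c(msg, "channel must be 'fluorescence' or 'transmitted'")
  if (length(msg)) msg else TRUE
})

#' ROIMap: a labeled partition of above-threshold pixels into ROIs
#'
#' Region labels are positive integers grown from local peaks of a temporal
#' standard-deviation image; label 0 marks background (excluded) pixels.
#'
#' @slot labels integer matrix, 0 = background.
#' @slot peaks integer matrix (n x 2, \[row, col\]) of ROI seed peaks.
#' @slot areas numeric vector of ROI areas in square microns.
#'
#' @export
setClass("ROIMap",
  representation(
    labels = "matrix",
    peaks = "matrix",
    areas = "numeric"
  )
)

setValidity("ROIMap", function(object) {
  msg <- character()
  n <- if (length(object@peaks)) nrow(object@peaks) else 0L
  lab <- object@labels
  if (length(lab) && max(lab) > n)
    msg <- c(msg, "labels exceed number of peaks")
  if (n && length(object@areas) != n)
    msg <- c(msg, "areas must have one entry per ROI")
  if (length(msg)) msg else TRUE
})

#' EpochedResponses: per-ROI traces cut and aligned to stimulus epochs
#'
#' Long-format table of baseline-subtracted responses, one row per sample,
#' keyed by ROI, condition and repeat.
#'
#' @slot data data.frame with columns `roi`, `condition`, `rep`, `time`
#'   (seconds from epoch onset; negative = baseline window), `value`.
#' @slot samplingRate Hz of the response traces.
#'
#' @export
setClass("EpochedResponses",
  representation(
    data = "data.frame",
    samplingRate = "numeric"
  )
)

setValidity("EpochedResponses", function(object) {
  msg <- character()
  need <- c("roi", "condition", "rep", "time", "value")
  if (!all(need %in% names(object@data)))
    msg <- c(msg, paste("data needs columns", paste(need, collapse = ", ")))
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' EncodingSpace: principal coordinates of the population response distances
#'
#' Result of weighted nonmetric multidimensional scaling of pairwise
#' correlation distances; coordinates are ordered by explained variance.
#'
#' @slot coords numeric matrix (units x dims).
#' @slot stress final stress of the embedding (Kruskal stress-1 on the
#'   weighted, masked distances).
#' @slot explainedR2 per-coordinate cumulative-free explained variance
#'   (squared correlation of single-coordinate distances with the masked
#'   response distances).
#'
#' @export
setClass("EncodingSpace",
  representation(
    coords = "matrix",
    stress = "numeric",
    explainedR2 = "numeric"
  )
)

setValidity("EncodingSpace", function(object) {
  msg <- character()
  if (length(object@stress) != 1L || object@stress < 0)
    msg <- c(msg, "stress must be a single non-negative number")
  if (length(object@explainedR2) != ncol(object@coords))
    msg <- c(msg, "explainedR2 must have one entry per coordinate")
  if (length(msg)) msg else TRUE
})

#' ArborModel: an axon arbor skeleton with ROI attachment points
#'
#' Planar-tree skeleton in 3-D microns; ROIs sit on skeleton nodes. The
#' length constant parameterizes how the paired response consistency of two
#' ROIs decays with their path distance (exp(-d/lambda) on the
#' observed-vs-expected consistency scale); `Inf` means a perfectly
#' homogeneous arbor.
#'
#' @slot nodes numeric matrix (n x 3), micron coordinates.
#' @slot edges integer matrix (m x 2) of node indices.
#' @slot roiNodes integer vector of node indices carrying ROIs.
#' @slot diameter equivalent diameter of the arbor territory (microns).
#' @slot lengthConstant microns; may be `Inf`.
#'
#' @export
setClass("ArborModel",
  representation(
    nodes = "matrix",
    edges = "matrix",
    roiNodes = "integer",
    diameter = "numeric",
    lengthConstant = "numeric"
  )
)

setValidity("ArborModel", function(object) {
  msg <- character()
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be n x 3")
  if (length(object@roiNodes) &&
      (max(object@roiNodes) > nrow(object@nodes) || min(object@roiNodes) < 1))
    msg <- c(msg, "roiNodes out of range")
  if (object@diameter <= 0) msg <- c(msg, "diameter must be positive")
  if (object@lengthConstant <= 0)
    msg <- c(msg, "lengthConstant must be positive (Inf allowed)")
  if (nrow(object@nodes) > 1) {
    if (!nrow(object@edges)) {
      msg <- c(msg, "skeleton must be connected")
    } else {
      g <- igraph::make_empty_graph(n = nrow(object@nodes), directed = FALSE)
      g <- igraph::add_edges(g, t(object@edges))
      if (!igraph::is_connected(g)) msg <- c(msg, "skeleton must be connected")
    }
  }
  if (length(msg)) msg else TRUE
})
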