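# Accessor generics and show methods for the core containers.

#' @rdname StimulusMovie-class
#' @param object,x an object of the documented class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname StimulusMovie-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname StimulusMovie-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname StimulusMovie-class
#' @export
setGeneric("stimulusLog", function(x) standardGeneric("stimulusLog"))
#' @rdname ImageSeries-class
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))
#' @rdname ROIMap-class
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname ROIMap-class
#' @export
setGeneric("roiPeaks", function(x) standardGeneric("roiPeaks"))
#' @rdname ROIMap-class
#' @export
setGeneric("roiAreas", function(x) standardGeneric("roiAreas"))
#' @rdname EpochedResponses-class
#' @export
setGeneric("responseTable", function(x) standardGeneric("responseTable"))
#' @rdname EpochedResponses-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EncodingSpace-class
#' @export
setGeneric("spaceCoords", function(x) standardGeneric("spaceCoords"))
#' @rdname EncodingSpace-class
#' @export
setGeneric("spaceStress", function(x) standardGeneric("spaceStress"))
#' @rdname EncodingSpace-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @rdname ArborModel-class
#' @export
setGeneric("arborNodes", function(x) standardGeneric("arborNodes"))
#' @rdname ArborModel-class
#' @export
setGeneric("arborEdges", function(x) standardGeneric("arborEdges"))
#' @rdname ArborModel-class
#' @export
setGeneric("arborRoiNodes", function(x) standardGeneric("arborRoiNodes"))
#' @rdname ArborModel-class
#' @export
setGeneric("arborDiameter", function(x) standardGeneric("arborDiameter"))

#' @rdname StimulusMovie-class
#' @export
setMethod("frames", "StimulusMovie", function(x) x@frames)
#' @rdname StimulusMovie-class
#' @export
setMethod("frameRate", "StimulusMovie", function(x) x@frameRate)
#' @rdname ImageSeries-class
#' @export
setMethod("frameRate", "ImageSeries", function(x) x@frameRate)
#' @rdname StimulusMovie-class
#' @export
setMethod("pixelSize", "StimulusMovie", function(x) x@pixelSize)
#' @rdname ImageSeries-class
#' @export
setMethod("pixelSize", "ImageSeries", function(x) x@pixelSize)
#' @rdname StimulusMovie-class
#' @export
setMethod("stimulusLog", "StimulusMovie", function(x) x@log)
#' @rdname ImageSeries-class
#' @export
setMethod("seriesData", "ImageSeries", function(x) x@data)
#' @rdname ROIMap-class
#' @export
setMethod("roiLabels", "ROIMap", function(x) x@labels)
#' @rdname ROIMap-class
#' @export
setMethod("roiPeaks", "ROIMap", function(x) x@peaks)
#' @rdname ROIMap-class
#' @export
setMethod("roiAreas", "ROIMap", function(x) x@areas)
#' @rdname EpochedResponses-class
#' @export
setMethod("responseTable", "EpochedResponses", function(x) x@data)
#' @rdname EpochedResponses-class
#' @export
setMethod("samplingRate", "EpochedResponses", function(x) x@samplingRate)
#' @rdname EncodingSpace-class
#' @export
setMethod("spaceCoords", "EncodingSpace", function(x) x@coords)
#' @rdname EncodingSpace-class
#' @export
setMethod("spaceStress", "EncodingSpace", function(x) x@stress)
#' @rdname EncodingSpace-class
#' @export
setMethod("explainedVariance", "EncodingSpace", function(x) x@explainedR2)
#' @rdname ArborModel-class
#' @export
setMethod("arborNodes", "ArborModel", function(x) x@nodes)
#' @rdname ArborModel-class
#' @export
setMethod("arborEdges", "ArborModel", function(x) x@edges)
#' @rdname ArborModel-class
#' @export
setMethod("arborRoiNodes", "ArborModel", function(x) x@roiNodes)
#' @rdname ArborModel-class
#' @export
setMethod("arborDiameter", "ArborModel", function(x) x@diameter)

setMethod("show", "StimulusMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "StimulusMovie: %d x %d px, %d frames @ %.3g Hz (%.3g um/px), %d log epochs\n",
    d[1], d[2], d[3], object@frameRate, object@pixelSize, nrow(object@log)))
})

setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageSeries [%s]: %d x %d px, %d frames @ %.3g Hz (%.3g um/px)\n",
              object@channel, d[1], d[2], d[3], object@frameRate,
              object@pixelSize))
})

setMethod("show", "ROIMap", function(object) {
  n <- if (length(object@peaks)) nrow(object@peaks) else 0L
  cat(sprintf("ROIMap: %d ROIs over %d x %d px (%d labeled px)\n",
              n, nrow(object@labels), ncol(object@labels),
              sum(object@labels > 0)))
})

setMethod("show", "EpochedResponses", function(object) {
  d <- object@data
  cat(sprintf(
    "EpochedResponses: %d ROIs x %d conditions (%d rows @ %.3g Hz)\n",
    length(unique(d$roi)), length(unique(d$condition)), nrow(d),
    object@samplingRate))
})

setMethod("show", "EncodingSpace", function(object) {
  cat(sprintf("EncodingSpace: %d units x %d coords, stress %.4f, R2[1] %.3f\n",
              nrow(object@coords), ncol(object@coords), object@stress,
              if (length(object@explainedR2)) object@explainedR2[1] else NA))
})

setMethod("show", "ArborModel", function(object) {
  cat(sprintf(
    "ArborModel: %d nodes, %d ROIs, equivalent diameter %.1f um, lambda %s um\n",
    nrow(object@nodes), length(object@roiNodes), object@diameter,
    format(object@lengthConstant)))
})
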