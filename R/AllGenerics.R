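#' @name bloodcount-accessors
#' @title Accessors for bloodcount containers
#' @description Slot accessors for the S4 containers; user code should use
#'   these rather than `@`.
#' @param x a bloodcount S4 object.
#' @param ... passed to methods.
NULL

#' @rdname bloodcount-accessors
#' @export
setGeneric("detections", function(x, ...) standardGeneric("detections"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("nDetections", function(x) standardGeneric("nDetections"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("imageWidth", function(x) standardGeneric("imageWidth"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("imageHeight", function(x) standardGeneric("imageHeight"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("annotationObjects", function(x) standardGeneric("annotationObjects"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("tiles", function(x) standardGeneric("tiles"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("gridOrder", function(x) standardGeneric("gridOrder"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("sweepThresholdGrid", function(x) standardGeneric("sweepThresholdGrid"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("sweepErrors", function(x) standardGeneric("sweepErrors"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("groundTruthTotals", function(x) standardGeneric("groundTruthTotals"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("estimatedTotals", function(x) standardGeneric("estimatedTotals"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))

#' @rdname bloodcount-accessors
#' @export
setGeneric("perImageCounts", function(x) standardGeneric("perImageCounts"))

#' Count objects per cell class
#'
#' Tallies detections (or ground-truth objects) by label. Classes absent from
#' the input map to 0; labels outside `classes` are ignored.
#'
#' @param x a [DetectionSet][DetectionSet-class] or
#'   [AnnotationSet][AnnotationSet-class].
#' @param classes character labels to count; defaults to [cellClasses()].
#' @return Named integer vector, one entry per requested class.
#' @export
setGeneric("countByClass", function(x, classes = cellClasses())
    standardGeneric("countByClass"))

#' Select the operating confidence threshold from a sweep
#'
#' Returns the candidate threshold with the minimum mean absolute count
#' error; ties are broken toward the lowest threshold, the rule implied by
#' choosing the 25% operating point for platelets when 25--40% tie.
#'
#' @param x a [ThresholdSweepResult][ThresholdSweepResult-class].
#' @return Numeric scalar threshold (fraction).
#' @export
setGeneric("selectThreshold", function(x) standardGeneric("selectThreshold"))

setMethod("detections", "DetectionSet", function(x, ...) x@detections)
setMethod("nDetections", "DetectionSet", function(x) nrow(x@detections))
setMethod("imageId", "AnnotationSet", function(x) x@imageId)
setMethod("imageWidth", "AnnotationSet", function(x) x@imageWidth)
setMethod("imageHeight", "AnnotationSet", function(x) x@imageHeight)
setMethod("annotationObjects", "AnnotationSet", function(x) x@objects)
setMethod("tiles", "TileGrid", function(x) x@tiles)
setMethod("gridOrder", "TileGrid", function(x) x@g)
setMethod("imageWidth", "TileGrid", function(x) x@imageWidth)
setMethod("imageHeight", "TileGrid", function(x) x@imageHeight)
setMethod("sweepThresholdGrid", "ThresholdSweepResult", function(x) x@thresholds)
setMethod("sweepErrors", "ThresholdSweepResult", function(x) x@errors)
setMethod("nImages", "ThresholdSweepResult", function(x) x@nImages)
setMethod("groundTruthTotals", "CountReport",
          function(x) stats::setNames(x@groundTruth, x@classes))
setMethod("estimatedTotals", "CountReport",
          function(x) stats::setNames(x@estimated, x@classes))
setMethod("accuracies", "CountReport",
          function(x) stats::setNames(x@accuracy, x@classes))
setMethod("perImageCounts", "CountReport", function(x) x@perImage)
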