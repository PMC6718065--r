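# Central S4 containers. Detections and ground-truth objects are stored as
# plain data.frames inside lightweight S4 wrappers so that box geometry stays
# vectorised; validity methods enforce the coordinate and confidence
# invariants once, at construction.

.DETECTION_COLS <- c("image_id", "label", "confidence", "x1", "y1", "x2", "y2")
.OBJECT_COLS <- c("label", "x1", "y1", "x2", "y2")

#' Counted blood-cell classes
#'
#' The three labels produced by the detector on stained smears:
#' red blood cells, white blood cells, and platelets. Labels are compared
#' case-sensitively after whitespace trimming; other labels are carried
#' through I/O but excluded from counting unless explicitly requested.
#'
#' @return Character vector `c("RBC", "WBC", "Platelets")`.
#' @export
#' @examples
#' cellClasses()
cellClasses <- function() c("RBC", "WBC", "Platelets")

emptyDetectionFrame <- function() {
    data.frame(image_id = character(), label = character(),
               confidence = numeric(), x1 = numeric(), y1 = numeric(),
               x2 = numeric(), y2 = numeric(), stringsAsFactors = FALSE)
}

emptyObjectFrame <- function() {
    data.frame(label = character(), x1 = numeric(), y1 = numeric(),
               x2 = numeric(), y2 = numeric(), stringsAsFactors = FALSE)
}

# shared box sanity checks; returns character() when clean
.checkBoxFrame <- function(df) {
    msgs <- character()
    coord <- c("x1", "y1", "x2", "y2")
    if (!all(vapply(df[coord], is.numeric, logical(1))))
        return("box coordinates must be numeric")
    if (nrow(df)) {
        if (!all(is.finite(as.matrix(df[coord]))))
            msgs <- c(msgs, "box coordinates must be finite")
        bad <- which(df$x1 >= df$x2 | df$y1 >= df$y2)
        if (length(bad))
            msgs <- c(msgs, paste0("degenerate box (x1 >= x2 or y1 >= y2) at row(s) ",
                                   paste(utils::head(bad, 5L), collapse = ", ")))
    }
    msgs
}

#' DetectionSet: detector output for one or more images
#'
#' Holds one row per detection: the image identifier, the cell label, the
#' detector confidence in \[0,1\], and the axis-aligned bounding box given by
#' its top-left `(x1, y1)` and bottom-right `(x2, y2)` corners in continuous,
#' 0-based pixel coordinates (width = `x2 - x1`). Extra columns (e.g. a
#' provenance tag added by the oracle detector) are preserved through
#' filtering and deduplication.
#'
#' @slot detections data.frame with columns `image_id`, `label`,
#'   `confidence`, `x1`, `y1`, `x2`, `y2` (extra columns allowed).
#' @export
setClass("DetectionSet", representation(detections = "data.frame"))

setValidity("DetectionSet", function(object) {
    df <- object@detections
    miss <- setdiff(.DETECTION_COLS, names(df))
    if (length(miss))
        return(paste("missing detection column(s):", paste(miss, collapse = ", ")))
    msgs <- .checkBoxFrame(df)
    if (nrow(df)) {
        if (!is.numeric(df$confidence) ||
            any(!is.finite(df$confidence) | df$confidence < 0 | df$confidence > 1))
            msgs <- c(msgs, "confidence must lie in [0, 1]")
        if (!is.character(df$image_id) || !is.character(df$label))
            msgs <- c(msgs, "image_id and label must be character")
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' AnnotationSet: ground-truth objects for a single smear image
#'
#' Pascal VOC-style ground truth: the image identifier, optional image
#' dimensions (NA when the source XML carries no `size` element), and one row
#' per annotated cell with its class label and bounding box.
#'
#' @slot imageId character scalar identifier.
#' @slot imageWidth,imageHeight numeric scalar pixels; `NA` when unknown.
#' @slot objects data.frame with columns `label`, `x1`, `y1`, `x2`, `y2`.
#' @export
setClass("AnnotationSet",
         representation(imageId = "character", imageWidth = "numeric",
                        imageHeight = "numeric", objects = "data.frame"))

setValidity("AnnotationSet", function(object) {
    if (length(object@imageId) != 1L)
        return("imageId must be a single string")
    if (length(object@imageWidth) != 1L || length(object@imageHeight) != 1L)
        return("image dimensions must be scalars (possibly NA)")
    df <- object@objects
    miss <- setdiff(.OBJECT_COLS, names(df))
    if (length(miss))
        return(paste("missing object column(s):", paste(miss, collapse = ", ")))
    msgs <- .checkBoxFrame(df)
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' TileGrid: exact G x G partition of an image
#'
#' Tiles are laid out row-major; the base tile is
#' `floor(width/g) x floor(height/g)` and the last row/column absorb any
#' remainder, so the tiles cover every pixel exactly once.
#'
#' @slot imageWidth,imageHeight numeric pixels.
#' @slot g integer grid order.
#' @slot tiles data.frame with columns `tile`, `origin_x`, `origin_y`,
#'   `width`, `height`.
#' @export
setClass("TileGrid",
         representation(imageWidth = "numeric", imageHeight = "numeric",
                        g = "integer", tiles = "data.frame"))

setValidity("TileGrid", function(object) {
    t <- object@tiles
    if (nrow(t) != object@g^2)
        return("tile count must equal g^2")
    if (any(t$width <= 0) || any(t$height <= 0))
        return("tile dimensions must be positive")
    if (!isTRUE(all.equal(sum(t$width * t$height),
                          object@imageWidth * object@imageHeight)))
        return("tiles must cover the image area exactly")
    TRUE
})

#' ThresholdSweepResult: count error across candidate confidence thresholds
#'
#' For one cell class, the mean absolute count error between ground truth and
#' the pipeline's estimate, evaluated over a validation image set at each
#' candidate confidence threshold.
#'
#' @slot cls character cell class.
#' @slot thresholds strictly increasing numeric candidates (fractions).
#' @slot errors numeric mean absolute count errors, one per candidate.
#' @slot nImages integer validation-set size.
#' @export
setClass("ThresholdSweepResult",
         representation(cls = "character", thresholds = "numeric",
                        errors = "numeric", nImages = "integer"))

setValidity("ThresholdSweepResult", function(object) {
    if (length(object@thresholds) != length(object@errors))
        return("thresholds and errors must have equal length")
    if (length(object@thresholds) == 0L)
        return("at least one candidate threshold is required")
    if (any(diff(object@thresholds) <= 0))
        return("thresholds must be strictly increasing")
    if (any(object@errors < 0))
        return("errors must be non-negative")
    if (any(object@thresholds < 0 | object@thresholds > 1))
        return("thresholds must be fractions in [0, 1]")
    TRUE
})

#' CountReport: per-class ground truth, estimate, and counting accuracy
#'
#' Aggregate totals over an image set, plus an optional per-image long table
#' (`image_id`, `label`, `ground_truth`, `estimated`). Accuracy is the
#' count accuracy `(1 - |est - gt| / gt) * 100` — a census-level agreement
#' measure, not a detection precision/recall.
#'
#' @slot classes character class labels, in report order.
#' @slot groundTruth,estimated numeric totals named by class.
#' @slot accuracy numeric percent, named by class.
#' @slot perImage data.frame per-image counts (possibly empty).
#' @export
setClass("CountReport",
         representation(classes = "character", groundTruth = "numeric",
                        estimated = "numeric", accuracy = "numeric",
                        perImage = "data.frame"))

setValidity("CountReport", function(object) {
    n <- length(object@classes)
    if (length(object@groundTruth) != n || length(object@estimated) != n ||
        length(object@accuracy) != n)
        return("groundTruth, estimated and accuracy must have one entry per class")
    if (any(object@groundTruth < 0) || any(object@estimated < 0))
        return("counts must be non-negative")
    TRUE
})

setMethod("show", "DetectionSet", function(object) {
    df <- object@detections
    cat("DetectionSet:", nrow(df), "detection(s) across",
        length(unique(df$image_id)), "image(s)\n")
    if (nrow(df)) {
        tab <- table(df$label)
        cat("  labels:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                               collapse = ", "), "\n")
    }
})

setMethod("show", "AnnotationSet", function(object) {
    cat("AnnotationSet for image '", object@imageId, "' (",
        object@imageWidth, " x ", object@imageHeight, "): ",
        nrow(object@objects), " object(s)\n", sep = "")
    if (nrow(object@objects)) {
        tab <- table(object@objects$label)
        cat("  labels:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                               collapse = ", "), "\n")
    }
})

setMethod("show", "TileGrid", function(object) {
    cat("TileGrid: ", object@g, " x ", object@g, " over ",
        object@imageWidth, " x ", object@imageHeight, " px\n", sep = "")
})

setMethod("show", "ThresholdSweepResult", function(object) {
    cat("ThresholdSweepResult for", object@cls, "over", object@nImages,
        "image(s)\n")
    print(data.frame(threshold = object@thresholds, error = object@errors))
})

setMethod("show", "CountReport", function(object) {
    cat("CountReport\n")
    print(data.frame(class = object@classes,
                     ground_truth = object@groundTruth,
                     estimated = object@estimated,
                     accuracy_pct = object@accuracy,
                     row.names = NULL))
})
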