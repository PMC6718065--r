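#' Construct a DetectionSet
#'
#' @param df data.frame with columns `image_id`, `label`, `confidence`,
#'   `x1`, `y1`, `x2`, `y2`. Labels and image ids are trimmed of surrounding
#'   whitespace; extra columns are kept.
#' @return A [DetectionSet][DetectionSet-class].
#' @export
#' @examples
#' detectionSet(data.frame(image_id = "img1", label = "RBC",
#'                         confidence = 0.9, x1 = 0, y1 = 0, x2 = 10, y2 = 10))
detectionSet <- function(df = emptyDetectionFrame()) {
    stopifnot(is.data.frame(df))
    miss <- setdiff(.DETECTION_COLS, names(df))
    if (length(miss))
        stop("missing detection column(s): ", paste(miss, collapse = ", "))
    df$image_id <- trimws(as.character(df$image_id))
    df$label <- trimws(as.character(df$label))
    for (cc in c("confidence", "x1", "y1", "x2", "y2"))
        df[[cc]] <- as.numeric(df[[cc]])
    rownames(df) <- NULL
    methods::new("DetectionSet", detections = df)
}

#' Construct an AnnotationSet
#'
#' @param imageId image identifier.
#' @param objects data.frame with columns `label`, `x1`, `y1`, `x2`, `y2`.
#' @param imageWidth,imageHeight image dimensions in pixels (`NA` if
#'   unknown).
#' @param clamp if `TRUE` and dimensions are known, boxes are clipped to
#'   `[0, width] x [0, height]`.
#' @return An [AnnotationSet][AnnotationSet-class].
#' @export
annotationSet <- function(imageId, objects = emptyObjectFrame(),
                          imageWidth = NA_real_, imageHeight = NA_real_,
                          clamp = FALSE) {
    stopifnot(is.data.frame(objects))
    miss <- setdiff(.OBJECT_COLS, names(objects))
    if (length(miss))
        stop("missing object column(s): ", paste(miss, collapse = ", "))
    objects$label <- trimws(as.character(objects$label))
    for (cc in c("x1", "y1", "x2", "y2"))
        objects[[cc]] <- as.numeric(objects[[cc]])
    if (clamp && !is.na(imageWidth) && !is.na(imageHeight) && nrow(objects)) {
        objects$x1 <- pmax(0, pmin(objects$x1, imageWidth))
        objects$x2 <- pmax(0, pmin(objects$x2, imageWidth))
        objects$y1 <- pmax(0, pmin(objects$y1, imageHeight))
        objects$y2 <- pmax(0, pmin(objects$y2, imageHeight))
    }
    rownames(objects) <- NULL
    unk <- setdiff(unique(objects$label), cellClasses())
    if (length(unk))
        warning("unknown cell label(s) preserved but not counted by default: ",
                paste(unk, collapse = ", "))
    methods::new("AnnotationSet", imageId = as.character(imageId),
                 imageWidth = as.numeric(imageWidth),
                 imageHeight = as.numeric(imageHeight), objects = objects)
}

# internal constructor used by sweepThresholds
thresholdSweepResult <- function(cls, thresholds, errors, nImages) {
    methods::new("ThresholdSweepResult", cls = cls,
                 thresholds = as.numeric(thresholds),
                 errors = as.numeric(errors), nImages = as.integer(nImages))
}
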