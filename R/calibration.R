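# Confidence-threshold calibration: for each candidate threshold, run the
# same filter (+ dedup) the pipeline will run at inference, count per image,
# and score the candidate by the mean absolute count error against ground
# truth over the validation set.

#' Mean absolute count error
#'
#' The calibration criterion: the average over validation images of the
#' absolute difference between the ground-truth and estimated counts of one
#' cell class,
#' \deqn{\varepsilon = \frac{1}{N} \sum_{i=1}^{N} |\chi_{gt}^{(i)} - \chi_{est}^{(i)}|.}
#'
#' @param groundTruth,estimated non-negative integer count vectors, one
#'   entry per image, aligned.
#' @return Numeric scalar error (cells per image).
#' @export
#' @examples
#' meanAbsoluteCountError(c(3, 5), c(4, 5))  # 0.5
meanAbsoluteCountError <- function(groundTruth, estimated) {
    if (!length(groundTruth))
        stop("at least one image is required")
    if (length(groundTruth) != length(estimated))
        stop("groundTruth and estimated must have equal length")
    if (any(groundTruth < 0) || any(estimated < 0))
        stop("counts must be non-negative")
    mean(abs(groundTruth - estimated))
}

.annotationList <- function(annotations) {
    if (methods::is(annotations, "AnnotationSet"))
        annotations <- list(annotations)
    stopifnot(is.list(annotations),
              all(vapply(annotations, methods::is, logical(1), "AnnotationSet")))
    stats::setNames(annotations, vapply(annotations, imageId, character(1)))
}

#' Sweep candidate confidence thresholds for one class
#'
#' For each candidate: keep detections of `cls` with confidence at or above
#' the candidate, apply duplicate suppression if the class is configured for
#' it (so calibration measures the same pipeline that runs at inference),
#' count per image, and compute the mean absolute count error against the
#' annotations. Images with no surviving detections count as zero.
#'
#' @param d a [DetectionSet][DetectionSet-class] covering the validation
#'   images (raw, unthresholded).
#' @param annotations list of [AnnotationSet][AnnotationSet-class] (or a
#'   single one); every detection image id must appear here.
#' @param cls the cell class to calibrate.
#' @param grid candidate thresholds (fractions), default 0.20--0.60 in steps
#'   of 0.05.
#' @param dedup a [dedupConfig()].
#' @return A [ThresholdSweepResult][ThresholdSweepResult-class].
#' @export
sweepThresholds <- function(d, annotations, cls,
                            grid = seq(0.20, 0.60, by = 0.05),
                            dedup = dedupConfig()) {
    stopifnot(methods::is(d, "DetectionSet"), length(cls) == 1L)
    anns <- .annotationList(annotations)
    if (!length(grid)) stop("threshold grid must be non-empty")
    grid <- sort(unique(as.numeric(grid)))
    df <- detections(d)
    missing <- setdiff(unique(df$image_id), names(anns))
    if (length(missing))
        stop("detections reference image(s) with no annotation: ",
             paste(missing, collapse = ", "))
    ids <- names(anns)
    gt <- vapply(anns, function(a) countByClass(a, cls)[[1]], numeric(1))
    sub <- df[df$label == cls, , drop = FALSE]
    dodedup <- cls %in% dedup$classes
    errs <- vapply(grid, function(t) {
        surv <- sub[sub$confidence >= t, , drop = FALSE]
        if (dodedup && nrow(surv)) {
            ds <- dedupDetections(methods::new("DetectionSet", detections = surv),
                                  dedup)
            surv <- detections(ds)
        }
        est <- vapply(ids, function(id) sum(surv$image_id == id), numeric(1))
        meanAbsoluteCountError(gt, est)
    }, numeric(1))
    thresholdSweepResult(cls, grid, errs, length(anns))
}

#' @describeIn selectThreshold minimum-error candidate, lowest threshold on
#'   ties.
#' @export
setMethod("selectThreshold", "ThresholdSweepResult", function(x) {
    x@thresholds[which.min(x@errors)]
})

#' Calibrate operating thresholds for several classes
#'
#' Runs [sweepThresholds()] per class and selects each operating point with
#' [selectThreshold()].
#'
#' @inheritParams sweepThresholds
#' @param classes character classes to calibrate.
#' @return List with `sweeps` (named list of
#'   [ThresholdSweepResult][ThresholdSweepResult-class]) and `thresholds`
#'   (named numeric operating points, fractions).
#' @export
calibrateThresholds <- function(d, annotations, classes = cellClasses(),
                                grid = seq(0.20, 0.60, by = 0.05),
                                dedup = dedupConfig()) {
    sweeps <- lapply(classes, function(cl)
        sweepThresholds(d, annotations, cl, grid = grid, dedup = dedup))
    names(sweeps) <- classes
    list(sweeps = sweeps,
         thresholds = vapply(sweeps, selectThreshold, numeric(1)))
}

#' Tabulate sweeps in report form
#'
#' One row per candidate threshold (as percent), one error column per class
#' — the layout in which calibration tables are usually printed.
#'
#' @param sweeps named list of
#'   [ThresholdSweepResult][ThresholdSweepResult-class] sharing one grid.
#' @return data.frame with column `threshold_pct` then one column per class.
#' @export
sweepTable <- function(sweeps) {
    stopifnot(length(sweeps) >= 1L)
    grid <- sweepThresholdGrid(sweeps[[1]])
    for (s in sweeps)
        if (!isTRUE(all.equal(sweepThresholdGrid(s), grid)))
            stop("all sweeps must share the same threshold grid")
    out <- data.frame(threshold_pct = grid * 100)
    for (nm in names(sweeps)) out[[nm]] <- sweepErrors(sweeps[[nm]])
    out
}
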