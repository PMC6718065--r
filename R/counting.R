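# Counting and reporting: cells are counted by label; aggregate accuracy is
# the census-style count accuracy (1 - |est - gt|/gt) * 100. Also the
# detector output-layer sizing rule and the end-to-end / tiled pipelines.

#' Final-layer filter count of a grid-cell detector
#'
#' Each anchor box predicts 5 values (objectness, x, y, width, height) plus
#' the class probabilities, so the final convolutional layer needs
#' `nAnchors * (nClasses + 5)` filters. With 5 anchors and the 3 blood-cell
#' classes this is 40.
#'
#' @param nAnchors number of anchor boxes (>= 1).
#' @param nClasses number of object classes (>= 1).
#' @return Integer filter count.
#' @export
#' @examples
#' filterCount(5, 3)  # 40
filterCount <- function(nAnchors, nClasses) {
    nAnchors <- as.integer(nAnchors); nClasses <- as.integer(nClasses)
    if (is.na(nAnchors) || nAnchors < 1L || is.na(nClasses) || nClasses < 1L)
        stop("nAnchors and nClasses must be integers >= 1")
    nAnchors * (nClasses + 5L)
}

setMethod("countByClass", "DetectionSet", function(x, classes = cellClasses()) {
    df <- detections(x)
    tab <- table(factor(df$label, levels = classes))
    stats::setNames(as.integer(tab), classes)
})

setMethod("countByClass", "AnnotationSet", function(x, classes = cellClasses()) {
    tab <- table(factor(annotationObjects(x)$label, levels = classes))
    stats::setNames(as.integer(tab), classes)
})

#' Counting accuracy against ground truth
#'
#' `(1 - |estimated - groundTruth| / groundTruth) * 100`, reported to two
#' decimals. This scores agreement of aggregate counts — it is not a
#' detection precision or recall, and it can go negative when the estimate
#' is off by more than the ground truth itself (reported as computed).
#'
#' @param groundTruth true total count (>= 1).
#' @param estimated estimated total count.
#' @return Accuracy in percent, rounded to 2 decimals. Vectorised.
#' @export
#' @examples
#' countingAccuracy(792, 823)  # 96.09
countingAccuracy <- function(groundTruth, estimated) {
    if (any(groundTruth < 1))
        stop("accuracy is undefined for ground-truth totals < 1")
    round((1 - abs(estimated - groundTruth) / groundTruth) * 100, 2)
}

#' Build a count report
#'
#' @param groundTruth,estimated named per-class totals (aligned by name).
#' @param perImage optional long data.frame (`image_id`, `label`,
#'   `ground_truth`, `estimated`).
#' @return A [CountReport][CountReport-class].
#' @export
#' @examples
#' countReport(c(RBC = 792, WBC = 61, Platelets = 55),
#'             c(RBC = 823, WBC = 53, Platelets = 53))
countReport <- function(groundTruth, estimated,
                        perImage = data.frame()) {
    stopifnot(!is.null(names(groundTruth)))
    classes <- names(groundTruth)
    estimated <- estimated[classes]
    if (any(is.na(estimated)))
        stop("estimated totals missing for some classes")
    gt <- as.numeric(groundTruth); est <- as.numeric(estimated)
    acc <- rep(NA_real_, length(gt))  # undefined when a class has no truth
    ok <- gt >= 1
    if (any(ok)) acc[ok] <- countingAccuracy(gt[ok], est[ok])
    methods::new("CountReport", classes = classes, groundTruth = gt,
                 estimated = est, accuracy = acc, perImage = perImage)
}

#' Write a count report to CSV or JSON
#'
#' @param report a [CountReport][CountReport-class].
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeCountReport <- function(report, path, format = c("csv", "json")) {
    format <- match.arg(format)
    tab <- data.frame(class = report@classes,
                      ground_truth = report@groundTruth,
                      estimated = report@estimated,
                      accuracy_pct = report@accuracy)
    if (format == "csv") {
        utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    } else {
        jsonlite::write_json(tab, path, dataframe = "rows", digits = NA)
    }
    invisible(path)
}

# per-image wide count table over given ids (zeros filled in)
.perImageCounts <- function(df, ids, classes) {
    out <- data.frame(image_id = ids, stringsAsFactors = FALSE)
    for (cl in classes)
        out[[cl]] <- vapply(ids, function(id)
            sum(df$image_id == id & df$label == cl), numeric(1))
    rownames(out) <- NULL
    out
}

#' Run the identification-and-counting pipeline
#'
#' Per image: confidence filtering at the per-class operating thresholds,
#' duplicate suppression for the configured classes, then counting by label.
#' Circular markers are emitted for every surviving detection (for
#' visualisation; counting operates on the detections themselves). When
#' annotations are supplied the result includes a
#' [CountReport][CountReport-class] with aggregate accuracy.
#'
#' @param d a raw [DetectionSet][DetectionSet-class] (one or many images).
#' @param thresholds [classThresholds()] operating points.
#' @param dedup a [dedupConfig()].
#' @param annotations optional list of
#'   [AnnotationSet][AnnotationSet-class] for accuracy reporting.
#' @param classes classes to count; defaults to the threshold names.
#' @return List with `detections` (surviving
#'   [DetectionSet][DetectionSet-class]), `counts` (per-image wide table),
#'   `totals` (named vector), `markers` (`image_id`, `label`, `cx`, `cy`,
#'   `r`), and `report` (a [CountReport][CountReport-class] or `NULL`).
#' @export
runPipeline <- function(d, thresholds, dedup = dedupConfig(),
                        annotations = NULL, classes = names(thresholds)) {
    filtered <- filterByConfidence(d, thresholds)
    kept <- dedupDetections(filtered, dedup)
    df <- detections(kept)
    ids <- if (is.null(annotations)) unique(df$image_id)
           else names(.annotationList(annotations))
    counts <- .perImageCounts(df, ids, classes)
    totals <- countByClass(kept, classes)
    markers <- if (nrow(df))
        cbind(df[, c("image_id", "label")], boxToCircle(df))
    else data.frame(image_id = character(), label = character(),
                    cx = numeric(), cy = numeric(), r = numeric())
    report <- NULL
    if (!is.null(annotations)) {
        anns <- .annotationList(annotations)
        extra <- setdiff(unique(df$image_id), names(anns))
        if (length(extra))
            stop("detections reference image(s) with no annotation: ",
                 paste(extra, collapse = ", "))
        gtm <- vapply(anns, countByClass, numeric(length(classes)),
                      classes = classes)
        gt <- if (is.matrix(gtm)) rowSums(gtm) else
            stats::setNames(sum(gtm), classes)
        perImage <- do.call(rbind, lapply(names(anns), function(id) {
            g <- countByClass(anns[[id]], classes)
            e <- vapply(classes, function(cl)
                sum(df$image_id == id & df$label == cl), numeric(1))
            data.frame(image_id = id, label = classes, ground_truth = g,
                       estimated = e, row.names = NULL)
        }))
        report <- countReport(stats::setNames(gt, classes), totals, perImage)
    }
    list(detections = kept, counts = counts, totals = totals,
         markers = markers, report = report)
}

#' Run the tiled pipeline for high-resolution smears
#'
#' Each tile's detections are processed individually (confidence filter,
#' then duplicate suppression within the tile) and projected back onto the
#' original image; global counts are the sums over tiles. With `g = 1` this
#' is exactly [runPipeline()] on the whole image. Optionally a second
#' duplicate-suppression pass can run on the merged global detections to
#' catch cells split across tile boundaries (an extension; off by default).
#'
#' @param imageWidth,imageHeight dimensions of the full image in pixels.
#' @param g grid order; tiles come from [makeTileGrid()].
#' @param tileDetections list of `g^2` [DetectionSet][DetectionSet-class]
#'   objects in tile-local coordinates, row-major tile order.
#' @param thresholds,dedup as in [runPipeline()].
#' @param classes classes to count.
#' @param dedupAfterMerge run a second dedup pass on the merged detections.
#' @return List with `detections` (global coordinates), `totals`, `markers`,
#'   and `grid` (the [TileGrid][TileGrid-class]).
#' @export
runTiledPipeline <- function(imageWidth, imageHeight, g, tileDetections,
                             thresholds, dedup = dedupConfig(),
                             classes = names(thresholds),
                             dedupAfterMerge = FALSE) {
    grid <- makeTileGrid(imageWidth, imageHeight, g)
    if (length(tileDetections) != g^2)
        stop("expected ", g^2, " tile detection sets, got ",
             length(tileDetections))
    tl <- tiles(grid)
    parts <- lapply(seq_len(g^2), function(k) {
        dk <- tileDetections[[k]]
        stopifnot(methods::is(dk, "DetectionSet"))
        dk <- dedupDetections(filterByConfidence(dk, thresholds), dedup)
        detections(projectToGlobal(dk, c(tl$origin_x[k], tl$origin_y[k])))
    })
    df <- do.call(rbind, parts)
    rownames(df) <- NULL
    merged <- methods::new("DetectionSet", detections = df)
    if (dedupAfterMerge) merged <- dedupDetections(merged, dedup)
    df <- detections(merged)
    markers <- if (nrow(df))
        cbind(df[, c("image_id", "label")], boxToCircle(df))
    else data.frame(image_id = character(), label = character(),
                    cx = numeric(), cy = numeric(), r = numeric())
    list(detections = merged, totals = countByClass(merged, classes),
         markers = markers, grid = grid)
}
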