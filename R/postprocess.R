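# Per-class confidence filtering and nearest-neighbour/IOU duplicate
# suppression — the double-count fix for platelets detected by two adjacent
# detector grid cells.

#' Per-class confidence thresholds
#'
#' Builds the named threshold vector used by [filterByConfidence()]. Values
#' above 1 are read as percentages (matching how operating points are
#' usually quoted, e.g. 55 for RBC) and normalised to fractions; values in
#' \[0, 1\] are taken as fractions.
#'
#' @param ... named thresholds, e.g. `RBC = 55, WBC = 35, Platelets = 25`,
#'   or a single named numeric vector.
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
#' @examples
#' classThresholds(RBC = 55, WBC = 35, Platelets = 25)
classThresholds <- function(...) {
    v <- c(...)
    if (is.list(v)) v <- unlist(v)
    if (!length(v) || is.null(names(v)) || any(!nzchar(names(v))))
        stop("thresholds must be named by cell class")
    v <- vapply(v, as.numeric, numeric(1))
    v <- ifelse(v > 1, v / 100, v)
    if (any(v < 0 | v > 1))
        stop("thresholds must lie in [0, 1] (or [0, 100] as percent)")
    v
}

#' Duplicate-suppression configuration
#'
#' By default only platelets are deduplicated — the one class the detector
#' double-counts, when the same platelet is picked up by two consecutive
#' grid cells — with an allowed overlap of 10% IOU between a platelet and
#' its closest platelet.
#'
#' @param classes character classes to deduplicate.
#' @param iouThreshold allowed IOU between a detection and its nearest
#'   same-class neighbour; overlaps strictly greater are discarded as double
#'   counts.
#' @return A list of class `DedupConfig`.
#' @export
dedupConfig <- function(classes = "Platelets", iouThreshold = 0.10) {
    iouThreshold <- as.numeric(iouThreshold)
    if (iouThreshold > 1 && iouThreshold <= 100) iouThreshold <- iouThreshold / 100
    if (is.na(iouThreshold) || iouThreshold < 0 || iouThreshold > 1)
        stop("iouThreshold must lie in [0, 1]")
    structure(list(classes = as.character(classes),
                   iouThreshold = iouThreshold),
              class = "DedupConfig")
}

#' Filter detections by per-class confidence threshold
#'
#' Keeps a detection iff its confidence is greater than or equal to the
#' threshold of its class (the threshold is a minimum confidence, so the
#' boundary survives). Input order is preserved; the filter is idempotent
#' and monotone in each threshold.
#'
#' @param d a [DetectionSet][DetectionSet-class].
#' @param thresholds named fractions from [classThresholds()]; every label
#'   present in `d` must have a threshold.
#' @return The filtered [DetectionSet][DetectionSet-class].
#' @export
filterByConfidence <- function(d, thresholds) {
    stopifnot(methods::is(d, "DetectionSet"))
    df <- detections(d)
    if (!nrow(df)) return(d)
    unk <- setdiff(unique(df$label), names(thresholds))
    if (length(unk))
        stop("no confidence threshold configured for class(es): ",
             paste(unk, collapse = ", "))
    keep <- df$confidence >= thresholds[df$label]
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    methods::new("DetectionSet", detections = df)
}

# greedy accepted-set dedup for the rows of one class within one image;
# returns the row indices (into `df`) that survive
.dedupClassRows <- function(df, rows, iouThreshold) {
    if (length(rows) <= 1L) return(rows)
    ord <- rows[order(-df$confidence[rows], seq_along(rows))]
    accepted <- integer(0)
    for (i in ord) {
        if (!length(accepted)) { accepted <- i; next }
        dist <- centerDistance(df[i, , drop = FALSE],
                               df[accepted, , drop = FALSE])
        nn <- accepted[which.min(dist)]
        if (boxIou(df[i, , drop = FALSE], df[nn, , drop = FALSE]) > iouThreshold)
            next  # double count: ignore this cell
        accepted <- c(accepted, i)
    }
    sort(accepted)
}

#' Suppress duplicate detections of the same cell
#'
#' For each configured class within each image, candidates are visited in
#' descending confidence; each candidate's nearest already-accepted
#' same-class detection (1-nearest neighbour by centre distance) is found,
#' and the candidate is discarded as a double count when its IOU with that
#' neighbour exceeds the allowed overlap, else accepted. Classes outside the
#' configuration pass through untouched; the output is a subset of the
#' input, in input order.
#'
#' @param d a [DetectionSet][DetectionSet-class].
#' @param config a [dedupConfig()].
#' @return The deduplicated [DetectionSet][DetectionSet-class].
#' @export
#' @examples
#' d <- detectionSet(data.frame(
#'     image_id = "img1", label = "Platelets", confidence = c(0.9, 0.8),
#'     x1 = c(0, 2), y1 = c(0, 0), x2 = c(20, 22), y2 = c(20, 20)))
#' nDetections(dedupDetections(d))  # 1: the weaker overlapping box is dropped
dedupDetections <- function(d, config = dedupConfig()) {
    stopifnot(methods::is(d, "DetectionSet"), inherits(config, "DedupConfig"))
    df <- detections(d)
    if (!nrow(df) || !length(config$classes)) return(d)
    keep <- rep(TRUE, nrow(df))
    for (img in unique(df$image_id)) {
        for (cls in config$classes) {
            rows <- which(df$image_id == img & df$label == cls)
            if (length(rows) > 1L) {
                surv <- .dedupClassRows(df, rows, config$iouThreshold)
                keep[setdiff(rows, surv)] <- FALSE
            }
        }
    }
    out <- df[keep, , drop = FALSE]
    rownames(out) <- NULL
    methods::new("DetectionSet", detections = out)
}
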