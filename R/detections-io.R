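# Detections interchange: line-oriented CSV with fixed header
# image_id,label,confidence,x1,y1,x2,y2 — diffable and language-neutral.
# Floats are written with %.17g so a write/read round trip is lossless.

.DET_HEADER <- "image_id,label,confidence,x1,y1,x2,y2"

#' Read detections from interchange CSV
#'
#' Expects a header row `image_id,label,confidence,x1,y1,x2,y2` followed by
#' one record per detection. Confidences outside \[0,1\] raise a validation
#' error; non-numeric coordinates raise a parse error naming the line.
#'
#' @param x path to a CSV file, or the CSV content as a character vector of
#'   lines (or one string with embedded newlines).
#' @return A [DetectionSet][DetectionSet-class].
#' @export
readDetections <- function(x) {
    lines <- if (length(x) == 1L && file.exists(x)) readLines(x)
             else unlist(strsplit(x, "\n", fixed = TRUE))
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("detections CSV is empty (header row required)")
    hdr <- gsub("\\s", "", lines[[1]])
    if (hdr != .DET_HEADER)
        stop("unexpected detections header: '", lines[[1]], "' (expected '",
             .DET_HEADER, "')")
    body <- lines[-1]
    if (!length(body)) return(detectionSet())
    parts <- strsplit(body, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 7L)
    if (length(bad))
        stop("malformed detection record at line ", bad[1] + 1L,
             ": expected 7 fields")
    m <- matrix(unlist(parts), ncol = 7L, byrow = TRUE)
    numcols <- suppressWarnings(apply(m[, 3:7, drop = FALSE], 2, as.numeric))
    numcols <- matrix(numcols, ncol = 5L)
    for (j in 1:5) {
        bad <- which(is.na(numcols[, j]))
        if (length(bad))
            stop("non-numeric value '", m[bad[1], j + 2], "' at line ",
                 bad[1] + 1L, ", field ",
                 c("confidence", "x1", "y1", "x2", "y2")[j])
    }
    conf <- numcols[, 1]
    if (any(conf < 0 | conf > 1))
        stop("confidence outside [0, 1] at line ",
             which(conf < 0 | conf > 1)[1] + 1L)
    detectionSet(data.frame(image_id = m[, 1], label = m[, 2],
                            confidence = conf, x1 = numcols[, 2],
                            y1 = numcols[, 3], x2 = numcols[, 4],
                            y2 = numcols[, 5], stringsAsFactors = FALSE))
}

#' Write detections to interchange CSV
#'
#' @param d a [DetectionSet][DetectionSet-class].
#' @param path optional file path; when `NULL` the CSV is returned as a
#'   character vector of lines.
#' @return The CSV lines, invisibly when written to `path`.
#' @export
writeDetections <- function(d, path = NULL) {
    stopifnot(methods::is(d, "DetectionSet"))
    df <- detections(d)
    lines <- c(.DET_HEADER,
               if (nrow(df)) paste(df$image_id, df$label,
                                   sprintf("%.17g", df$confidence),
                                   .fmtNum(df$x1), .fmtNum(df$y1),
                                   .fmtNum(df$x2), .fmtNum(df$y2), sep = ","))
    if (is.null(path)) return(lines)
    writeLines(lines, path)
    invisible(lines)
}
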