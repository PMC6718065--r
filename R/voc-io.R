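# Pascal VOC XML I/O, BCCD dialect: <annotation> root, optional <size>,
# <object> nodes carrying <name> and <bndbox>/<xmin,ymin,xmax,ymax>.
# Coordinates are treated as continuous and 0-based with width = x2 - x1,
# matching the circle-marker arithmetic, not the historical VOC 1-based
# inclusive convention.

#' Read a Pascal VOC annotation (BCCD dialect)
#'
#' Parses ground-truth cell annotations from VOC XML. Objects are returned
#' in document order. A missing `size` element yields `NA` image dimensions.
#' Labels outside `RBC`/`WBC`/`Platelets` are preserved with a warning.
#'
#' @param x XML as a single string, or a path to an XML file.
#' @param imageId identifier for the image; defaults to the `filename`
#'   element (without extension) when present, else `"image"`.
#' @return An [AnnotationSet][AnnotationSet-class].
#' @export
#' @examples
#' xml <- paste0("<annotation><size><width>640</width><height>480</height>",
#'               "</size><object><name>WBC</name><bndbox><xmin>10</xmin>",
#'               "<ymin>20</ymin><xmax>110</xmax><ymax>120</ymax></bndbox>",
#'               "</object></annotation>")
#' readVocAnnotation(xml)
readVocAnnotation <- function(x, imageId = NULL) {
    doc <- tryCatch(xml2::read_xml(x), error = function(e)
        stop("VOC parse error: ", conditionMessage(e), call. = FALSE))
    if (xml2::xml_name(doc) != "annotation")
        stop("VOC parse error: root element is <", xml2::xml_name(doc),
             ">, expected <annotation>")
    num1 <- function(node, path) {
        n <- xml2::xml_find_first(node, path)
        if (inherits(n, "xml_missing")) NA_real_
        else as.numeric(xml2::xml_text(n))
    }
    w <- num1(doc, "./size/width")
    h <- num1(doc, "./size/height")
    if (is.null(imageId)) {
        fn <- xml2::xml_find_first(doc, "./filename")
        imageId <- if (inherits(fn, "xml_missing")) "image"
                   else sub("\\.[A-Za-z0-9]+$", "", trimws(xml2::xml_text(fn)))
    }
    objs <- xml2::xml_find_all(doc, "./object")
    if (length(objs)) {
        lab <- trimws(xml2::xml_text(xml2::xml_find_all(objs, "./name")))
        box <- t(vapply(seq_along(objs), function(i) {
            b <- c(num1(objs[[i]], "./bndbox/xmin"),
                   num1(objs[[i]], "./bndbox/ymin"),
                   num1(objs[[i]], "./bndbox/xmax"),
                   num1(objs[[i]], "./bndbox/ymax"))
            if (any(is.na(b)))
                stop("VOC parse error: object ", i, " has an incomplete bndbox")
            if (b[3] <= b[1] || b[4] <= b[2])
                stop("invalid box at object ", i,
                     ": xmax <= xmin or ymax <= ymin")
            b
        }, numeric(4)))
        objects <- data.frame(label = lab, x1 = box[, 1], y1 = box[, 2],
                              x2 = box[, 3], y2 = box[, 4],
                              stringsAsFactors = FALSE)
    } else {
        objects <- emptyObjectFrame()
    }
    annotationSet(imageId, objects, imageWidth = w, imageHeight = h)
}

#' Write an AnnotationSet as Pascal VOC XML
#'
#' Integer coordinates are emitted without decimals; non-integer coordinates
#' keep full precision, so a read/write round trip is lossless.
#'
#' @param a an [AnnotationSet][AnnotationSet-class].
#' @param path optional file path; when `NULL` the XML is returned as a
#'   string.
#' @return The XML text, invisibly when written to `path`.
#' @export
writeVocAnnotation <- function(a, path = NULL) {
    stopifnot(methods::is(a, "AnnotationSet"))
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", paste0(imageId(a), ".jpg"))
    if (!is.na(imageWidth(a)) && !is.na(imageHeight(a))) {
        sz <- xml2::xml_add_child(doc, "size")
        xml2::xml_add_child(sz, "width", .fmtNum(imageWidth(a)))
        xml2::xml_add_child(sz, "height", .fmtNum(imageHeight(a)))
        xml2::xml_add_child(sz, "depth", "3")
    }
    obj <- annotationObjects(a)
    for (i in seq_len(nrow(obj))) {
        o <- xml2::xml_add_child(doc, "object")
        xml2::xml_add_child(o, "name", obj$label[i])
        bb <- xml2::xml_add_child(o, "bndbox")
        xml2::xml_add_child(bb, "xmin", .fmtNum(obj$x1[i]))
        xml2::xml_add_child(bb, "ymin", .fmtNum(obj$y1[i]))
        xml2::xml_add_child(bb, "xmax", .fmtNum(obj$x2[i]))
        xml2::xml_add_child(bb, "ymax", .fmtNum(obj$y2[i]))
    }
    txt <- as.character(doc)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}

#' Read a directory of VOC annotations
#'
#' @param dir directory containing `*.xml` files.
#' @return Named list of [AnnotationSet][AnnotationSet-class] objects keyed
#'   by image id (file stem).
#' @export
readVocDirectory <- function(dir) {
    files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
    if (!length(files)) stop("no .xml annotation files found in ", dir)
    anns <- lapply(files, function(f)
        readVocAnnotation(f, imageId = sub("\\.xml$", "", basename(f))))
    stats::setNames(anns, vapply(anns, imageId, character(1)))
}
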