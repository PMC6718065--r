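# Cartoon rendering of synthetic smears. Deliberately simple: the package's
# claims are about detection post-processing, not image realism, so cells
# are flat class-coloured discs on a noisy background.

.CLASS_COLORS <- list(RBC = c(0.85, 0.45, 0.45),    # eosin pink
                      WBC = c(0.45, 0.30, 0.70),    # basophilic violet
                      Platelets = c(0.75, 0.45, 0.75),
                      other = c(0.50, 0.50, 0.50))

.classColor <- function(label) {
    if (label %in% names(.CLASS_COLORS)) .CLASS_COLORS[[label]]
    else .CLASS_COLORS$other
}

#' Render a synthetic smear image
#'
#' Draws each annotated cell as a filled disc inscribed in its box
#' (class-coded colour, radius half the shorter side) over a light
#' background with additive Gaussian noise. Discs are painted in object
#' order, so later cells overdraw earlier ones where they overlap.
#'
#' @param a an [AnnotationSet][AnnotationSet-class] with known dimensions.
#' @param backgroundNoiseSd SD of the background noise (intensity units,
#'   image range \[0, 1\]).
#' @param seed RNG seed for the background noise.
#' @return Numeric array `height x width x 3` with values in \[0, 1\].
#' @export
renderImage <- function(a, backgroundNoiseSd = 0.02, seed = NULL) {
    stopifnot(methods::is(a, "AnnotationSet"))
    W <- imageWidth(a); H <- imageHeight(a)
    if (is.na(W) || is.na(H))
        stop("annotation has unknown image dimensions")
    withSeed(seed, {
        bg <- 0.86 + stats::rnorm(H * W, 0, backgroundNoiseSd)
        bg <- pmin(1, pmax(0, bg))
        img <- array(rep(bg, 3), dim = c(H, W, 3))
        obj <- annotationObjects(a)
        # pixel centres: column j covers x in [j-1, j], centre j - 0.5
        px <- matrix(rep(seq_len(W) - 0.5, each = H), nrow = H)
        py <- matrix(rep(seq_len(H) - 0.5, times = W), nrow = H)
        for (i in seq_len(nrow(obj))) {
            cx <- (obj$x1[i] + obj$x2[i]) / 2
            cy <- (obj$y1[i] + obj$y2[i]) / 2
            r <- min(obj$x2[i] - obj$x1[i], obj$y2[i] - obj$y1[i]) / 2
            mask <- (px - cx)^2 + (py - cy)^2 <= r^2
            col <- .classColor(obj$label[i])
            for (ch in 1:3) {
                plane <- img[, , ch]
                plane[mask] <- col[ch]
                img[, , ch] <- plane
            }
        }
        img
    })
}

#' Overlay circular cell markers on an image
#'
#' Draws marker outlines (2 px rings, darkened class colour) from a marker
#' table as produced by [runPipeline()].
#'
#' @param img numeric array `height x width x 3`.
#' @param markers data.frame with `label`, `cx`, `cy`, `r` columns.
#' @return The annotated image array.
#' @export
drawMarkers <- function(img, markers) {
    H <- dim(img)[1]; W <- dim(img)[2]
    px <- matrix(rep(seq_len(W) - 0.5, each = H), nrow = H)
    py <- matrix(rep(seq_len(H) - 0.5, times = W), nrow = H)
    for (i in seq_len(nrow(markers))) {
        dd <- sqrt((px - markers$cx[i])^2 + (py - markers$cy[i])^2)
        ring <- abs(dd - markers$r[i]) <= 1
        col <- .classColor(markers$label[i]) * 0.6
        for (ch in 1:3) {
            plane <- img[, , ch]
            plane[ring] <- col[ch]
            img[, , ch] <- plane
        }
    }
    img
}

#' Write an image array as PNG
#'
#' @param img numeric array `height x width x 3` in \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImagePng <- function(img, path) {
    png::writePNG(img, path)
    invisible(path)
}
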