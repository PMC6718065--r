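# Box geometry. All functions are vectorised over data.frames carrying
# x1/y1/x2/y2 columns; a single box may be given as a named numeric vector.

.asBoxFrame <- function(b) {
    if (is.numeric(b) && !is.null(names(b)))
        b <- as.data.frame(as.list(b))
    stopifnot(is.data.frame(b), all(c("x1", "y1", "x2", "y2") %in% names(b)))
    b
}

.recycle2 <- function(a, b) {
    na <- nrow(a); nb <- nrow(b)
    if (na == nb) return(list(a = a, b = b))
    if (na == 1L) return(list(a = a[rep(1L, nb), , drop = FALSE], b = b))
    if (nb == 1L) return(list(a = a, b = b[rep(1L, na), , drop = FALSE]))
    stop("incompatible numbers of boxes: ", na, " vs ", nb)
}

#' Convert bounding boxes to circular cell markers
#'
#' Blood cells are close to circular, so rectangular detector boxes are
#' rendered as circles: the centre is the box centre and the radius is half
#' the box *width* — the height plays no role, by construction. An
#' `"enclosing"` mode using half the larger side is available for markers
#' that must cover elongated boxes.
#'
#' @param b boxes: data.frame with `x1`, `y1`, `x2`, `y2` columns, or a
#'   single named numeric vector.
#' @param mode `"width"` (default) or `"enclosing"`.
#' @return data.frame with columns `cx`, `cy`, `r` (pixels).
#' @export
#' @examples
#' boxToCircle(c(x1 = 2, y1 = 4, x2 = 8, y2 = 10))  # centre (5,7), r = 3
boxToCircle <- function(b, mode = c("width", "enclosing")) {
    mode <- match.arg(mode)
    b <- .asBoxFrame(b)
    r <- switch(mode,
                width = (b$x2 - b$x1) / 2,
                enclosing = pmax(b$x2 - b$x1, b$y2 - b$y1) / 2)
    data.frame(cx = (b$x1 + b$x2) / 2, cy = (b$y1 + b$y2) / 2, r = r)
}

#' Intersection over union of bounding boxes
#'
#' Continuous-area IOU: intersection area divided by union area; 0 for
#' disjoint boxes, 1 only for identical boxes. Vectorised elementwise with
#' recycling of a single box.
#'
#' @param a,b boxes as in [boxToCircle()].
#' @return Numeric vector of IOU values in \[0, 1\].
#' @export
#' @examples
#' boxIou(c(x1 = 0, y1 = 0, x2 = 10, y2 = 10),
#'        c(x1 = 5, y1 = 0, x2 = 15, y2 = 10))  # 1/3
boxIou <- function(a, b) {
    p <- .recycle2(.asBoxFrame(a), .asBoxFrame(b))
    a <- p$a; b <- p$b
    iw <- pmax(0, pmin(a$x2, b$x2) - pmax(a$x1, b$x1))
    ih <- pmax(0, pmin(a$y2, b$y2) - pmax(a$y1, b$y1))
    inter <- iw * ih
    union <- (a$x2 - a$x1) * (a$y2 - a$y1) +
             (b$x2 - b$x1) * (b$y2 - b$y1) - inter
    inter / union
}

#' Euclidean distance between box centres
#'
#' The distance metric behind the nearest-neighbour query in platelet
#' duplicate suppression.
#'
#' @param a,b boxes as in [boxToCircle()].
#' @return Numeric vector of distances in pixels.
#' @export
centerDistance <- function(a, b) {
    p <- .recycle2(.asBoxFrame(a), .asBoxFrame(b))
    a <- p$a; b <- p$b
    sqrt(((a$x1 + a$x2) / 2 - (b$x1 + b$x2) / 2)^2 +
         ((a$y1 + a$y2) / 2 - (b$y1 + b$y2) / 2)^2)
}

#' Partition an image into a G x G tile grid
#'
#' High-resolution smears are processed tile by tile; the grid is an exact
#' partition (no overlap, no gap). The base tile is
#' `floor(width/g) x floor(height/g)`; the last row and column absorb the
#' remainder.
#'
#' @param width,height image dimensions in pixels.
#' @param g grid order (>= 1); the image must be at least `g` pixels in each
#'   dimension.
#' @return A [TileGrid][TileGrid-class]; tiles are listed row-major.
#' @export
#' @examples
#' tiles(makeTileGrid(300, 300, 3))
makeTileGrid <- function(width, height, g) {
    g <- as.integer(g)
    if (is.na(g) || g < 1L) stop("grid order g must be an integer >= 1")
    if (width < g || height < g)
        stop("image dimensions (", width, " x ", height,
             ") must be at least g = ", g)
    w0 <- floor(width / g); h0 <- floor(height / g)
    col <- rep(0:(g - 1L), times = g)
    row <- rep(0:(g - 1L), each = g)
    ox <- col * w0; oy <- row * h0
    tw <- ifelse(col == g - 1L, width - ox, w0)
    th <- ifelse(row == g - 1L, height - oy, h0)
    methods::new("TileGrid", imageWidth = as.numeric(width),
                 imageHeight = as.numeric(height), g = g,
                 tiles = data.frame(tile = seq_len(g^2), origin_x = ox,
                                    origin_y = oy, width = tw, height = th))
}

#' Project tile-local detections into global image coordinates
#'
#' Translates every box by the tile origin; labels, confidences and any
#' extra columns are untouched, so widths and heights are preserved exactly.
#'
#' @param d a [DetectionSet][DetectionSet-class] in tile-local coordinates.
#' @param tileOrigin numeric length-2 `(origin_x, origin_y)`.
#' @return A [DetectionSet][DetectionSet-class] in global coordinates.
#' @export
projectToGlobal <- function(d, tileOrigin) {
    stopifnot(methods::is(d, "DetectionSet"), length(tileOrigin) == 2L)
    df <- detections(d)
    df$x1 <- df$x1 + tileOrigin[1]; df$x2 <- df$x2 + tileOrigin[1]
    df$y1 <- df$y1 + tileOrigin[2]; df$y2 <- df$y2 + tileOrigin[2]
    methods::new("DetectionSet", detections = df)
}

#' Split global detections into tile-local detection sets
#'
#' Assigns each detection to the tile containing its box centre and rewrites
#' its coordinates relative to the tile origin — the inverse of
#' [projectToGlobal()] for detections fully interior to a tile. Used to
#' emulate per-tile detector output when exercising the tiled pipeline.
#'
#' @param d a [DetectionSet][DetectionSet-class] in global coordinates.
#' @param grid a [TileGrid][TileGrid-class].
#' @return List of `g^2` [DetectionSet][DetectionSet-class] objects in tile
#'   order (row-major).
#' @export
splitDetectionsByTile <- function(d, grid) {
    stopifnot(methods::is(d, "DetectionSet"), methods::is(grid, "TileGrid"))
    df <- detections(d)
    g <- gridOrder(grid)
    w0 <- floor(imageWidth(grid) / g); h0 <- floor(imageHeight(grid) / g)
    cx <- (df$x1 + df$x2) / 2; cy <- (df$y1 + df$y2) / 2
    col <- pmin(floor(cx / w0), g - 1)
    row <- pmin(floor(cy / h0), g - 1)
    idx <- row * g + col + 1
    tl <- tiles(grid)
    lapply(seq_len(g^2), function(k) {
        sub <- df[which(idx == k), , drop = FALSE]
        sub$x1 <- sub$x1 - tl$origin_x[k]; sub$x2 <- sub$x2 - tl$origin_x[k]
        sub$y1 <- sub$y1 - tl$origin_y[k]; sub$y2 <- sub$y2 - tl$origin_y[k]
        rownames(sub) <- NULL
        methods::new("DetectionSet", detections = sub)
    })
}
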