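# Fixture builders and independent oracles shared across test files.

det_frame <- function(image_id = "img1", label = "RBC", confidence = 0.9,
                      x1 = 0, y1 = 0, x2 = 10, y2 = 10) {
    data.frame(image_id = image_id, label = label, confidence = confidence,
               x1 = x1, y1 = y1, x2 = x2, y2 = y2, stringsAsFactors = FALSE)
}

# random integer-coordinate box c(x1, y1, x2, y2) within [0, lim]^2
rand_int_box <- function(lim = 50, min_size = 3, max_size = 30) {
    w <- sample(min_size:max_size, 1)
    h <- sample(min_size:max_size, 1)
    x1 <- sample(0:(lim - w), 1)
    y1 <- sample(0:(lim - h), 1)
    c(x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h)
}

# Independent IOU oracle: count grid cells (centres at step/2 offsets) that
# fall inside each box. Exact for integer boxes at step = 1; approximates
# continuous boxes as step -> 0.
iou_grid_oracle <- function(a, b, step = 1) {
    x0 <- min(a[1], b[1]); x1 <- max(a[3], b[3])
    y0 <- min(a[2], b[2]); y1 <- max(a[4], b[4])
    xs <- seq(x0 + step / 2, x1, by = step)
    ys <- seq(y0 + step / 2, y1, by = step)
    gx <- rep(xs, times = length(ys))
    gy <- rep(ys, each = length(xs))
    inA <- gx > a[1] & gx < a[3] & gy > a[2] & gy < a[4]
    inB <- gx > b[1] & gx < b[3] & gy > b[2] & gy < b[4]
    u <- sum(inA | inB)
    if (u == 0) return(0)
    sum(inA & inB) / u
}

box_vec <- function(b) c(x1 = b$x1, y1 = b$y1, x2 = b$x2, y2 = b$y2)

# VOC XML skeleton for parser tests
voc_xml <- function(objects, width = 640, height = 480) {
    objs <- paste0(vapply(objects, function(o) paste0(
        "<object><name>", o$name, "</name><bndbox>",
        "<xmin>", o$box[1], "</xmin><ymin>", o$box[2], "</ymin>",
        "<xmax>", o$box[3], "</xmax><ymax>", o$box[4], "</ymax>",
        "</bndbox></object>"), character(1)), collapse = "")
    paste0("<annotation><filename>test.jpg</filename>",
           "<size><width>", width, "</width><height>", height,
           "</height><depth>3</depth></size>", objs, "</annotation>")
}
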