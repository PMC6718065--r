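test_that("VOC annotations parse with fields mapped in document order", {
    xml <- voc_xml(list(list(name = "WBC", box = c(10, 20, 110, 120))))
    a <- readVocAnnotation(xml)
    expect_s4_class(a, "AnnotationSet")
    expect_equal(imageId(a), "test")
    expect_equal(imageWidth(a), 640)
    expect_equal(imageHeight(a), 480)
    obj <- annotationObjects(a)
    expect_equal(nrow(obj), 1L)
    expect_equal(obj$label, "WBC")
    expect_equal(unlist(obj[, c("x1", "y1", "x2", "y2")], use.names = FALSE),
                 c(10, 20, 110, 120))

    # several objects: order preserved
    multi <- voc_xml(list(list(name = "RBC", box = c(0, 0, 50, 50)),
                          list(name = "Platelets", box = c(5, 5, 25, 25)),
                          list(name = "RBC", box = c(100, 100, 160, 150))))
    expect_equal(annotationObjects(readVocAnnotation(multi))$label,
                 c("RBC", "Platelets", "RBC"))
})

test_that("VOC annotations with no objects or no size parse cleanly", {
    a <- readVocAnnotation(voc_xml(list()))
    expect_equal(nrow(annotationObjects(a)), 0L)

    nosize <- "<annotation><object><name>RBC</name><bndbox><xmin>1</xmin><ymin>2</ymin><xmax>9</xmax><ymax>8</ymax></bndbox></object></annotation>"
    a2 <- readVocAnnotation(nosize)
    expect_true(is.na(imageWidth(a2)) && is.na(imageHeight(a2)))
    expect_equal(nrow(annotationObjects(a2)), 1L)
})

test_that("VOC read/write round trip is lossless", {
    objs <- list(list(name = "RBC", box = c(0, 0, 60, 55)),
                 list(name = "WBC", box = c(100, 90, 220, 210)),
                 list(name = "Platelets", box = c(30, 40, 52, 60)),
                 list(name = "RBC", box = c(500, 400, 580, 470)),
                 list(name = "RBC", box = c(7, 300, 77, 372)))
    a <- readVocAnnotation(voc_xml(objs))
    b <- readVocAnnotation(writeVocAnnotation(a))
    expect_identical(annotationObjects(b), annotationObjects(a))
    expect_equal(imageWidth(b), imageWidth(a))

    # seeded random 10-object fixture, non-integer coordinates included
    set.seed(41)
    df <- data.frame(label = sample(cellClasses(), 10, replace = TRUE),
                     x1 = runif(10, 0, 300), y1 = runif(10, 0, 200))
    df$x2 <- df$x1 + runif(10, 5, 100)
    df$y2 <- df$y1 + runif(10, 5, 100)
    r <- annotationSet("rand", df, imageWidth = 640, imageHeight = 480)
    r2 <- readVocAnnotation(writeVocAnnotation(r), imageId = "rand")
    expect_equal(annotationObjects(r2), annotationObjects(r))
})

test_that("VOC parser rejects malformed input with located errors", {
    expect_error(readVocAnnotation("<annotation><object></annotation>"),
                 "parse error")
    expect_error(readVocAnnotation("<notvoc/>"), "expected <annotation>")
    bad <- voc_xml(list(list(name = "RBC", box = c(10, 10, 60, 60)),
                        list(name = "WBC", box = c(100, 100, 90, 150))))
    expect_error(readVocAnnotation(bad), "object 2")
})

test_that("detections CSV parses records and enforces field validity", {
    d <- readDetections(c("image_id,label,confidence,x1,y1,x2,y2",
                          "img1,RBC,0.90,0,0,10,10"))
    df <- detections(d)
    expect_equal(df$label, "RBC")
    expect_equal(df$confidence, 0.90)
    expect_equal(unlist(df[, c("x1", "y1", "x2", "y2")], use.names = FALSE),
                 c(0, 0, 10, 10))

    empty <- readDetections("image_id,label,confidence,x1,y1,x2,y2")
    expect_equal(nDetections(empty), 0L)

    expect_error(readDetections(c("image_id,label,confidence,x1,y1,x2,y2",
                                  "img1,RBC,1.5,0,0,10,10")),
                 "confidence outside")
    expect_error(readDetections(c("image_id,label,confidence,x1,y1,x2,y2",
                                  "img1,RBC,0.9,0,0,10,10",
                                  "img1,RBC,0.9,0,zero,10,10")),
                 "line 3")
    expect_error(readDetections("x,y"), "header")
})

test_that("detections round trip preserves all fields at full precision", {
    set.seed(99)
    n <- 100
    df <- data.frame(image_id = sprintf("im%02d", sample(1:8, n, TRUE)),
                     label = sample(cellClasses(), n, TRUE),
                     confidence = runif(n),
                     x1 = runif(n, 0, 500), y1 = runif(n, 0, 400),
                     stringsAsFactors = FALSE)
    df$x2 <- df$x1 + runif(n, 1, 120)
    df$y2 <- df$y1 + runif(n, 1, 120)
    d <- detectionSet(df)
    rt <- readDetections(writeDetections(d))
    expect_identical(detections(rt), detections(d))

    # file-based path too
    p <- tempfile(fileext = ".csv")
    on.exit(unlink(p))
    writeDetections(d, p)
    expect_identical(detections(readDetections(p)), detections(d))
})

test_that("container validity catches malformed boxes and confidences", {
    expect_error(detectionSet(det_frame(x1 = 10, x2 = 5)), "degenerate box")
    expect_error(detectionSet(det_frame(confidence = 1.2)), "confidence")
    expect_warning(annotationSet("i", data.frame(label = "Monocyte", x1 = 0,
                                                 y1 = 0, x2 = 5, y2 = 5)),
                   "unknown cell label")
})
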