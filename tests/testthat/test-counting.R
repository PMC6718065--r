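test_that("final-layer filter count matches the anchor/class sizing rule", {
    expect_identical(filterCount(5, 3), 40L)
    expect_identical(filterCount(5, 20), 125L)   # original 20-class setup
    expect_identical(filterCount(1, 1), 6L)
    for (na in 1:10) for (nc in 1:10)
        expect_identical(filterCount(na, nc), as.integer(na * (nc + 5)))
    expect_error(filterCount(0, 3), ">= 1")
    expect_error(filterCount(5, -1), ">= 1")
})

test_that("counting by label covers all classes and conserves totals", {
    expect_equal(countByClass(detectionSet()),
                 c(RBC = 0L, WBC = 0L, Platelets = 0L))
    d <- detectionSet(det_frame(label = c("RBC", "RBC", "WBC"),
                                x1 = c(0, 20, 40), x2 = c(10, 30, 50)))
    expect_equal(countByClass(d), c(RBC = 2L, WBC = 1L, Platelets = 0L))

    set.seed(77)
    for (i in 1:10) {
        n <- sample(1:50, 1)
        df <- det_frame(label = sample(cellClasses(), n, TRUE),
                        confidence = runif(n), x1 = runif(n, 0, 100),
                        y1 = runif(n, 0, 100))
        df$x2 <- df$x1 + 5; df$y2 <- df$y1 + 5
        expect_equal(sum(countByClass(detectionSet(df))), n)
    }
})

test_that("counting accuracy reproduces the reference totals to 2 decimals", {
    expect_equal(countingAccuracy(792, 823), 96.09)
    expect_equal(countingAccuracy(61, 53), 86.89)
    expect_equal(countingAccuracy(55, 53), 96.36)
    expect_equal(countingAccuracy(100, 100), 100.00)
    expect_error(countingAccuracy(0, 5), "undefined")

    rep <- countReport(c(RBC = 792, WBC = 61, Platelets = 55),
                       c(RBC = 823, WBC = 53, Platelets = 53))
    expect_equal(accuracies(rep),
                 c(RBC = 96.09, WBC = 86.89, Platelets = 96.36))
    p <- tempfile(fileext = ".csv"); on.exit(unlink(p))
    writeCountReport(rep, p)
    tab <- read.csv(p)
    expect_equal(tab$accuracy_pct, c(96.09, 86.89, 96.36))
})

test_that("zero-noise oracle detections are counted back exactly", {
    ds <- generateDataset(10, synthConfig(seed = 55), noise = noiseConfig(),
                          seed = 55)
    res <- runPipeline(ds$detections,
                       classThresholds(RBC = 55, WBC = 35, Platelets = 25),
                       annotations = ds$annotations)
    gt <- Reduce(`+`, lapply(ds$annotations, countByClass))
    expect_equal(res$totals, gt)
    rep <- res$report
    acc <- accuracies(rep)
    expect_true(all(acc[groundTruthTotals(rep) > 0] == 100))
    # markers: one circle per surviving detection, centred on its box
    expect_equal(nrow(res$markers), nDetections(res$detections))
    d1 <- detections(res$detections)[1, ]
    expect_equal(res$markers$cx[1], (d1$x1 + d1$x2) / 2)
    expect_equal(res$markers$r[1], (d1$x2 - d1$x1) / 2)
})

test_that("injected platelet duplicates are corrected without touching other classes", {
    noise <- noiseConfig(duplicateRate = 1, tpConfidence = c(0.8, 1.0))
    ds <- generateDataset(10, synthConfig(seed = 91), noise = noise,
                          seed = 91)
    res <- runPipeline(ds$detections,
                       classThresholds(RBC = 0.2, WBC = 0.2, Platelets = 0.2),
                       annotations = ds$annotations)
    gt <- Reduce(`+`, lapply(ds$annotations, countByClass))
    expect_equal(res$totals, gt)

    # without dedup the platelet count is inflated by the duplicates
    raw <- runPipeline(ds$detections,
                       classThresholds(RBC = 0.2, WBC = 0.2, Platelets = 0.2),
                       dedup = dedupConfig(classes = character()))
    ndup <- sum(detections(ds$detections)$origin == "dup")
    expect_gt(ndup, 0)
    expect_equal(raw$totals[["Platelets"]], gt[["Platelets"]] + ndup)
    expect_equal(raw$totals[["RBC"]], gt[["RBC"]])
})

test_that("empty detection sets yield zero counts and no markers", {
    res <- runPipeline(detectionSet(), classThresholds(RBC = 0.5))
    expect_equal(res$totals, c(RBC = 0L))
    expect_equal(nrow(res$markers), 0L)
})

test_that("a 1x1 grid reproduces the untiled pipeline exactly", {
    ds <- generateDataset(1, synthConfig(seed = 62), noise = noiseConfig(),
                          seed = 62)
    thr <- classThresholds(RBC = 55, WBC = 35, Platelets = 25)
    grid <- makeTileGrid(640, 480, 1)
    tiled <- runTiledPipeline(640, 480, 1,
                              splitDetectionsByTile(ds$detections, grid),
                              thr)
    flat <- runPipeline(ds$detections, thr)
    expect_identical(detections(tiled$detections), detections(flat$detections))
    expect_equal(tiled$totals, flat$totals)
    expect_equal(tiled$markers, flat$markers)
})

test_that("tiling is count-consistent when cells are interior to tiles", {
    # 300x300 image, 3x3 grid, cells strictly inside tiles (margin 2 px),
    # platelets mutually disjoint so dedup is path-independent
    set.seed(112)
    rows <- list()
    tl <- tiles(makeTileGrid(300, 300, 3))
    for (i in 1:40) {
        k <- sample(9, 1)
        cls <- sample(cellClasses(), 1, prob = c(0.7, 0.1, 0.2))
        sz <- switch(cls, RBC = runif(1, 20, 40), WBC = runif(1, 40, 60),
                     Platelets = runif(1, 8, 14))
        x1 <- tl$origin_x[k] + runif(1, 2, tl$width[k] - sz - 2)
        y1 <- tl$origin_y[k] + runif(1, 2, tl$height[k] - sz - 2)
        rows[[i]] <- det_frame(label = cls, confidence = round(runif(1, 0.6, 1), 2),
                               x1 = x1, y1 = y1, x2 = x1 + sz, y2 = y1 + sz)
    }
    df <- do.call(rbind, rows)
    # keep platelets pairwise disjoint
    plt <- df[df$label == "Platelets", ]
    if (nrow(plt) > 1) {
        drop <- rep(FALSE, nrow(plt))
        for (i in 2:nrow(plt))
            for (j in 1:(i - 1))
                if (!drop[j] && boxIou(plt[i, ], plt[j, ]) > 0) drop[i] <- TRUE
        df <- rbind(df[df$label != "Platelets", ], plt[!drop, ])
    }
    d <- detectionSet(df)
    thr <- classThresholds(RBC = 0.55, WBC = 0.35, Platelets = 0.25)
    grid <- makeTileGrid(300, 300, 3)
    tiled <- runTiledPipeline(300, 300, 3, splitDetectionsByTile(d, grid), thr)
    flat <- runPipeline(d, thr)
    expect_equal(tiled$totals, flat$totals)

    # and the tiled path really used 9 tiles with local->global translation
    loc <- splitDetectionsByTile(d, grid)
    k <- which(vapply(loc, nDetections, integer(1)) > 0)[1]
    b <- detections(loc[[k]])[1, ]
    gb <- detections(projectToGlobal(loc[[k]],
                                     c(tiles(grid)$origin_x[k],
                                       tiles(grid)$origin_y[k])))[1, ]
    expect_equal(gb$x1 - b$x1, tiles(grid)$origin_x[k])
    expect_equal(gb$y1 - b$y1, tiles(grid)$origin_y[k])
})
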