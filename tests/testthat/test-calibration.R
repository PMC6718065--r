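test_that("mean absolute count error follows its defining sum", {
    expect_equal(meanAbsoluteCountError(c(3, 5, 2), c(3, 5, 2)), 0)
    expect_equal(meanAbsoluteCountError(c(3, 5), c(4, 5)), 0.5)
    # 60 images each off by one, against an explicit brute-force sum
    gt <- rep(10, 60); est <- gt + rep(c(1, -1), 30)
    expect_equal(meanAbsoluteCountError(gt, est),
                 sum(abs(gt - est)) / 60)
    expect_equal(meanAbsoluteCountError(gt, est), 1.0)

    expect_error(meanAbsoluteCountError(numeric(), numeric()),
                 "at least one image")
    expect_error(meanAbsoluteCountError(1:3, 1:2), "equal length")
    # invariant to image ordering
    set.seed(3)
    g <- rpois(30, 10); e <- rpois(30, 10); p <- sample(30)
    expect_equal(meanAbsoluteCountError(g[p], e[p]),
                 meanAbsoluteCountError(g, e))
})

test_that("threshold sweep enumerates survivors per candidate", {
    # a perfect detector: zero error at every candidate
    ann <- annotationSet("img1", data.frame(
        label = c("RBC", "RBC"), x1 = c(0, 100), y1 = c(0, 100),
        x2 = c(50, 150), y2 = c(50, 150)), 640, 480)
    perfect <- detectionSet(det_frame(confidence = 1.0,
                                      x1 = c(0, 100), y1 = c(0, 100),
                                      x2 = c(50, 150), y2 = c(50, 150)))
    s0 <- sweepThresholds(perfect, ann, "RBC")
    expect_equal(sweepErrors(s0), rep(0, 9))
    expect_equal(nImages(s0), 1L)

    # gt = 2 RBCs, detections at 0.9 / 0.6 / 0.3:
    # t=0.25 keeps 3 (err 1), t=0.55 keeps 2 (err 0), t=0.75 keeps 1 (err 1)
    noisy <- detectionSet(det_frame(confidence = c(0.9, 0.6, 0.3),
                                    x1 = c(0, 100, 200), y1 = c(0, 100, 200),
                                    x2 = c(50, 150, 250), y2 = c(50, 150, 250)))
    s <- sweepThresholds(noisy, ann, "RBC", grid = c(0.25, 0.55, 0.75))
    expect_equal(sweepErrors(s), c(1, 0, 1))
    expect_equal(selectThreshold(s), 0.55)

    expect_error(sweepThresholds(noisy, annotationSet("other"), "RBC"),
                 "no annotation")
})

test_that("surviving counts are non-increasing in the threshold", {
    set.seed(23)
    ds <- generateDataset(5, synthConfig(seed = 23),
                          noise = noiseConfig(tpConfidence = c(0.2, 1),
                                              falsePositiveRate = 2,
                                              fpConfidence = c(0.05, 0.6)),
                          seed = 23)
    df <- detections(ds$detections)
    for (cls in cellClasses()) {
        counts <- vapply(seq(0, 1, 0.1), function(t)
            sum(df$label == cls & df$confidence >= t), numeric(1))
        expect_true(all(diff(counts) <= 0))
    }
})

test_that("operating thresholds minimise the sweep error, lowest on ties", {
    grid <- seq(0.20, 0.60, by = 0.05)
    rbc <- new("ThresholdSweepResult", cls = "RBC", thresholds = grid,
               errors = c(5.650, 4.417, 3.450, 2.750, 2.500, 2.183, 2.133,
                          2.083, 2.100), nImages = 60L)
    wbc <- new("ThresholdSweepResult", cls = "WBC", thresholds = grid,
               errors = c(0.083, 0.050, 0.033, 0.017, 0.050, 0.100, 0.150,
                          0.200, 0.333), nImages = 60L)
    plt <- new("ThresholdSweepResult", cls = "Platelets", thresholds = grid,
               errors = c(0.217, 0.083, 0.083, 0.083, 0.083, 0.100, 0.100,
                          0.117, 0.150), nImages = 60L)
    expect_equal(selectThreshold(rbc), 0.55)
    expect_equal(selectThreshold(wbc), 0.35)
    # four-way tie at 0.083 across 25-40%: lowest threshold wins
    expect_equal(selectThreshold(plt), 0.25)

    flat <- new("ThresholdSweepResult", cls = "RBC", thresholds = grid,
                errors = rep(0.5, 9), nImages = 60L)
    expect_equal(selectThreshold(flat), 0.20)

    expect_equal(sweepTable(list(RBC = rbc, WBC = wbc, Platelets = plt))$RBC,
                 sweepErrors(rbc))
})

test_that("calibration recovers a separating threshold from the oracle", {
    # true cells score >= 0.7, spurious boxes <= 0.3: every grid point in
    # (0.3, 0.7] gives zero count error and the lowest such point is chosen
    noise <- noiseConfig(tpConfidence = c(0.70, 1.0),
                         fpConfidence = c(0.25, 0.30),
                         falsePositiveRate = 4)
    ds <- generateDataset(60, synthConfig(seed = 207), noise = noise,
                          seed = 207)
    cal <- calibrateThresholds(ds$detections, ds$annotations)
    for (cls in cellClasses()) {
        s <- cal$sweeps[[cls]]
        sel <- cal$thresholds[[cls]]
        expect_equal(min(sweepErrors(s)), 0)
        expect_true(sel > 0.3 && sel <= 0.7, info = cls)
        # zero error at every candidate above the false-positive band
        expect_equal(sweepErrors(s)[sweepThresholdGrid(s) > 0.3],
                     rep(0, sum(sweepThresholdGrid(s) > 0.3)))
    }
})
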