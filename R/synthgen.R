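# Synthetic smear generator and noisy oracle detector. The generator
# emulates BCCD-scale content: 640 x 480 images with many mid-sized RBCs,
# an occasional large WBC, and small platelets; default per-image class
# means (13.2 / 1.0 / 0.9) reproduce the 792 / 61 / 55 totals of a
# 60-image test set. The oracle detector stands in for the trained network
# and reproduces its reported failure modes: localisation jitter, missed
# cells, spurious boxes, and double-counted platelets.

#' Synthetic smear configuration
#'
#' @param imageWidth,imageHeight canvas in pixels (BCCD-scale default
#'   640 x 480).
#' @param classMeans named mean cells per image; counts are Poisson.
#' @param sizeRanges named list of `c(min, max)` box widths in pixels;
#'   platelets < RBC < WBC, emulating smear morphology.
#' @param allowEdgeTruncation when `TRUE`, cell centres may fall near the
#'   border and boxes are clipped to the image, producing the
#'   edge-truncated cells real smears contain.
#' @param plateletMaxIou true platelets are rejection-sampled to pairwise
#'   IOU at or below this value, so a platelet's only strong overlap is an
#'   injected duplicate; set `NA` to disable.
#' @param seed integer RNG seed (optional; generation functions also accept
#'   a seed directly).
#' @return A list of class `SynthConfig`.
#' @export
synthConfig <- function(imageWidth = 640, imageHeight = 480,
                        classMeans = c(RBC = 13.2, WBC = 1.0, Platelets = 0.9),
                        sizeRanges = list(RBC = c(50, 80), WBC = c(90, 140),
                                          Platelets = c(16, 30)),
                        allowEdgeTruncation = TRUE,
                        plateletMaxIou = 0.10, seed = NULL) {
    stopifnot(!is.null(names(classMeans)), all(classMeans >= 0),
              all(names(classMeans) %in% names(sizeRanges)))
    for (nm in names(sizeRanges)) {
        r <- sizeRanges[[nm]]
        if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
            stop("sizeRanges$", nm, " must be a positive c(min, max)")
    }
    if (all(c("RBC", "WBC", "Platelets") %in% names(sizeRanges))) {
        if (!(sizeRanges$Platelets[2] < sizeRanges$RBC[1]))
            stop("platelet sizes must be smaller than RBC sizes")
        if (!(sizeRanges$RBC[2] < sizeRanges$WBC[1]))
            stop("RBC sizes must be smaller than WBC sizes")
    }
    maxsz <- max(vapply(sizeRanges, max, numeric(1)))
    if (maxsz > imageWidth || maxsz > imageHeight)
        stop("largest cell (", maxsz, " px) does not fit the ",
             imageWidth, " x ", imageHeight, " canvas")
    structure(list(imageWidth = imageWidth, imageHeight = imageHeight,
                   classMeans = classMeans, sizeRanges = sizeRanges,
                   allowEdgeTruncation = allowEdgeTruncation,
                   plateletMaxIou = plateletMaxIou, seed = seed),
              class = "SynthConfig")
}

#' Oracle-detector noise configuration
#'
#' All defaults are zero/degenerate, i.e. a perfect detector: every
#' ground-truth cell is returned with confidence 1.0 and exact coordinates.
#' Confidences are drawn uniformly from the given closed ranges and
#' reported to `confidenceDigits` decimals, the coarse precision detector
#' score logs typically print.
#'
#' @param localizationJitterSd SD in pixels of independent Normal jitter on
#'   each box corner.
#' @param falseNegativeRate per-cell probability of being missed.
#' @param falsePositiveRate per-image mean of Poisson-distributed spurious
#'   boxes (random class, class-typical size).
#' @param duplicateRate per-platelet probability of spawning a shifted
#'   near-duplicate (IOU with its source > 0.10 by construction, confidence
#'   strictly below its source's — the weaker second-grid-cell detection).
#' @param tpConfidence,fpConfidence `c(lo, hi)` uniform confidence ranges
#'   for true and spurious detections, within \[0, 1\].
#' @param confidenceDigits decimals confidences are rounded to.
#' @param seed integer RNG seed (optional).
#' @return A list of class `NoiseConfig`.
#' @export
noiseConfig <- function(localizationJitterSd = 0, falseNegativeRate = 0,
                        falsePositiveRate = 0, duplicateRate = 0,
                        tpConfidence = c(1, 1), fpConfidence = c(0.05, 0.30),
                        confidenceDigits = 2, seed = NULL) {
    for (r in list(falseNegativeRate, duplicateRate))
        if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
    if (falsePositiveRate < 0) stop("falsePositiveRate must be >= 0")
    for (cc in list(tpConfidence, fpConfidence))
        if (length(cc) != 2L || any(cc < 0 | cc > 1) || cc[1] > cc[2])
            stop("confidence ranges must be c(lo, hi) within [0, 1]")
    structure(list(localizationJitterSd = localizationJitterSd,
                   falseNegativeRate = falseNegativeRate,
                   falsePositiveRate = falsePositiveRate,
                   duplicateRate = duplicateRate,
                   tpConfidence = tpConfidence, fpConfidence = fpConfidence,
                   confidenceDigits = confidenceDigits, seed = seed),
              class = "NoiseConfig")
}

# sample one integer-coordinate box of class `cls`; clipped to the canvas
.sampleBox <- function(cfg, cls) {
    r <- cfg$sizeRanges[[cls]]
    w <- stats::runif(1, r[1], r[2])
    h <- w * stats::runif(1, 0.9, 1.1)
    if (cfg$allowEdgeTruncation) {
        cx <- stats::runif(1, 2, cfg$imageWidth - 2)
        cy <- stats::runif(1, 2, cfg$imageHeight - 2)
    } else {
        cx <- stats::runif(1, w / 2, cfg$imageWidth - w / 2)
        cy <- stats::runif(1, h / 2, cfg$imageHeight - h / 2)
    }
    b <- c(x1 = max(0, cx - w / 2), y1 = max(0, cy - h / 2),
           x2 = min(cfg$imageWidth, cx + w / 2),
           y2 = min(cfg$imageHeight, cy + h / 2))
    round(b)
}

#' Generate a synthetic ground-truth annotation
#'
#' Cell counts are Poisson with the configured per-class means; boxes are
#' placed uniformly at random with class-typical sizes (RBC overlaps are
#' allowed, as in a real smear). True platelets are rejection-sampled to
#' pairwise IOU at or below `plateletMaxIou`. Deterministic given the seed.
#'
#' @param cfg a [synthConfig()].
#' @param imageId identifier for the generated image.
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return An [AnnotationSet][AnnotationSet-class].
#' @export
generateAnnotation <- function(cfg = synthConfig(), imageId = "synth-0001",
                               seed = cfg$seed) {
    stopifnot(inherits(cfg, "SynthConfig"))
    withSeed(seed, {
        rows <- list()
        for (cls in names(cfg$classMeans)) {
            n <- stats::rpois(1, cfg$classMeans[[cls]])
            if (n == 0) next
            placed <- NULL
            for (i in seq_len(n)) {
                reject <- cls == "Platelets" && !is.na(cfg$plateletMaxIou)
                for (try in seq_len(200L)) {
                    b <- .sampleBox(cfg, cls)
                    if (!reject || is.null(placed) ||
                        all(boxIou(as.data.frame(as.list(b)), placed) <=
                            cfg$plateletMaxIou))
                        break
                    if (try == 200L)
                        stop("could not place a non-overlapping platelet; ",
                             "lower classMeans or raise plateletMaxIou")
                }
                placed <- rbind(placed, as.data.frame(as.list(b)))
            }
            placed$label <- cls
            rows[[cls]] <- placed
        }
        objects <- if (length(rows)) {
            df <- do.call(rbind, rows)
            df[, c("label", "x1", "y1", "x2", "y2")]
        } else emptyObjectFrame()
        annotationSet(imageId, objects, imageWidth = cfg$imageWidth,
                      imageHeight = cfg$imageHeight)
    })
}

#' Simulate noisy detector output for an annotated image
#'
#' The oracle detector: each ground-truth cell survives with probability
#' `1 - falseNegativeRate`, gets independent Normal corner jitter and a
#' confidence draw from the true-positive range; Poisson-many spurious
#' boxes of random class are added with confidences from the
#' false-positive range; and each surviving platelet spawns a shifted
#' near-duplicate with probability `duplicateRate` (duplicate IOU with its
#' source > 0.10 by construction). The returned detections carry an
#' `origin` column (`"tp"`, `"dup"`, `"fp"`). Deterministic given the seed.
#'
#' @param a an [AnnotationSet][AnnotationSet-class].
#' @param noise a [noiseConfig()].
#' @param cfg a [synthConfig()] (used for spurious-box sizes).
#' @param seed RNG seed; defaults to `noise$seed`.
#' @return A [DetectionSet][DetectionSet-class].
#' @export
simulateDetections <- function(a, noise = noiseConfig(), cfg = synthConfig(),
                               seed = noise$seed) {
    stopifnot(methods::is(a, "AnnotationSet"), inherits(noise, "NoiseConfig"))
    W <- imageWidth(a); H <- imageHeight(a)
    rconf <- function(n, range) round(stats::runif(n, range[1], range[2]),
                                      noise$confidenceDigits)
    withSeed(seed, {
        obj <- annotationObjects(a)
        out <- list()
        if (nrow(obj)) {
            keep <- stats::runif(nrow(obj)) > noise$falseNegativeRate
            tp <- obj[keep, , drop = FALSE]
            if (nrow(tp)) {
                sd <- noise$localizationJitterSd
                jit <- function(v) v + stats::rnorm(length(v), 0, sd)
                x1 <- jit(tp$x1); x2 <- jit(tp$x2)
                y1 <- jit(tp$y1); y2 <- jit(tp$y2)
                # jitter must not invert a box
                xlo <- pmin(x1, x2); xhi <- pmax(x1, x2)
                ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
                eps <- xhi - xlo < 1; xhi[eps] <- xlo[eps] + 1
                eps <- yhi - ylo < 1; yhi[eps] <- ylo[eps] + 1
                conf <- rconf(nrow(tp), noise$tpConfidence)
                out$tp <- data.frame(image_id = imageId(a), label = tp$label,
                                     confidence = conf, x1 = xlo, y1 = ylo,
                                     x2 = xhi, y2 = yhi, origin = "tp",
                                     stringsAsFactors = FALSE)
                plt <- which(out$tp$label == "Platelets")
                dup <- plt[stats::runif(length(plt)) < noise$duplicateRate]
                if (length(dup)) {
                    src <- out$tp[dup, , drop = FALSE]
                    w <- src$x2 - src$x1; h <- src$y2 - src$y1
                    # shift 30% of width / 10% of height toward the interior:
                    # IOU with the source ~ 0.44, well above the 10% cutoff
                    sx <- ifelse((src$x1 + src$x2) / 2 < W / 2, 1, -1) * 0.3 * w
                    sy <- ifelse((src$y1 + src$y2) / 2 < H / 2, 1, -1) * 0.1 * h
                    dconf <- pmax(0.05, src$confidence -
                                            stats::runif(nrow(src), 0.05, 0.2))
                    out$dup <- data.frame(image_id = imageId(a),
                                          label = "Platelets",
                                          confidence = round(dconf,
                                                             noise$confidenceDigits),
                                          x1 = src$x1 + sx, y1 = src$y1 + sy,
                                          x2 = src$x2 + sx, y2 = src$y2 + sy,
                                          origin = "dup",
                                          stringsAsFactors = FALSE)
                }
            }
        }
        nfp <- stats::rpois(1, noise$falsePositiveRate)
        if (nfp > 0) {
            labs <- sample(names(cfg$classMeans), nfp, replace = TRUE)
            boxes <- do.call(rbind, lapply(labs, function(cl)
                as.data.frame(as.list(.sampleBox(cfg, cl)))))
            out$fp <- data.frame(image_id = imageId(a), label = labs,
                                 confidence = rconf(nfp, noise$fpConfidence),
                                 boxes, origin = "fp",
                                 stringsAsFactors = FALSE)
        }
        df <- if (length(out)) do.call(rbind, out) else
            cbind(emptyDetectionFrame(), origin = character())
        rownames(df) <- NULL
        detectionSet(df)
    })
}

#' Generate a synthetic dataset with oracle detections
#'
#' Draws `n` annotated images and, when `noise` is supplied, the matching
#' oracle-detector output. A single seed drives the whole dataset.
#'
#' @param n number of images.
#' @param cfg a [synthConfig()].
#' @param noise a [noiseConfig()], or `NULL` for annotations only.
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @param idPrefix image-id prefix.
#' @return List with `annotations` (named list of
#'   [AnnotationSet][AnnotationSet-class]) and `detections` (a combined
#'   [DetectionSet][DetectionSet-class], or `NULL`).
#' @export
generateDataset <- function(n, cfg = synthConfig(), noise = NULL,
                            seed = cfg$seed, idPrefix = "img") {
    withSeed(seed, {
        anns <- list(); dets <- list()
        for (i in seq_len(n)) {
            id <- sprintf("%s-%04d", idPrefix, i)
            a <- generateAnnotation(cfg, imageId = id, seed = NULL)
            anns[[id]] <- a
            if (!is.null(noise))
                dets[[id]] <- detections(simulateDetections(a, noise, cfg,
                                                            seed = NULL))
        }
        det <- NULL
        if (!is.null(noise)) {
            df <- do.call(rbind, dets)
            rownames(df) <- NULL
            det <- detectionSet(df)
        }
        list(annotations = anns, detections = det)
    })
}
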