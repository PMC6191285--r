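test_that("segmentation recovers count, centroids and intensities", {
    cfg <- simulationConfig(seed = 3, pixelSize = 50)
    pos <- gridCentres(23, 192, 192, 20)
    tru <- granuleTruth(y = pos$y, x = pos$x, radius = 300, enrichment = 21)
    sim <- simulateGranuleImage(cfg, tru, backgroundLevel = 200,
                                imageDim = c(192, 192))
    rec <- segmentGranules(sim$image, minArea = 10000)
    expect_equal(nrow(rec), 23L)
    # centroids within 0.5 px of truth (order-free nearest matching)
    d <- sqrt(outer(rec$y, tru$y, "-")^2 + outer(rec$x, tru$x, "-")^2)
    expect_lt(max(apply(d, 1, min)), 0.5)

    # uniform image -> empty record table, not an error
    flat <- ImageStack(matrix(100, 64, 64), pixelSize = 50)
    expect_equal(nrow(segmentGranules(flat)), 0L)
    # non-finite pixels are rejected
    bad <- matrix(100, 16, 16); bad[3, 3] <- NaN
    expect_error(segmentGranules(ImageStack(bad)), "non-finite")
})

test_that("total intensity is recovered within 1% when PSF tails are captured", {
    cfg <- simulationConfig(seed = 9, pixelSize = 50, psfSigma = 1)
    pos <- gridCentres(9, 160, 160, 25)
    tru <- granuleTruth(y = pos$y, x = pos$x, radius = 350, enrichment = 15)
    sim <- simulateGranuleImage(cfg, tru, backgroundLevel = 100,
                                imageDim = c(160, 160))
    rec <- segmentGranules(sim$image, minArea = 10000, measureDilation = 4)
    expect_equal(nrow(rec), 9L)
    d <- sqrt(outer(rec$y, sim$truths$y, "-")^2 +
              outer(rec$x, sim$truths$x, "-")^2)
    truthTotal <- sim$truths$rendered_total[apply(d, 1, which.min)]
    expect_lt(max(abs(rec$net_intensity - truthTotal) / truthTotal), 0.01)
})

test_that("area-to-diameter conversions follow both conventions", {
    expect_equal(round(areaToDiameter(91797), 1), 606.0)
    expect_equal(round(areaToDiameter(44533), 1), 422.1)
    expect_equal(areaToDiameter(pi, "circular"), 2)
    expect_equal(areaToDiameter(0), 0)
    expect_error(areaToDiameter(-1), ">= 0")
})

test_that("fold enrichment measures ratios and is scale invariant", {
    cfg <- simulationConfig(seed = 3, pixelSize = 50)
    tru <- granuleTruth(y = c(30, 90), x = c(30, 90), radius = 400,
                        enrichment = 21)
    sim <- simulateGranuleImage(cfg, tru, backgroundLevel = 100,
                                imageDim = c(128, 128))
    g <- roiDiscs(128, 128, tru$y, tru$x, 6)
    r <- roiDiscs(128, 128, c(30, 90), c(90, 30), 6)
    e <- foldEnrichment(sim$image, g, r)
    expect_equal(foldEnrichment(e), 21)
    # identical ROI sets give exactly 1
    e1 <- foldEnrichment(sim$image, g, g)
    expect_equal(foldEnrichment(e1), 1)
    # invariance under global intensity rescaling
    scaled <- ImageStack(imgData(sim$image) * 7.3, pixelSize = 50)
    e2 <- foldEnrichment(scaled, g, r)
    expect_equal(foldEnrichment(e2), foldEnrichment(e))
    # zero reference is an explicit error
    dark <- ImageStack(matrix(0, 128, 128), pixelSize = 50)
    expect_error(foldEnrichment(dark, g, r), "zero")
    expect_error(foldEnrichment(sim$image, matrix(0L, 128, 128), r), "empty")
})

test_that("fold enrichment recovers 25x truth within 10% under Poisson noise", {
    folds <- vapply(1:3, function(s) {
        cfg <- simulationConfig(seed = s, pixelSize = 50, poissonNoise = TRUE)
        pos <- gridCentres(18, 192, 192, 20)
        tru <- granuleTruth(y = pos$y, x = pos$x, radius = 300,
                            enrichment = 25)
        sim <- simulateGranuleImage(cfg, tru, backgroundLevel = 200,
                                    imageDim = c(192, 192))
        rec <- segmentGranules(sim$image, minArea = 10000)
        g <- roiDiscs(192, 192, rec$y, rec$x, sqrt(rec$area_nm2 / pi) / 50)
        # reference ROIs midway between granule grid rows: far from any granule
        gy <- seq(20, 171, length.out = 5)
        mid <- head(gy, -1) + diff(gy) / 2
        ref <- roiDiscs(192, 192, rep(mid, 5), rep(gy, each = 4), 3)
        foldEnrichment(foldEnrichment(sim$image, g, ref,
                                      referenceKind = "nucleoplasm"))
    }, numeric(1))
    expect_true(all(abs(folds - 25) / 25 < 0.1))
})

test_that("nucleoplasmic and granular fractions partition nuclear signal", {
    # nucleus with a known photon budget: 30% outside granules
    nuc <- matrix(FALSE, 64, 64); nuc[10:54, 10:54] <- TRUE
    gr <- matrix(FALSE, 64, 64); gr[20:29, 20:29] <- TRUE
    img <- matrix(0, 64, 64)
    img[gr] <- 700 / sum(gr)        # 70% of photons in granules
    img[nuc & !gr] <- 300 / sum(nuc & !gr)
    stack <- ImageStack(img, pixelSize = 50)
    p <- nucleoplasmicFraction(stack, nuc, gr)
    expect_equal(as.numeric(p), 30, tolerance = 1e-9)
    expect_equal(as.numeric(p) + attr(p, "granularPercent"), 100)
    # all signal in granules -> 0%; no granules -> 100%
    expect_equal(as.numeric(nucleoplasmicFraction(
        ImageStack(ifelse(gr, 1, 0) + ifelse(nuc & !gr, 0, 0)), nuc, gr)), 0)
    expect_equal(as.numeric(nucleoplasmicFraction(
        ImageStack(ifelse(nuc, 1, 0)), nuc, matrix(FALSE, 64, 64))), 100)
    expect_error(nucleoplasmicFraction(ImageStack(matrix(0, 64, 64)), nuc, gr),
                 "zero")
    expect_error(nucleoplasmicFraction(stack, gr, nuc), "inside")
})

test_that("granule classification separates hollow, small and big", {
    cfg <- simulationConfig(seed = 2, pixelSize = 50)
    tru <- granuleTruth(y = c(30, 30, 95), x = c(30, 95, 30),
                        radius = c(500, 250, 1100),
                        shellFraction = c(0.4, 0, 0), enrichment = 15)
    sim <- simulateGranuleImage(cfg, tru, 100, imageDim = c(160, 160))
    rec <- segmentGranules(sim$image, minArea = 5000)
    rec <- rec[order(-rec$area_nm2), ]
    # diameters under the paper convention: 2 sqrt(pi r^2) = 2 r sqrt(pi)
    expect_equal(rec$class_label,
                 c("big_nonhollow", "hollow", "small"))
    expect_lt(rec$hollow_dip_ratio[2], 0.7)
    # tiny granule: unclassified
    rec1 <- rec[3, ]; rec1$area_nm2 <- (50 * 1)^2; rec1$y <- 95; rec1$x <- 30
    expect_equal(as.character(classifyGranule(rec1, sim$image)),
                 "unclassified")
})

test_that("line profiles measure top-hat and blurred granule sizes", {
    m <- matrix(10, 40, 50)
    m[21, 22:31] <- 100    # 10-px top-hat at row 20 (0-based)
    img <- ImageStack(m, pixelSize = 100)
    p <- profileSize(img, from = c(20, 5), to = c(20, 45),
                     backgroundStats = c(mean = 10, sd = 1))
    expect_equal(p$size, 1000)
    expect_equal(p$totalIntensity, 10 * 100)
    # all-background profile errors
    expect_error(profileSize(img, from = c(5, 5), to = c(5, 45),
                             backgroundStats = c(mean = 10, sd = 1)),
                 "no granule")
    # two granules on the line: ambiguity unless largest-run policy
    m2 <- m; m2[21, 40:42] <- 100
    img2 <- ImageStack(m2, pixelSize = 100)
    expect_error(profileSize(img2, from = c(20, 5), to = c(20, 48),
                             backgroundStats = c(mean = 10, sd = 1)),
                 "multiple")
    p2 <- profileSize(img2, from = c(20, 5), to = c(20, 48),
                      backgroundStats = c(mean = 10, sd = 1),
                      largestRun = TRUE)
    expect_equal(p2$size, 1000)

    # blurred granule of truth radius r: with the edge threshold on the steep
    # half-maximum part of the blurred profile, the measured size is within
    # one PSF sigma of the true diameter 2r (blur oracle: a blurred top-hat
    # crosses half-maximum at the true edge)
    cfg <- simulationConfig(seed = 1, pixelSize = 100, psfSigma = 1.5)
    tru <- granuleTruth(y = 32, x = 32, radius = 800, enrichment = 20)
    sim <- simulateGranuleImage(cfg, tru, 100, imageDim = c(64, 64))
    peak <- max(imgData(sim$image)[1, 1, 1, 33, ])
    halfMaxSd <- (peak - 100) / 2 / 2   # so mean + 2 sd = half maximum
    pb <- profileSize(sim$image, from = c(32, 5), to = c(32, 59),
                      backgroundStats = c(mean = 100, sd = halfMaxSd))
    expect_lt(abs(pb$size - 1600), 1.5 * 100)
})

test_that("colocalization matches co-placed granules and is symmetric", {
    mk <- function(y, x) data.frame(y_nm = y, x_nm = x)
    a <- mk(c(0, 1000, 2000), c(0, 0, 0))
    expect_equal(as.numeric(colocalizationFraction(a, a, 100)), 100)
    b <- mk(c(50000, 60000), c(0, 0))
    expect_equal(as.numeric(colocalizationFraction(a, b, 100)), 0)
    expect_error(colocalizationFraction(mk(numeric(0), numeric(0)), a, 100),
                 "empty")
    # symmetry for bijective matchings
    set.seed(11)
    p <- mk(runif(20, 0, 5000), runif(20, 0, 5000))
    q <- mk(p$y_nm + rnorm(20, 0, 30), p$x_nm + rnorm(20, 0, 30))
    expect_equal(as.numeric(colocalizationFraction(p, q, 200)),
                 as.numeric(colocalizationFraction(q, p, 200)))

    # field built with 95% co-placement recovers ~95%
    set.seed(12)
    n <- 40
    y1 <- runif(n, 0, 40000); x1 <- runif(n, 0, 40000)
    co <- rep(c(TRUE, FALSE), c(38, 2))   # 95% co-placed
    y2 <- ifelse(co, y1 + rnorm(n, 0, 40), y1 + 30000)
    x2 <- ifelse(co, x1 + rnorm(n, 0, 40), x1 + 30000)
    frac <- as.numeric(colocalizationFraction(mk(y1, x1), mk(y2, x2), 300))
    expect_equal(frac, 95, tolerance = 0.03)
})

test_that("3D counting recovers associated-nucleus truth", {
    cs <- simulateCountingStack(simulationConfig(seed = 4), 10, 7)
    expect_equal(as.integer(countAssociatedNuclei(cs$stack)), 7L)
    cs0 <- simulateCountingStack(simulationConfig(seed = 5), 5, 0)
    expect_equal(as.integer(countAssociatedNuclei(cs0$stack)), 0L)
    # empty nuclei channel -> 0, not an error
    empty <- ImageStack(array(10, c(1, 4, 2, 16, 16)))
    expect_equal(as.integer(countAssociatedNuclei(empty)), 0L)
})

test_that("ablation-sized fields reproduce the PGC count contrast", {
    c1 <- simulateCountingStack(simulationConfig(seed = 6), 36, 36,
                                stackDim = c(24, 160, 160))
    c2 <- simulateCountingStack(simulationConfig(seed = 7), 22, 22,
                                stackDim = c(24, 160, 160))
    n1 <- as.integer(countAssociatedNuclei(c1$stack))
    n2 <- as.integer(countAssociatedNuclei(c2$stack))
    expect_equal(n1, 36L)
    expect_equal(n2, 22L)
    expect_equal(percentChange(n1, n2), 100 * (36 - 22) / 36)
})

test_that("tracking links granules and detects intensity-conserving fusion", {
    mk <- function(y, x, I) data.frame(id = seq_along(y), y_nm = y,
                                       x_nm = x, total_intensity = I)
    # two converging granules merge at frame 3 with conserved intensity
    frames <- list(mk(c(0, 1000), c(0, 0), c(50, 60)),
                   mk(c(200, 800), c(0, 0), c(50, 60)),
                   mk(500, 0, 110))
    tk <- trackAndDetectFusion(frames, maxStep = 400)
    expect_equal(nrow(tk$fusions), 1L)
    expect_equal(tk$fusions$frame, 3L)
    # stationary granules: no events, two persistent tracks
    stay <- list(mk(c(0, 1000), c(0, 0), c(50, 60)),
                 mk(c(0, 1000), c(0, 0), c(50, 60)))
    tk2 <- trackAndDetectFusion(stay, maxStep = 400)
    expect_equal(nrow(tk2$fusions), 0L)
    expect_equal(length(unique(tk2$tracks$track)), 2L)
    # merge with non-conserved intensity: warning, no event
    bad <- list(mk(c(0, 1000), c(0, 0), c(50, 60)),
                mk(c(200, 800), c(0, 0), c(50, 60)),
                mk(500, 0, 400))
    expect_warning(tk3 <- trackAndDetectFusion(bad, maxStep = 400),
                   "mismatch")
    expect_equal(nrow(tk3$fusions), 0L)
})
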