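test_that("granule image renders the requested enrichment and geometry", {
    cfg <- simulationConfig(seed = 1, pixelSize = 50)
    tr <- granuleTruth(y = 32, x = 32, radius = 400, enrichment = 21)
    sim <- simulateGranuleImage(cfg, tr, backgroundLevel = 100,
                                imageDim = c(64, 64))
    m <- imgData(sim$image)[1, 1, 1, , ]
    # noiseless, PSF off: interior pixels exactly at enrichment x background
    expect_equal(max(m) / 100, 21)
    expect_equal(m[33, 33], 2100)   # 1-based index of 0-based centre (32, 32)
    expect_equal(m[1, 1], 100)
    # rendered_total bookkeeping: above-background sum over the footprint
    expect_equal(sim$truths$rendered_total, sum(m - 100))

    # hollow granule: centre strictly dimmer than shell before noise
    trH <- granuleTruth(y = 32, x = 32, radius = 400, shellFraction = 0.4,
                        enrichment = 15)
    simH <- simulateGranuleImage(cfg, trH, backgroundLevel = 100,
                                 imageDim = c(64, 64))
    mh <- imgData(simH$image)[1, 1, 1, , ]
    expect_lt(mh[33, 33], max(mh))

    # overlap is rejected unless explicitly allowed
    tr2 <- granuleTruth(y = c(30, 34), x = c(30, 34), radius = 400,
                        enrichment = 10)
    expect_error(simulateGranuleImage(cfg, tr2, 100, imageDim = c(64, 64)),
                 "overlap")
    expect_silent(simulateGranuleImage(cfg, tr2, 100, imageDim = c(64, 64),
                                       allowOverlap = TRUE))
    # footprints must fit inside the image
    trOut <- granuleTruth(y = 2, x = 32, radius = 400, enrichment = 10)
    expect_error(simulateGranuleImage(cfg, trOut, 100, imageDim = c(64, 64)),
                 "inside")
})

test_that("generators are bit-reproducible under a fixed seed", {
    cfg <- simulationConfig(seed = 7, pixelSize = 50, psfSigma = 1,
                            gaussianSigma = 0.02, poissonNoise = TRUE)
    tr <- granuleTruth(y = 32, x = 32, radius = 400, enrichment = 21)
    s1 <- simulateGranuleImage(cfg, tr, 100, imageDim = c(64, 64))
    s2 <- simulateGranuleImage(cfg, tr, 100, imageDim = c(64, 64))
    expect_identical(imgData(s1$image), imgData(s2$image))

    kt <- kineticTruth(mobileFraction = 0.5, rate = 0.1, bleachDepth = 0.8)
    t1 <- simulateFrapTrace(kt, cfg, 100)
    t2 <- simulateFrapTrace(kt, cfg, 100)
    expect_identical(roiIntensity(t1), roiIntensity(t2))

    c1 <- simulateCountingStack(cfg, 5, 3)
    c2 <- simulateCountingStack(cfg, 5, 3)
    expect_identical(imgData(c1$stack), imgData(c2$stack))

    h1 <- simulateDnaHistogram(c(0.5, 0.2, 0.3), nCells = 2000, seed = 3)
    h2 <- simulateDnaHistogram(c(0.5, 0.2, 0.3), nCells = 2000, seed = 3)
    expect_identical(h1$count, h2$count)
})

test_that("noiseless FRAP forward model matches the closed form exactly", {
    a <- 0.436; b <- log(2) / 10.5; depth <- 0.8; kimg <- 0.01; f0 <- 1000
    kt <- kineticTruth(mobileFraction = a, rate = b, bleachDepth = depth,
                       acquisitionBleachRate = kimg, nPre = 5L)
    cfg <- simulationConfig(seed = 1)
    tr <- simulateFrapTrace(kt, cfg, duration = 240, f0 = f0,
                            backgroundLevel = 0)
    tt <- traceTime(tr)
    fb <- f0 * (1 - depth)
    expected <- c(rep(f0, 5),
                  fb + a * (f0 - fb) * (1 - exp(-b * (tt[-(1:5)] - tt[6]))))
    expected <- expected * exp(-kimg * tt)
    expect_lt(max(abs(roiIntensity(tr) - expected)), 1e-10)
    # reference decays with imaging bleach only
    expect_lt(max(abs(referenceIntensity(tr) - f0 * exp(-kimg * tt))), 1e-10)
})

test_that("FRAP limiting regimes behave analytically", {
    cfg <- simulationConfig(seed = 1)
    # a = 1: recovers to F0
    full <- simulateFrapTrace(kineticTruth(1, rate = 0.1, bleachDepth = 0.8),
                              cfg, duration = 300, backgroundLevel = 0)
    expect_equal(tail(roiIntensity(full), 1), 1000, tolerance = 1e-6)
    # a = 0: flat at the bleached level
    immob <- simulateFrapTrace(kineticTruth(0, rate = 0.1, bleachDepth = 0.8),
                               cfg, duration = 100, backgroundLevel = 0)
    post <- roiIntensity(immob)[-(1:5)]
    expect_true(all(abs(post - 200) < 1e-10))
    # value at t1/2 = ln2/b after the bleach is exactly halfway to plateau
    # (rate chosen so t1/2 = 7 s falls on the 1 s frame grid)
    half <- simulateFrapTrace(kineticTruth(0.5, rate = log(2) / 7,
                                           bleachDepth = 0.8),
                              cfg, duration = 100, f0 = 1000,
                              backgroundLevel = 0)
    tt <- traceTime(half); y <- roiIntensity(half)
    i <- which(tt - tt[6] == 7)
    plateau <- 200 + 0.5 * 800
    expect_equal((y[i] - 200) / (plateau - 200), 0.5, tolerance = 1e-12)
})

test_that("FLIP integrator conserves fluorescence and matches expm oracle", {
    K <- matrix(0, 4, 4)
    K[1, 2] <- K[2, 1] <- 0.02; K[2, 3] <- K[3, 2] <- 0.02
    K[3, 4] <- K[4, 3] <- 0.02
    cfg <- simulationConfig(seed = 1)

    # conservation without any bleaching: relative drift < 1e-6 over 240 steps
    ktC <- kineticTruth(0.4, rate = 0.1, bleachRate = 0, couplingMatrix = K)
    fl <- simulateFlip(ktC, cfg, regions = 4, bleachRegion = 1, duration = 240)
    tot <- Reduce(`+`, lapply(fl, roiIntensity))
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)

    # zero coupling: only the bleached region is depleted
    kt0 <- kineticTruth(0.4, rate = 0.1, bleachRate = 0.5,
                        couplingMatrix = matrix(0, 3, 3), nPre = 1L)
    fl0 <- simulateFlip(kt0, cfg, regions = 3, bleachRegion = 2,
                        duration = 60)
    expect_lt(tail(roiIntensity(fl0[[2]]), 1), 10)
    expect_equal(tail(roiIntensity(fl0[[1]]), 1), 1000, tolerance = 1e-9)
    expect_equal(tail(roiIntensity(fl0[[3]]), 1), 1000, tolerance = 1e-9)

    # chain coupling: depletion decreases with graph distance at every frame
    ktA <- kineticTruth(0.8, rate = 0.1, bleachRate = 0.5,
                        couplingMatrix = K, nPre = 1L)
    flA <- simulateFlip(ktA, cfg, regions = 4, bleachRegion = 1,
                        duration = 240)
    f2 <- roiIntensity(flA[[2]]); f3 <- roiIntensity(flA[[3]])
    f4 <- roiIntensity(flA[[4]])
    post <- -(1:2)   # skip pre-bleach and first bleach frame
    expect_true(all(f2[post] <= f3[post] + 1e-9))
    expect_true(all(f3[post] <= f4[post] + 1e-9))

    # accuracy against the matrix-exponential solution of the full system
    skip_if_not_installed("Matrix")
    ktE <- kineticTruth(0.4, rate = 0.1, bleachRate = 0.5,
                        acquisitionBleachRate = 0.005, couplingMatrix = K,
                        nPre = 1L)
    flE <- simulateFlip(ktE, cfg, regions = 4, bleachRegion = 1,
                        duration = 240)
    Fhat <- t(vapply(flE, roiIntensity,
                     numeric(length(traceTime(flE[[1]])))))
    a <- 0.4; f0 <- 1000
    L <- K; diag(L) <- -rowSums(K)
    kb <- c(0.5, 0, 0, 0); kimg <- 0.005
    A <- rbind(cbind(L - diag(kb + kimg), matrix(0, 4, 4)),
               cbind(matrix(0, 4, 4), -diag(kb + kimg)))
    x0 <- c(rep(a * f0, 4), rep((1 - a) * f0, 4))
    times <- traceTime(flE[[1]])
    Fo <- matrix(NA, 4, length(times)); Fo[, 1] <- x0[1:4] + x0[5:8]
    for (i in 2:length(times)) {
        x <- as.vector(Matrix::expm(A * (times[i] - times[1])) %*% x0)
        Fo[, i] <- x[1:4] + x[5:8]
    }
    expect_lt(max(abs(Fhat - Fo)) / f0, 2e-3)
})

test_that("photoconversion redistributes and conserves converted signal", {
    cfg <- simulationConfig(seed = 1)
    # isolated granules retain converted signal (no imaging bleach)
    kt0 <- kineticTruth(0.8, rate = 0.1, couplingMatrix = matrix(0, 3, 3))
    pc0 <- simulatePhotoconversion(kt0, cfg, convertedRegions = 1:3,
                                   duration = 230)
    expect_lt(max(abs(pc0$converted - pc0$converted[, 1])), 1e-9)

    # coupling: converted signal appears elsewhere, total conserved
    K <- matrix(0.02, 3, 3); diag(K) <- 0
    ktc <- kineticTruth(0.8, rate = 0.1, couplingMatrix = K)
    pc <- simulatePhotoconversion(ktc, cfg, convertedRegions = 1,
                                  duration = 230)
    expect_gt(pc$converted[2, ncol(pc$converted)], 1)
    tot <- colSums(pc$converted)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)

    # converting every region leaves no redistribution gradient
    pcAll <- simulatePhotoconversion(ktc, cfg, convertedRegions = 1:3,
                                     duration = 230)
    expect_lt(max(abs(pcAll$converted - pcAll$converted[, 1])), 1e-6)
    expect_error(simulatePhotoconversion(ktc, cfg, convertedRegions = integer(0),
                                         duration = 10), "non-empty")
})

test_that("counting-stack generator places the requested truth", {
    cfg <- simulationConfig(seed = 4)
    cs <- simulateCountingStack(cfg, 10, 7)
    expect_equal(unname(cs$truth), c(10, 7))
    expect_equal(dim(cs$stack)[3], 2L)
    # no association: germ channel is pure background
    cs0 <- simulateCountingStack(simulationConfig(seed = 5), 5, 0)
    germ <- imgData(cs0$stack)[1, , 2, , ]
    expect_equal(max(germ), min(germ))
    expect_error(simulateCountingStack(cfg, 3, 4), "<=")
})

test_that("DNA-content histogram generator matches its mixture definition", {
    # pure G1 and pure G2/M are unimodal at the right positions
    h1 <- simulateDnaHistogram(c(1, 0, 0), g1Mean = 200, nCells = 5000,
                               seed = 1)
    expect_equal(h1$bin_center[which.max(h1$count)], 200, tolerance = 0.05)
    h2 <- simulateDnaHistogram(c(0, 0, 1), g1Mean = 200, nCells = 5000,
                               seed = 1)
    expect_equal(h2$bin_center[which.max(h2$count)], 400, tolerance = 0.05)

    # Monte-Carlo tally: mass below 1.5 g1Mean = G1 + lower half of S
    # (sub-population means are symmetric about 1.5 g1Mean)
    h <- simulateDnaHistogram(c(0.5, 0.2, 0.3), g1Mean = 200, cv = 0.05,
                              nCells = 20000, seed = 2)
    vals <- attr(h, "values")
    expect_equal(mean(vals < 300), 0.5 + 0.2 / 2, tolerance = 0.02)

    expect_error(simulateDnaHistogram(c(0.5, 0.2, 0.2), nCells = 100),
                 "sum to 1")
    expect_error(simulateDnaHistogram(c(0.5, 0.2, 0.3), cv = 0), "cv")
})
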