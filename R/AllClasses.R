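#' @import methods
NULL

#' ImageStack: an n-dimensional fluorescence image with physical calibration
#'
#' Container for time-lapse / z-stack fluorescence data. The pixel array is
#' always stored with the fixed axis order \code{(t, z, channel, y, x)};
#' axes that are absent in the raw data have length one. Pixel centres sit at
#' integer coordinates and indices are 0-based in all reported centroids, so
#' a granule centred on pixel (10, 20) has centroid \code{c(y = 10, x = 20)}.
#'
#' @slot imgData 5-dimensional numeric array, axis order (t, z, channel, y, x).
#' @slot pixelSize physical pixel size in nm per pixel.
#' @slot frameInterval time between consecutive frames in seconds.
#'
#' @seealso [ImageStack()] for construction, [readImageStack()] for TIFF input.
#' @export
setClass("ImageStack",
         representation(imgData = "array",
                        pixelSize = "numeric",
                        frameInterval = "numeric"),
         prototype(pixelSize = 1, frameInterval = 1))

setValidity("ImageStack", function(object) {
    msg <- NULL
    if (length(dim(object@imgData)) != 5L)
        msg <- c(msg, "imgData must have 5 dimensions (t, z, channel, y, x)")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive number")
    if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
        object@frameInterval <= 0)
        msg <- c(msg, "frameInterval must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' Construct an ImageStack
#'
#' Accepts a matrix (interpreted as a single-frame, single-channel (y, x)
#' image), a 3-dimensional array (interpreted as (z, y, x)) or a full
#' 5-dimensional (t, z, channel, y, x) array.
#'
#' @param data numeric matrix or array.
#' @param pixelSize pixel size in nm/pixel.
#' @param frameInterval frame interval in seconds.
#' @return An [ImageStack-class] object.
#' @examples
#' img <- ImageStack(matrix(100, 32, 32), pixelSize = 50)
#' dim(img)
#' @export
ImageStack <- function(data, pixelSize = 1, frameInterval = 1) {
    d <- dim(data)
    if (is.null(d) || length(d) == 2L) {
        data <- array(data, c(1L, 1L, 1L, dim(as.matrix(data))))
    } else if (length(d) == 3L) {
        data <- array(data, c(1L, 1L, d))   # (z, y, x) -> singleton t, c
        data <- aperm(data, c(1L, 3L, 2L, 4L, 5L))
    } else if (length(d) != 5L) {
        stop("data must be a matrix, a (z, y, x) array or a 5-d (t, z, c, y, x) array")
    }
    new("ImageStack", imgData = data, pixelSize = as.numeric(pixelSize),
        frameInterval = as.numeric(frameInterval))
}

#' SimulationConfig: acquisition and noise parameters for the generators
#'
#' Holds the parameters shared by all synthetic-data generators: random seed,
#' physical calibration, Gaussian point-spread blur and the Poisson-Gaussian
#' noise model. An identical configuration (including the seed) always
#' reproduces bit-identical output.
#'
#' @slot seed integer random seed.
#' @slot pixelSize nm per pixel.
#' @slot frameInterval seconds between frames.
#' @slot psfSigma Gaussian PSF standard deviation in pixels (0 disables blur).
#' @slot gaussianSigma additive Gaussian read-noise standard deviation,
#'   expressed as a fraction of the noiseless signal (0 disables).
#' @slot poissonNoise logical; apply Poisson shot noise before Gaussian noise.
#' @export
setClass("SimulationConfig",
         representation(seed = "integer", pixelSize = "numeric",
                        frameInterval = "numeric", psfSigma = "numeric",
                        gaussianSigma = "numeric", poissonNoise = "logical"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
    if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
    if (object@gaussianSigma < 0) msg <- c(msg, "gaussianSigma must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SimulationConfig
#'
#' @param seed integer random seed.
#' @param pixelSize nm/pixel (default 50, a typical confocal sampling).
#' @param frameInterval seconds per frame (default 1 s, the acquisition rate
#'   used for the photobleaching experiments this package models).
#' @param psfSigma Gaussian PSF sigma in pixels.
#' @param gaussianSigma Gaussian noise sd as a fraction of signal.
#' @param poissonNoise apply Poisson shot noise.
#' @return A [SimulationConfig-class] object.
#' @examples
#' simulationConfig(seed = 1, gaussianSigma = 0.02)
#' @export
simulationConfig <- function(seed = 1L, pixelSize = 50, frameInterval = 1,
                             psfSigma = 0, gaussianSigma = 0,
                             poissonNoise = FALSE) {
    new("SimulationConfig", seed = as.integer(seed),
        pixelSize = as.numeric(pixelSize),
        frameInterval = as.numeric(frameInterval),
        psfSigma = as.numeric(psfSigma),
        gaussianSigma = as.numeric(gaussianSigma),
        poissonNoise = isTRUE(poissonNoise))
}

#' KineticTruth: ground-truth exchange kinetics for simulated photobleaching
#'
#' Parameterises the compartmental forward model behind the FRAP, FLIP and
#' photoconversion generators. The mobile fraction is the proportion of
#' fluorophore that exchanges with the surroundings; the remainder is
#' immobile and never leaves its compartment. The recovery rate relates to
#' the half-time of recovery by t1/2 = ln(2) / rate.
#'
#' @slot mobileFraction mobile fraction a, dimensionless in [0, 1].
#' @slot rate exchange rate constant b in 1/s.
#' @slot bleachDepth fraction of ROI fluorescence removed by the bleach
#'   pulse, in [0, 1] (FRAP).
#' @slot bleachRate continuous bleaching rate constant in 1/s applied to the
#'   targeted region (FLIP).
#' @slot acquisitionBleachRate unintentional imaging bleach rate k_img in 1/s,
#'   applied to every compartment.
#' @slot couplingMatrix symmetric matrix of exchange rate constants (1/s)
#'   between regions; off-diagonal entries must be non-negative.
#' @slot nPre number of pre-bleach frames.
#' @export
setClass("KineticTruth",
         representation(mobileFraction = "numeric", rate = "numeric",
                        bleachDepth = "numeric", bleachRate = "numeric",
                        acquisitionBleachRate = "numeric",
                        couplingMatrix = "matrix", nPre = "integer"))

setValidity("KineticTruth", function(object) {
    msg <- NULL
    if (object@mobileFraction < 0 || object@mobileFraction > 1)
        msg <- c(msg, "mobileFraction must lie in [0, 1]")
    if (object@rate < 0) msg <- c(msg, "rate must be >= 0")
    if (object@bleachDepth < 0 || object@bleachDepth > 1)
        msg <- c(msg, "bleachDepth must lie in [0, 1]")
    if (object@bleachRate < 0) msg <- c(msg, "bleachRate must be >= 0")
    if (object@acquisitionBleachRate < 0)
        msg <- c(msg, "acquisitionBleachRate must be >= 0")
    K <- object@couplingMatrix
    if (nrow(K) != ncol(K))
        msg <- c(msg, "couplingMatrix must be square")
    else {
        if (!isTRUE(all.equal(K, t(K))))
            msg <- c(msg, "couplingMatrix must be symmetric")
        if (any(K[row(K) != col(K)] < 0))
            msg <- c(msg, "couplingMatrix off-diagonal entries must be >= 0")
    }
    if (object@nPre < 0L) msg <- c(msg, "nPre must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a KineticTruth
#'
#' @param mobileFraction mobile fraction in [0, 1].
#' @param rate recovery rate constant b (1/s). Alternatively supply
#'   \code{halfTime}; the two are related by b = ln(2)/t1/2.
#' @param halfTime recovery half-time in seconds (used when \code{rate} is
#'   missing).
#' @param bleachDepth FRAP bleach depth in [0, 1].
#' @param bleachRate FLIP continuous bleach rate (1/s).
#' @param acquisitionBleachRate imaging bleach rate k_img (1/s).
#' @param couplingMatrix symmetric inter-region exchange matrix (1/s).
#' @param nPre pre-bleach frame count (default 5, as in the acquisition
#'   protocol this package models).
#' @return A [KineticTruth-class] object.
#' @examples
#' kineticTruth(mobileFraction = 0.436, halfTime = 10.5, bleachDepth = 0.8)
#' @export
kineticTruth <- function(mobileFraction, rate = NULL, halfTime = NULL,
                         bleachDepth = 0.8, bleachRate = 0,
                         acquisitionBleachRate = 0,
                         couplingMatrix = matrix(0, 1, 1), nPre = 5L) {
    if (is.null(rate)) {
        if (is.null(halfTime))
            stop("supply either 'rate' or 'halfTime'")
        rate <- log(2) / halfTime
    }
    new("KineticTruth", mobileFraction = as.numeric(mobileFraction),
        rate = as.numeric(rate), bleachDepth = as.numeric(bleachDepth),
        bleachRate = as.numeric(bleachRate),
        acquisitionBleachRate = as.numeric(acquisitionBleachRate),
        couplingMatrix = couplingMatrix, nPre = as.integer(nPre))
}

#' RecoveryTrace: time-resolved intensities from a photobleaching experiment
#'
#' One bleach (or region) ROI intensity time series, with optional reference
#' and background ROI series on the same uniform time grid, and the number of
#' pre-bleach frames.
#'
#' @slot time time points in seconds, strictly increasing, uniform.
#' @slot roi intensity of the bleached/measured ROI (counts).
#' @slot reference intensity of an unbleached reference ROI (counts), or
#'   length-0 if absent.
#' @slot background background ROI intensity (counts), or length-0 if absent.
#' @slot nPre number of pre-bleach frames.
#' @slot label free-text label.
#' @export
setClass("RecoveryTrace",
         representation(time = "numeric", roi = "numeric",
                        reference = "numeric", background = "numeric",
                        nPre = "integer", label = "character"))

setValidity("RecoveryTrace", function(object) {
    msg <- NULL
    n <- length(object@time)
    if (n < 2L) msg <- c(msg, "trace needs at least two time points")
    else {
        dt <- diff(object@time)
        if (any(dt <= 0)) msg <- c(msg, "time must be strictly increasing")
        else if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
            msg <- c(msg, "time grid must be uniform (1e-9 relative tolerance)")
    }
    if (length(object@roi) != n)
        msg <- c(msg, "roi and time must have equal length")
    if (length(object@reference) && length(object@reference) != n)
        msg <- c(msg, "reference must be empty or match time length")
    if (length(object@background) && length(object@background) != n)
        msg <- c(msg, "background must be empty or match time length")
    if (object@nPre < 1L) msg <- c(msg, "nPre must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct a RecoveryTrace
#'
#' @param time time points (s), uniform grid.
#' @param roi measured ROI intensities.
#' @param reference optional reference ROI intensities.
#' @param background optional background ROI intensities.
#' @param nPre pre-bleach frame count.
#' @param label trace label.
#' @return A [RecoveryTrace-class] object.
#' @export
RecoveryTrace <- function(time, roi, reference = numeric(0),
                          background = numeric(0), nPre = 5L, label = "") {
    new("RecoveryTrace", time = as.numeric(time), roi = as.numeric(roi),
        reference = as.numeric(reference), background = as.numeric(background),
        nPre = as.integer(nPre), label = as.character(label))
}

#' FitResult: parameters of a single-exponential FRAP recovery fit
#'
#' Result of fitting f(t) = a (1 - exp(-b t)) to a normalized, averaged
#' recovery curve. The mobile fraction is reported in percent (0-100 scale);
#' the half-time is derived from the rate as t1/2 = ln(2)/b, never fitted
#' independently.
#'
#' @slot mobileFraction fitted plateau a, percent.
#' @slot rate fitted rate constant b, 1/s.
#' @slot halfTime ln(2)/b, seconds.
#' @slot se named numeric: standard errors of a (percent) and b (1/s) from
#'   the fit covariance.
#' @slot rSquared coefficient of determination of the fit.
#' @slot nCurves number of individual curves averaged into the fitted curve.
#' @export
setClass("FitResult",
         representation(mobileFraction = "numeric", rate = "numeric",
                        halfTime = "numeric", se = "numeric",
                        rSquared = "numeric", nCurves = "integer"))

setValidity("FitResult", function(object) {
    msg <- NULL
    if (object@mobileFraction < 0 || object@mobileFraction > 110)
        msg <- c(msg, "mobileFraction (percent) outside [0, 110]: over-recovery")
    if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
    if (abs(object@halfTime * object@rate - log(2)) > 1e-12 * log(2))
        msg <- c(msg, "halfTime must equal ln(2)/rate")
    if (is.null(msg)) TRUE else msg
})

#' FlipResult: per-region fluorescence-loss quantification
#'
#' Percent-remaining curves per region (100 at the anchor frame by
#' construction), endpoint depletion per region, the mean depletion of the
#' no-specimen control, and the control-corrected redistribution (region
#' depletion minus control depletion, floored at zero).
#'
#' @slot time time points (s).
#' @slot percentRemaining matrix, regions x time, percent of the anchor value.
#' @slot endpointDepletion per-region 100 - final percent remaining.
#' @slot controlDepletion mean endpoint depletion of control traces (NA when
#'   no control was supplied).
#' @slot correctedRedistribution per-region depletion minus control
#'   depletion, floored at 0 (NA without control).
#' @export
setClass("FlipResult",
         representation(time = "numeric", percentRemaining = "matrix",
                        endpointDepletion = "numeric",
                        controlDepletion = "numeric",
                        correctedRedistribution = "numeric"))

#' EnrichmentResult: fold enrichment of granules over a reference compartment
#'
#' @slot granuleMean mean per-area intensity over granule ROIs.
#' @slot referenceMean mean per-area intensity over reference ROIs.
#' @slot foldEnrichment granuleMean / referenceMean.
#' @slot referenceKind one of "intergranular", "somatic_cytoplasm",
#'   "nucleoplasm", "somatic_nucleoplasm".
#' @slot nGranules number of granule ROIs.
#' @slot nReference number of reference ROIs.
#' @export
setClass("EnrichmentResult",
         representation(granuleMean = "numeric", referenceMean = "numeric",
                        foldEnrichment = "numeric", referenceKind = "character",
                        nGranules = "integer", nReference = "integer"))

setValidity("EnrichmentResult", function(object) {
    msg <- NULL
    if (object@foldEnrichment < 0) msg <- c(msg, "foldEnrichment must be >= 0")
    rel <- abs(object@foldEnrichment -
               object@granuleMean / object@referenceMean)
    if (!is.finite(rel) || rel > 1e-12 * max(1, object@foldEnrichment))
        msg <- c(msg, "foldEnrichment must equal granuleMean/referenceMean")
    if (is.null(msg)) TRUE else msg
})

#' CellCycleFit: Dean-Jett-Fox-style decomposition of a DNA-content histogram
#'
#' @slot fractions named percent vector (G1, S, G2M), summing to 100.
#' @slot g1Mean fitted G1 mean in channel units.
#' @slot g2Mean G2/M mean, constrained to exactly 2 x g1Mean.
#' @slot cv shared coefficient of variation of the Gaussian components.
#' @slot residualNorm residual norm of the least-squares mixture fit.
#' @export
setClass("CellCycleFit",
         representation(fractions = "numeric", g1Mean = "numeric",
                        g2Mean = "numeric", cv = "numeric",
                        residualNorm = "numeric"))

setValidity("CellCycleFit", function(object) {
    msg <- NULL
    if (abs(sum(object@fractions) - 100) > 0.01)
        msg <- c(msg, "fractions must sum to 100 (+/- 0.01)")
    if (abs(object@g2Mean - 2 * object@g1Mean) > 1e-9 * object@g1Mean)
        msg <- c(msg, "g2Mean must equal 2 * g1Mean (ploidy constraint)")
    if (is.null(msg)) TRUE else msg
})
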