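#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("imgData", "ImageStack", function(x) x@imgData)

#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("pixelSize", "SimulationConfig", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("frameInterval", "ImageStack", function(x) x@frameInterval)

#' @rdname accessors
#' @export
setMethod("frameInterval", "SimulationConfig", function(x) x@frameInterval)

#' @describeIn ImageStack dimensions of the (t, z, channel, y, x) array.
#' @param x an ImageStack.
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@imgData))

#' @rdname accessors
#' @export
setMethod("traceTime", "RecoveryTrace", function(x) x@time)

#' @rdname accessors
#' @export
setMethod("roiIntensity", "RecoveryTrace", function(x) x@roi)

#' @rdname accessors
#' @export
setMethod("referenceIntensity", "RecoveryTrace", function(x) x@reference)

#' @rdname accessors
#' @export
setMethod("backgroundIntensity", "RecoveryTrace", function(x) x@background)

#' @rdname accessors
#' @export
setMethod("nPre", "RecoveryTrace", function(x) x@nPre)

#' @rdname accessors
#' @export
setMethod("nPre", "KineticTruth", function(x) x@nPre)

#' @rdname accessors
#' @export
setMethod("mobileFraction", "FitResult", function(x) x@mobileFraction)

#' @rdname accessors
#' @export
setMethod("mobileFraction", "KineticTruth", function(x) x@mobileFraction)

#' @rdname accessors
#' @export
setMethod("recoveryRate", "FitResult", function(x) x@rate)

#' @rdname accessors
#' @export
setMethod("recoveryRate", "KineticTruth", function(x) x@rate)

#' @rdname accessors
#' @export
setMethod("halfTime", "FitResult", function(x) x@halfTime)

#' @rdname accessors
#' @export
setMethod("halfTime", "KineticTruth", function(x) log(2) / x@rate)

#' @rdname accessors
#' @export
setMethod("stdErrors", "FitResult", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("rSquared", "FitResult", function(x) x@rSquared)

#' @rdname accessors
#' @export
setMethod("foldEnrichment", "EnrichmentResult", function(x) x@foldEnrichment)

#' @rdname accessors
#' @export
setMethod("percentRemaining", "FlipResult", function(x) x@percentRemaining)

#' @rdname accessors
#' @export
setMethod("endpointDepletion", "FlipResult", function(x) x@endpointDepletion)

#' @rdname accessors
#' @export
setMethod("controlDepletion", "FlipResult", function(x) x@controlDepletion)

#' @rdname accessors
#' @export
setMethod("correctedRedistribution", "FlipResult",
          function(x) x@correctedRedistribution)

#' @rdname accessors
#' @export
setMethod("cycleFractions", "CellCycleFit", function(x) x@fractions)

#' Confidence interval for the fitted mobile fraction
#'
#' Wald interval a +/- z * SE(a) on the percent scale, from the fit
#' covariance of a [fitRecovery()] result.
#'
#' @param fit a [FitResult-class].
#' @param level confidence level (default 0.95).
#' @return Numeric length-2 vector (lower, upper), percent.
#' @export
mobileFractionCI <- function(fit, level = 0.95) {
    stopifnot(is(fit, "FitResult"))
    z <- stats::qnorm(1 - (1 - level) / 2)
    fit@mobileFraction + c(-1, 1) * z * fit@se[["a"]]
}

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@imgData)
    cat("ImageStack: ", paste(d, collapse = " x "),
        " (t, z, channel, y, x)\n", sep = "")
    cat("  pixel size: ", object@pixelSize, " nm/px; frame interval: ",
        object@frameInterval, " s\n", sep = "")
    cat("  intensity range: [", format(min(object@imgData)), ", ",
        format(max(object@imgData)), "]\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: seed ", object@seed, ", ", object@pixelSize,
        " nm/px, dt ", object@frameInterval, " s, PSF sigma ",
        object@psfSigma, " px\n", sep = "")
    cat("  noise: Poisson ", if (object@poissonNoise) "on" else "off",
        ", Gaussian sigma ", object@gaussianSigma, " (fraction of signal)\n",
        sep = "")
})

setMethod("show", "KineticTruth", function(object) {
    cat("KineticTruth: mobile fraction ", object@mobileFraction,
        ", rate ", signif(object@rate, 4), "/s (t1/2 ",
        signif(log(2) / object@rate, 4), " s)\n", sep = "")
    cat("  bleach depth ", object@bleachDepth, ", bleach rate ",
        object@bleachRate, "/s, k_img ", object@acquisitionBleachRate,
        "/s, ", nrow(object@couplingMatrix), " region(s), ",
        object@nPre, " pre-bleach frame(s)\n", sep = "")
})

setMethod("show", "RecoveryTrace", function(object) {
    cat("RecoveryTrace '", object@label, "': ", length(object@time),
        " frames, dt ", signif(diff(object@time[1:2]), 4), " s, ",
        object@nPre, " pre-bleach\n", sep = "")
    cat("  reference: ", if (length(object@reference)) "yes" else "no",
        "; background: ", if (length(object@background)) "yes" else "no",
        "\n", sep = "")
})

setMethod("show", "FitResult", function(object) {
    cat("Single-exponential recovery fit (", object@nCurves,
        " curve(s) averaged)\n", sep = "")
    cat(sprintf("  mobile fraction a: %.1f %% (SE %.2f)\n",
                object@mobileFraction, object@se[["a"]]))
    cat(sprintf("  rate b: %.4f /s (SE %.4f);  t1/2 = ln(2)/b = %.2f s\n",
                object@rate, object@se[["b"]], object@halfTime))
    cat(sprintf("  R-squared: %.4f\n", object@rSquared))
})

setMethod("show", "FlipResult", function(object) {
    cat("FLIP analysis: ", nrow(object@percentRemaining), " region(s), ",
        length(object@time), " frames\n", sep = "")
    cat("  endpoint depletion (%): ",
        paste(sprintf("%.1f", object@endpointDepletion), collapse = ", "),
        "\n", sep = "")
    cat("  control depletion (%): ",
        if (is.na(object@controlDepletion)) "none"
        else sprintf("%.1f", object@controlDepletion), "\n", sep = "")
    if (!anyNA(object@correctedRedistribution))
        cat("  corrected redistribution (%): ",
            paste(sprintf("%.1f", object@correctedRedistribution),
                  collapse = ", "), "\n", sep = "")
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("Fold enrichment: %.2f (granule mean %.4g over %s mean %.4g)\n",
                object@foldEnrichment, object@granuleMean,
                object@referenceKind, object@referenceMean))
    cat("  ", object@nGranules, " granule ROI(s), ", object@nReference,
        " reference ROI(s)\n", sep = "")
})

setMethod("show", "CellCycleFit", function(object) {
    cat("Cell-cycle deconvolution (G2 mean constrained to 2 x G1 mean)\n")
    cat(sprintf("  G1 %.1f %%, S %.1f %%, G2/M %.1f %%\n",
                object@fractions[["G1"]], object@fractions[["S"]],
                object@fractions[["G2M"]]))
    cat(sprintf("  G1 mean %.1f, CV %.3f, residual norm %.3g\n",
                object@g1Mean, object@cv, object@residualNorm))
})
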