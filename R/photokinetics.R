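#' @include AllClasses.R
NULL

#' Normalize a FRAP recovery trace
#'
#' Background-subtracts the ROI and reference series, forms the
#' double-normalized curve
#' \deqn{F_n(t) = \frac{F_{roi}(t) / F_{ref}(t)}{\langle F_{roi}/F_{ref}
#'   \rangle_{pre}}}
#' and, in \code{"full_scale"} mode (the default), rescales it to
#' \deqn{F_{fs}(t) = \frac{F_n(t) - F_n(t_{bleach})}{1 - F_n(t_{bleach})}}
#' so that the bleach-frame value is exactly 0 and the pre-bleach mean maps
#' to exactly 1. Full-scale normalization corrects for differences in bleach
#' depth between experiments, so curves from different sessions can be
#' averaged. Because the reference enters as a ratio, acquisition bleaching
#' applied equally to ROI and reference cancels.
#'
#' The bleach frame is identified as the global minimum of the normalized
#' trace within the first three post-bleach frames (a single-pulse protocol
#' puts the minimum immediately after the pulse).
#'
#' @param trace a [RecoveryTrace-class] with a reference series (required)
#'   and optional background series.
#' @param mode \code{"full_scale"} or \code{"double"}.
#' @return A data.frame with columns \code{time} and \code{value}, carrying
#'   attributes \code{nPre}, \code{bleachFrame} (index) and \code{mode}.
#' @export
normalizeFrap <- function(trace, mode = c("full_scale", "double")) {
    stopifnot(is(trace, "RecoveryTrace"))
    mode <- match.arg(mode)
    n <- length(trace@time)
    nPre <- trace@nPre
    if (n <= nPre) stop("trace has no post-bleach frames")
    if (!length(trace@reference))
        stop("reference ROI required for double/full-scale normalization")
    bg <- if (length(trace@background)) trace@background else 0
    roi <- trace@roi - bg
    ref <- trace@reference - bg
    if (any(ref <= 0))
        stop("background-subtracted reference is non-positive")
    ratio <- roi / ref
    fn <- ratio / mean(ratio[seq_len(nPre)])
    win <- (nPre + 1L):min(nPre + 3L, n)
    bleachFrame <- win[which.min(fn[win])]
    if (mode == "double") {
        out <- data.frame(time = trace@time, value = fn)
    } else {
        fb <- fn[bleachFrame]
        if (fb >= 1 - 1e-12)
            stop("no bleach depth: normalized value at bleach frame is >= 1")
        out <- data.frame(time = trace@time, value = (fn - fb) / (1 - fb))
    }
    attr(out, "nPre") <- nPre
    attr(out, "bleachFrame") <- bleachFrame
    attr(out, "mode") <- mode
    out
}

#' Average normalized recovery curves
#'
#' Pointwise mean and standard error of the mean over curves sharing one
#' time grid. No resampling is performed; mismatched grids are an error.
#'
#' @param curves list of [normalizeFrap()] outputs (data.frames with
#'   \code{time} and \code{value}).
#' @return A data.frame with columns \code{time}, \code{mean}, \code{sem},
#'   carrying attributes \code{n}, \code{nPre} and \code{bleachFrame} when
#'   the inputs carry them consistently.
#' @export
aggregateCurves <- function(curves) {
    if (!length(curves)) stop("no curves supplied")
    tgrid <- curves[[1]]$time
    for (cu in curves)
        if (length(cu$time) != length(tgrid) ||
            max(abs(cu$time - tgrid)) > 1e-9 * max(1, max(abs(tgrid))))
            stop("curves do not share a common time grid; no resampling is performed")
    vals <- vapply(curves, function(cu) cu$value, numeric(length(tgrid)))
    vals <- matrix(vals, nrow = length(tgrid))
    nc <- length(curves)
    m <- rowMeans(vals)
    sem <- if (nc > 1) apply(vals, 1, stats::sd) / sqrt(nc)
           else rep(0, length(tgrid))
    out <- data.frame(time = tgrid, mean = m, sem = sem)
    attr(out, "n") <- nc
    np <- unique(vapply(curves, function(cu)
        as.integer(attr(cu, "nPre", exact = TRUE) %||% NA_integer_), integer(1)))
    if (length(np) == 1L && !is.na(np)) {
        # noise can shift the detected minimum of an individual trace by a
        # frame; re-locate the bleach frame on the averaged curve instead
        attr(out, "nPre") <- np
        win <- (np + 1L):min(np + 3L, length(m))
        attr(out, "bleachFrame") <- win[which.min(m[win])]
    } else {
        bf <- unique(vapply(curves, function(cu)
            as.integer(attr(cu, "bleachFrame", exact = TRUE) %||%
                           NA_integer_), integer(1)))
        if (length(bf) == 1L && !is.na(bf)) attr(out, "bleachFrame") <- bf
    }
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a single-exponential recovery curve
#'
#' Nonlinear least squares of f(t) = a (1 - exp(-b t)) on the post-bleach
#' part of a normalized recovery curve, with time re-zeroed at the bleach
#' frame. The mobile fraction a is reported in percent; the half-time is
#' derived as t1/2 = ln(2)/b. Initial values are derivative-free: a0 is the
#' mean of the last 10 percent of the curve and b0 = ln(2) / (first time the
#' curve exceeds a0/2). Standard errors come from the fit covariance.
#'
#' @param curve a data.frame with \code{time} and \code{value} (or
#'   \code{mean}) columns, as produced by [normalizeFrap()] or
#'   [aggregateCurves()]. The bleach frame is taken from the
#'   \code{bleachFrame} attribute; absent that, the curve is assumed to be
#'   post-bleach-only with time already zeroed at the bleach.
#' @return A [FitResult-class].
#' @examples
#' t <- 0:120
#' fit <- fitRecovery(data.frame(time = t, value = 0.5 * (1 - exp(-0.1 * t))))
#' mobileFraction(fit)
#' @export
fitRecovery <- function(curve) {
    y <- curve$value %||% curve$mean
    if (is.null(y)) stop("curve must have a 'value' or 'mean' column")
    bf <- attr(curve, "bleachFrame", exact = TRUE)
    if (is.null(bf)) {
        tt <- curve$time - curve$time[1]
    } else {
        keep <- bf:length(y)
        tt <- curve$time[keep] - curve$time[bf]
        y <- y[keep]
    }
    if (sum(tt > 0) < 5L)
        stop("need at least 5 post-bleach points to fit")
    nTail <- max(1L, ceiling(0.1 * length(y)))
    a0 <- mean(utils::tail(y, nTail))
    if (!is.finite(a0) || a0 <= 0)
        stop("no recovery: curve does not rise above zero")
    iHalf <- which(y > a0 / 2 & tt > 0)[1]
    if (is.na(iHalf))
        stop("no recovery: curve never exceeds half its plateau")
    b0 <- log(2) / tt[iHalf]
    fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * (1 - exp(-b * tt)),
                          data = data.frame(tt = tt, y = y),
                          start = list(a = a0, b = b0),
                          lower = c(a = 0, b = 1e-8),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e)
            stop("recovery fit did not converge (start a=", signif(a0, 3),
                 ", b=", signif(b0, 3), "): ", conditionMessage(e)))
    co <- stats::coef(fit)
    if (co[["b"]] <= 1e-8) stop("no recovery: fitted rate is not positive")
    se <- summary(fit)$coefficients[, "Std. Error"]
    res <- stats::resid(fit)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    new("FitResult",
        mobileFraction = 100 * co[["a"]], rate = co[["b"]],
        halfTime = log(2) / co[["b"]],
        se = c(a = 100 * se[["a"]], b = se[["b"]]),
        rSquared = r2,
        nCurves = as.integer(attr(curve, "n", exact = TRUE) %||% 1L))
}

#' Quantify fluorescence loss in photobleaching (FLIP)
#'
#' Converts each region trace to percent fluorescence remaining relative to
#' its anchor value (the raw time-0 intensity by default, configurable to
#' the pre-bleach mean), computes the endpoint depletion per region, and
#' corrects it by the mean depletion of control traces recorded with the
#' bleach target outside the specimen (depletion due to unintentional
#' imaging bleach). Corrected redistribution is floored at 0; negative
#' corrections are reported via a message. No reference-ROI normalization is
#' applied, in keeping with the FLIP protocol this implements.
#'
#' @param regionTraces list of [RecoveryTrace-class], one per region, on a
#'   shared time grid.
#' @param controlTraces optional list of control [RecoveryTrace-class]; when
#'   absent the correction is skipped with a warning.
#' @param anchor \code{"t0"} (raw first frame, default) or \code{"pre_mean"}
#'   (mean of the pre-bleach frames).
#' @return A [FlipResult-class].
#' @export
flipAnalysis <- function(regionTraces, controlTraces = NULL,
                         anchor = c("t0", "pre_mean")) {
    anchor <- match.arg(anchor)
    if (!length(regionTraces)) stop("no region traces supplied")
    tgrid <- regionTraces[[1]]@time
    pct <- function(tr) {
        if (length(tr@time) != length(tgrid) ||
            max(abs(tr@time - tgrid)) > 1e-9 * max(1, max(abs(tgrid))))
            stop("all traces must share one time grid")
        a <- if (anchor == "t0") tr@roi[1]
             else mean(tr@roi[seq_len(tr@nPre)])
        if (a == 0) stop("zero initial intensity in trace '", tr@label, "'")
        100 * tr@roi / a
    }
    pr <- t(vapply(regionTraces, pct, numeric(length(tgrid))))
    rownames(pr) <- vapply(regionTraces, function(x) x@label, character(1))
    depl <- 100 - pr[, ncol(pr)]
    if (is.null(controlTraces)) {
        warning("no control traces: unintentional-bleaching correction skipped")
        ctrl <- NA_real_
        corr <- rep(NA_real_, length(depl))
    } else {
        cpr <- t(vapply(controlTraces, pct, numeric(length(tgrid))))
        ctrl <- mean(100 - cpr[, ncol(cpr)])
        corr <- depl - ctrl
        if (any(corr < 0))
            message("negative corrected redistribution in ",
                    sum(corr < 0), " region(s); floored at 0")
        corr <- pmax(corr, 0)
    }
    new("FlipResult", time = tgrid, percentRemaining = pr,
        endpointDepletion = unname(depl), controlDepletion = ctrl,
        correctedRedistribution = unname(corr))
}

#' Quantify photoconversion retention and exchange
#'
#' From two-channel photoconversion traces: the retention of each targeted
#' (converted) region is its converted-channel intensity as percent of its
#' first post-conversion value; the appearance in each non-targeted region
#' is its converted-channel intensity as percent of the mean initial
#' intensity of the targeted regions.
#'
#' @param pc output of [simulatePhotoconversion()] or a compatible list with
#'   \code{time} and a \code{converted} regions x frames matrix.
#' @param targeted indices of the converted regions (defaults to
#'   \code{pc$convertedRegions}).
#' @return A list with \code{time}, \code{retention} (matrix, targeted
#'   regions x frames, percent) and \code{appearance} (matrix, non-targeted
#'   regions x frames, percent; zero rows when every region was targeted).
#' @export
photoconversionAnalysis <- function(pc, targeted = pc$convertedRegions) {
    C <- pc$converted
    if (!length(targeted)) stop("no targeted regions given")
    init <- C[targeted, 1]
    if (all(init <= 0))
        stop("zero post-conversion intensity in all targeted regions")
    retention <- 100 * C[targeted, , drop = FALSE] / init
    rownames(retention) <- paste0("region_", targeted)
    others <- setdiff(seq_len(nrow(C)), targeted)
    appearance <- 100 * C[others, , drop = FALSE] / mean(init)
    if (length(others)) rownames(appearance) <- paste0("region_", others)
    list(time = pc$time, retention = retention, appearance = appearance)
}
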