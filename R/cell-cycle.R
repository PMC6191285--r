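#' @include simulate-histogram.R
NULL

# Component design matrix for the DNA-content mixture at parameters
# (g1Mean, cv): columns G1, S (equal-weight average of the 10 sub-Gaussians)
# and G2/M (mean fixed at 2 * g1Mean), evaluated at the bin centres and
# scaled by the bin width so coefficients are cell counts.
.cycleDesign <- function(x, g1Mean, cv, binWidth, nS = 10L) {
    g1 <- stats::dnorm(x, g1Mean, cv * g1Mean)
    g2 <- stats::dnorm(x, 2 * g1Mean, cv * 2 * g1Mean)
    mu <- .sPhaseMeans(g1Mean, nS)
    s <- rowMeans(vapply(mu, function(m) stats::dnorm(x, m, cv * m),
                         numeric(length(x))))
    cbind(G1 = g1, S = s, G2M = g2) * binWidth
}

#' Deconvolve a DNA-content histogram into cell-cycle fractions
#'
#' Least-squares mixture fit in the Dean-Jett-Fox tradition: a G1 Gaussian,
#' a G2/M Gaussian whose mean is constrained to exactly twice the G1 mean
#' (ploidy constraint), and an S-phase component modelled as 10 evenly
#' spaced Gaussian sub-populations strictly between the two, all sharing one
#' coefficient of variation. For fixed (G1 mean, CV) the three component
#' masses are solved by non-negative least squares; the outer parameters are
#' optimized by Nelder-Mead. Fractions are reported in percent and sum
#' to 100.
#'
#' @param histogram data.frame with columns \code{bin_center} and
#'   \code{count} (at least 50 bins spanning both the G1 and G2/M modes),
#'   e.g. from [simulateDnaHistogram()].
#' @param g1Init optional starting value for the G1 mean; defaults to the
#'   histogram's highest-count bin.
#' @param cvInit starting coefficient of variation.
#' @return A [CellCycleFit-class]. A fit in which the G2/M mass is below
#'   0.1 percent triggers a warning (unimodal histogram) but still reports
#'   fractions.
#' @examples
#' h <- simulateDnaHistogram(c(0.6, 0.1, 0.3), nCells = 5000, seed = 2)
#' fitCellCycle(h)
#' @export
fitCellCycle <- function(histogram, g1Init = NULL, cvInit = 0.05) {
    x <- histogram$bin_center
    counts <- histogram$count
    if (length(x) < 50L)
        stop("histogram must have at least 50 bins")
    bw <- stats::median(diff(x))
    if (is.null(g1Init)) g1Init <- x[which.max(counts)]
    nnlsAt <- function(par) {
        m <- exp(par[1]); cv <- exp(par[2])
        A <- .cycleDesign(x, m, cv, bw)
        fit <- pracma::lsqnonneg(A, counts)
        list(coef = fit$x, rss = sum((A %*% fit$x - counts)^2))
    }
    obj <- function(par) nnlsAt(par)$rss
    opt <- stats::optim(c(log(g1Init), log(cvInit)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    sol <- nnlsAt(opt$par)
    masses <- sol$coef
    if (sum(masses) == 0) stop("cell-cycle fit failed: all masses zero")
    frac <- 100 * masses / sum(masses)
    names(frac) <- c("G1", "S", "G2M")
    if (frac[["G2M"]] < 0.1)
        warning("G2/M mass below 0.1%: histogram looks unimodal; ",
                "fractions reported anyway")
    g1 <- exp(opt$par[1])
    new("CellCycleFit", fractions = frac, g1Mean = g1, g2Mean = 2 * g1,
        cv = exp(opt$par[2]), residualNorm = sqrt(sol$rss))
}
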