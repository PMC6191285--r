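#' @include utils.R
NULL

# Means of the S-phase sub-populations used by both the generator and the
# cell-cycle fitter: nS Gaussians evenly spaced strictly between the G1 and
# G2/M means (discretized Dean-Jett-Fox construction).
.sPhaseMeans <- function(g1Mean, nS = 10L) {
    g1Mean * (1 + seq_len(nS) / (nS + 1))
}

#' Simulate a DNA-content histogram
#'
#' Draws per-cell DNA-content (e.g. DAPI) intensities from a three-component
#' model: G1 cells ~ Normal(g1Mean, cv * g1Mean); G2/M cells ~
#' Normal(2 g1Mean, cv * 2 g1Mean); S cells are assigned uniformly to 10
#' Gaussian sub-populations with means evenly spaced strictly between the G1
#' and G2/M means and the same relative cv. Returns the binned histogram.
#'
#' @param fractions numeric length-3 (G1, S, G2M), non-negative, summing to
#'   1 (tolerance 1e-6).
#' @param g1Mean G1 mean in channel units.
#' @param cv coefficient of variation, > 0.
#' @param nCells number of cells to draw.
#' @param seed integer random seed.
#' @param bins number of histogram bins.
#' @param range channel range covered by the bins.
#' @return A data.frame with columns \code{bin_center} and \code{count};
#'   the raw per-cell intensities are attached as attribute \code{"values"}
#'   and the ground-truth fractions as attribute \code{"truth"}.
#' @examples
#' h <- simulateDnaHistogram(c(0.5, 0.2, 0.3), g1Mean = 200, cv = 0.05,
#'                           nCells = 5000, seed = 1)
#' @export
simulateDnaHistogram <- function(fractions, g1Mean = 200, cv = 0.05,
                                 nCells = 20000, seed = 1L, bins = 128L,
                                 range = c(0, 3 * g1Mean)) {
    if (length(fractions) != 3L || any(fractions < 0))
        stop("fractions must be three non-negative numbers (G1, S, G2M)")
    if (abs(sum(fractions) - 1) > 1e-6)
        stop("fractions must sum to 1 (tolerance 1e-6)")
    if (cv <= 0) stop("cv must be > 0")
    set.seed(as.integer(seed))
    phase <- sample.int(3L, nCells, replace = TRUE, prob = fractions)
    vals <- numeric(nCells)
    n1 <- sum(phase == 1L); n3 <- sum(phase == 3L); n2 <- sum(phase == 2L)
    if (n1) vals[phase == 1L] <- stats::rnorm(n1, g1Mean, cv * g1Mean)
    if (n3) vals[phase == 3L] <- stats::rnorm(n3, 2 * g1Mean, cv * 2 * g1Mean)
    if (n2) {
        mu <- .sPhaseMeans(g1Mean)[sample.int(10L, n2, replace = TRUE)]
        vals[phase == 2L] <- stats::rnorm(n2, mu, cv * mu)
    }
    breaks <- seq(range[1], range[2], length.out = bins + 1L)
    vals <- pmin(pmax(vals, range[1]), range[2])
    counts <- graphics::hist(vals, breaks = breaks, plot = FALSE)$counts
    out <- data.frame(bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
                      count = counts)
    attr(out, "values") <- vals
    attr(out, "truth") <- c(G1 = fractions[1], S = fractions[2],
                            G2M = fractions[3]) * 100
    out
}
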