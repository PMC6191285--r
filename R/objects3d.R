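#' @include utils.R
NULL

# Greedy one-to-one matching by ascending centroid distance under a cap.
# Returns an integer vector: for each row of a, the matched row of b or NA.
.greedyMatch <- function(ay, ax, by, bx, maxDist) {
    na <- length(ay); nb <- length(by)
    if (!na || !nb) return(rep(NA_integer_, na))
    d <- sqrt(outer(ay, by, "-")^2 + outer(ax, bx, "-")^2)
    ord <- order(d)
    match <- rep(NA_integer_, na)
    usedB <- logical(nb)
    for (k in ord) {
        if (d[k] > maxDist) break
        i <- (k - 1L) %% na + 1L
        j <- (k - 1L) %/% na + 1L
        if (is.na(match[i]) && !usedB[j]) {
            match[i] <- j
            usedB[j] <- TRUE
        }
    }
    match
}

#' Colocalization between two channels of granule records
#'
#' Matches granules of channel 1 to granules of channel 2 by greedy
#' one-to-one nearest-centroid pairing under a distance cap and reports the
#' percent of channel-1 granules with a match.
#'
#' @param records1,records2 [segmentGranules()] tables from the same frame
#'   and registration (must contain \code{y_nm}, \code{x_nm}).
#' @param maxCentroidDistance matching cap in nm.
#' @return Percent of channel-1 granules matched (0-100), with the match
#'   index vector attached as attribute \code{"matches"}.
#' @export
colocalizationFraction <- function(records1, records2, maxCentroidDistance) {
    if (!nrow(records1))
        stop("records1 is empty; colocalization percent undefined")
    m <- .greedyMatch(records1$y_nm, records1$x_nm,
                      records2$y_nm, records2$x_nm, maxCentroidDistance)
    structure(100 * sum(!is.na(m)) / nrow(records1), matches = m)
}

#' Count nuclei with associated germ-plasm signal in 3D
#'
#' Labels nuclei as 3D connected components of the supra-Otsu nuclei channel
#' and counts those whose surrounding shell (a dilation of the nucleus minus
#' all nuclei) has mean germ-plasm intensity above
#' \code{background mean + thresholdK * sd} of the germ-plasm channel. Even a
#' small amount of associated signal counts, in keeping with how associated
#' nuclei are scored in live embryos.
#'
#' @param stack two-channel [ImageStack-class].
#' @param nucleiChannel,germChannel channel indices.
#' @param t time point.
#' @param thresholdK association threshold in background sd units.
#' @param shellWidth shell thickness in pixels around each nucleus.
#' @param minVoxels minimum nucleus size in voxels (filters hot pixels).
#' @return Number of associated nuclei, with attributes \code{"nNuclei"}
#'   (total count) and \code{"associated"} (logical per nucleus). An empty
#'   nuclei channel yields 0.
#' @export
countAssociatedNuclei <- function(stack, nucleiChannel = 1L,
                                  germChannel = 2L, t = 1L, thresholdK = 2,
                                  shellWidth = 2, minVoxels = 9L) {
    stopifnot(is(stack, "ImageStack"))
    nuc <- .getVolume(stack, t = t, channel = nucleiChannel)
    germ <- .getVolume(stack, t = t, channel = germChannel)
    rng <- range(nuc)
    if (rng[1] == rng[2]) return(structure(0L, nNuclei = 0L,
                                           associated = logical(0)))
    norm <- (nuc - rng[1]) / (rng[2] - rng[1])
    # global Otsu over all voxels (any 2D arrangement has the same histogram)
    thr <- EBImage::otsu(EBImage::Image(matrix(norm, nrow = dim(norm)[2])))
    mask <- norm > thr
    lab <- .label3d(mask)
    nlab <- max(lab)
    if (nlab == 0L) return(structure(0L, nNuclei = 0L, associated = logical(0)))
    keep <- which(tabulate(lab[lab > 0], nlab) >= minVoxels)
    if (!length(keep)) return(structure(0L, nNuclei = 0L,
                                        associated = logical(0)))
    # germ-channel background outside dilated germ foreground
    grng <- range(germ)
    if (grng[1] == grng[2]) {
        gbg <- c(mean = grng[1], sd = 0)
    } else {
        gnorm <- (germ - grng[1]) / (grng[2] - grng[1])
        gthr <- EBImage::otsu(EBImage::Image(matrix(gnorm,
                                                    nrow = dim(germ)[2])))
        gfg <- .dilate3d(gnorm > gthr, 2)
        gv <- germ[!gfg]
        if (!length(gv)) gv <- as.vector(germ)
        gbg <- c(mean = mean(gv), sd = stats::sd(gv))
    }
    allNuc <- lab > 0
    assoc <- logical(length(keep))
    for (i in seq_along(keep)) {
        comp <- lab == keep[i]
        shell <- .dilate3d(comp, shellWidth) & !allNuc
        if (!any(shell)) next
        assoc[i] <- mean(germ[shell]) > gbg[["mean"]] + thresholdK * gbg[["sd"]]
    }
    structure(sum(assoc), nNuclei = length(keep), associated = assoc)
}
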