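#' @include utils.R
NULL

#' Simulate a field of fluorescent granules
#'
#' Renders round, optionally hollow granules of prescribed fold enrichment on
#' a uniform background, then applies the Gaussian PSF and the
#' Poisson-then-Gaussian noise model of the configuration. Before blur and
#' noise, a pixel inside a solid granule has intensity
#' \code{background * enrichment}; outside all granules the intensity is
#' \code{background}. Hollow granules carry the full enrichment only in an
#' outer shell of relative thickness \code{shell_fraction}, with a dimmer
#' interior (its above-background increment scaled by
#' \code{hollowInteriorLevel}), so the interior is strictly dimmer than the
#' shell before noise.
#'
#' @param config a [SimulationConfig-class]; its seed makes the output
#'   bit-reproducible.
#' @param truths a [granuleTruth()] table.
#' @param backgroundLevel background intensity in counts, > 0.
#' @param nucleusMask optional logical (y, x) matrix; when supplied the
#'   background level applies only inside the mask and pixels outside carry
#'   \code{outsideLevel}.
#' @param imageDim image size c(ny, nx) in pixels.
#' @param allowOverlap allow granule footprints to overlap (default FALSE:
#'   overlap corrupts the per-granule ground truth and raises an error).
#' @param hollowInteriorLevel interior increment of hollow granules relative
#'   to the shell increment, in [0, 1).
#' @param outsideLevel intensity outside \code{nucleusMask}.
#' @return A list with elements \code{image} (an [ImageStack-class] with one
#'   channel per distinct truth channel) and \code{truths} (the input table
#'   augmented with \code{radius_px} and \code{rendered_total}, the
#'   above-background intensity sum each granule contributes before noise).
#' @examples
#' cfg <- simulationConfig(seed = 1, pixelSize = 50)
#' tr <- granuleTruth(y = 32, x = 32, radius = 400, enrichment = 21)
#' sim <- simulateGranuleImage(cfg, tr, backgroundLevel = 100,
#'                             imageDim = c(64, 64))
#' max(imgData(sim$image)) / 100
#' @export
simulateGranuleImage <- function(config, truths, backgroundLevel,
                                 nucleusMask = NULL, imageDim = c(128, 128),
                                 allowOverlap = FALSE,
                                 hollowInteriorLevel = 0.3,
                                 outsideLevel = backgroundLevel) {
    stopifnot(is(config, "SimulationConfig"))
    if (backgroundLevel <= 0) stop("backgroundLevel must be > 0")
    if (hollowInteriorLevel < 0 || hollowInteriorLevel >= 1)
        stop("hollowInteriorLevel must lie in [0, 1)")
    ny <- imageDim[1]; nx <- imageDim[2]
    truths$radius_px <- truths$radius_nm / config@pixelSize

    if (any(truths$y - truths$radius_px < 0 | truths$y + truths$radius_px > ny - 1 |
            truths$x - truths$radius_px < 0 | truths$x + truths$radius_px > nx - 1))
        stop("granule footprints must lie inside the image")
    if (!allowOverlap && nrow(truths) > 1) {
        same <- outer(truths$channel, truths$channel, "==")
        dd <- as.matrix(stats::dist(truths[, c("y", "x")]))
        rr <- outer(truths$radius_px, truths$radius_px, "+")
        clash <- dd < rr & upper.tri(dd) & same
        if (any(clash))
            stop("granule footprints overlap; set allowOverlap = TRUE to permit")
    }

    channels <- sort(unique(truths$channel))
    arr <- array(0, c(1L, 1L, length(channels), ny, nx))
    truths$rendered_total <- NA_real_
    set.seed(config@seed)
    for (ci in seq_along(channels)) {
        base <- if (is.null(nucleusMask)) matrix(backgroundLevel, ny, nx)
                else ifelse(nucleusMask, backgroundLevel, outsideLevel)
        enr <- matrix(0, ny, nx)
        for (i in which(truths$channel == channels[ci])) {
            r <- truths$radius_px[i]
            m <- .discMask(ny, nx, truths$y[i], truths$x[i], r)
            sf <- truths$shell_fraction[i]
            add <- matrix(0, ny, nx)
            if (sf > 0) {
                inner <- .discMask(ny, nx, truths$y[i], truths$x[i],
                                   r * (1 - sf))
                add[m] <- truths$enrichment[i] - 1
                add[inner] <- (truths$enrichment[i] - 1) * hollowInteriorLevel
            } else add[m] <- truths$enrichment[i] - 1
            enr <- enr + add
            truths$rendered_total[i] <- backgroundLevel * sum(add)
        }
        clean <- .psfBlur(base + backgroundLevel * enr, config@psfSigma)
        arr[1, 1, ci, , ] <- .applyNoise(clean, config)
    }
    list(image = ImageStack(arr, pixelSize = config@pixelSize,
                            frameInterval = config@frameInterval),
         truths = truths)
}

#' Simulate a two-channel 3D stack of nuclei and germ-plasm signal
#'
#' Places \code{nNuclei} non-overlapping spherical nuclei in a 3D volume
#' (channel 1) and renders a germ-plasm shell around exactly
#' \code{nAssociated} of them (channel 2), emulating the input of 3D counting
#' of germ-plasm-associated nuclei in a living embryo.
#'
#' @param config a [SimulationConfig-class].
#' @param nNuclei number of nuclei to place.
#' @param nAssociated number of nuclei that carry a germ-plasm shell
#'   (<= nNuclei).
#' @param stackDim volume size c(nz, ny, nx) in pixels; must accommodate a
#'   nucleus plus shell with a margin in every axis.
#' @param nucleusRadius nucleus radius in pixels.
#' @param shellWidth germ-plasm shell thickness in pixels.
#' @param backgroundLevel background counts in both channels.
#' @param nucleusEnrichment,germEnrichment fold intensity of nuclei / shells
#'   over background.
#' @param maxTries placement attempts before giving up with an error.
#' @return List with \code{stack} (two-channel [ImageStack-class]),
#'   \code{truth} = c(nNuclei, nAssociated) and \code{centres} (placed
#'   nucleus centres, 0-based (z, y, x); the first \code{nAssociated} rows
#'   are the associated ones).
#' @export
simulateCountingStack <- function(config, nNuclei, nAssociated,
                                  stackDim = c(20, 96, 96), nucleusRadius = 4,
                                  shellWidth = 2, backgroundLevel = 50,
                                  nucleusEnrichment = 10, germEnrichment = 8,
                                  maxTries = 2000L) {
    stopifnot(is(config, "SimulationConfig"))
    if (nAssociated > nNuclei) stop("nAssociated must be <= nNuclei")
    nz <- stackDim[1]; ny <- stackDim[2]; nx <- stackDim[3]
    margin <- nucleusRadius + shellWidth + 2
    marginZ <- nucleusRadius + shellWidth + 1
    if (2 * marginZ >= nz - 1 || 2 * margin >= min(ny, nx) - 1)
        stop("stackDim too small for the nucleus radius and shell width")
    minSep <- 2 * (nucleusRadius + shellWidth) + 2
    set.seed(config@seed)
    centres <- matrix(NA_real_, nNuclei, 3)
    placed <- 0L; tries <- 0L
    while (placed < nNuclei) {
        tries <- tries + 1L
        if (tries > maxTries)
            stop("could not place ", nNuclei,
                 " nuclei without overlap; reduce the count or enlarge the stack")
        cand <- c(stats::runif(1, marginZ, nz - 1 - marginZ),
                  stats::runif(1, margin, ny - 1 - margin),
                  stats::runif(1, margin, nx - 1 - margin))
        if (placed > 0 &&
            min(sqrt(colSums((t(centres[seq_len(placed), , drop = FALSE]) - cand)^2))) < minSep)
            next
        placed <- placed + 1L
        centres[placed, ] <- cand
    }
    zz <- array(0:(nz - 1), stackDim)
    yy <- aperm(array(0:(ny - 1), c(ny, nz, nx)), c(2, 1, 3))
    xx <- aperm(array(0:(nx - 1), c(nx, nz, ny)), c(2, 3, 1))
    nucMask <- array(FALSE, stackDim)
    germMask <- array(FALSE, stackDim)
    for (i in seq_len(nNuclei)) {
        d2 <- (zz - centres[i, 1])^2 + (yy - centres[i, 2])^2 +
            (xx - centres[i, 3])^2
        nucMask <- nucMask | d2 <= nucleusRadius^2
        if (i <= nAssociated)
            germMask <- germMask | (d2 <= (nucleusRadius + shellWidth)^2 &
                                    d2 > nucleusRadius^2)
    }
    arr <- array(0, c(1L, nz, 2L, ny, nx))
    cleanNuc <- backgroundLevel * (1 + (nucleusEnrichment - 1) * nucMask)
    cleanGerm <- backgroundLevel * (1 + (germEnrichment - 1) * germMask)
    for (z in seq_len(nz)) {
        arr[1, z, 1, , ] <- .psfBlur(matrix(cleanNuc[z, , ], ny, nx),
                                     config@psfSigma)
        arr[1, z, 2, , ] <- .psfBlur(matrix(cleanGerm[z, , ], ny, nx),
                                     config@psfSigma)
    }
    arr[1, , 1, , ] <- .applyNoise(array(arr[1, , 1, , ], c(nz, ny, nx)), config)
    arr[1, , 2, , ] <- .applyNoise(array(arr[1, , 2, , ], c(nz, ny, nx)), config)
    list(stack = ImageStack(arr, pixelSize = config@pixelSize,
                            frameInterval = config@frameInterval),
         truth = c(nNuclei = nNuclei, nAssociated = nAssociated),
         centres = centres)
}
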