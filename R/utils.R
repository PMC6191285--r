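#' @include AllClasses.R
NULL

# Logical disc mask on a (ny, nx) grid; pixel centres at integer coords,
# 0-based. Radius in pixels.
.discMask <- function(ny, nx, cy, cx, r) {
    yy <- matrix(0:(ny - 1), ny, nx)
    xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
    (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Gaussian PSF blur of a matrix; sigma in pixels, replicate-free (circular)
# boundary is acceptable because the generators keep objects away from edges.
.psfBlur <- function(m, sigma) {
    if (sigma <= 0) return(m)
    sz <- 2L * ceiling(3 * sigma) + 1L
    k <- EBImage::makeBrush(sz, shape = "Gaussian", sigma = sigma)
    as.matrix(EBImage::filter2(EBImage::Image(m), k, boundary = "circular"))
}

# Poisson-then-Gaussian noise; Gaussian sd is a fraction of the noiseless
# signal. Assumes the RNG state has been set by the caller.
.applyNoise <- function(clean, config) {
    x <- clean
    if (config@poissonNoise)
        x <- array(stats::rpois(length(x), pmax(as.vector(x), 0)), dim(x))
    if (config@gaussianSigma > 0)
        x <- x + array(stats::rnorm(length(x), 0,
                                    config@gaussianSigma *
                                        pmax(abs(as.vector(clean)), 0)),
                       dim(x))
    x
}

# Background statistics per the package convention: mean and sd over pixels
# outside a 2-px dilation of all supra-Otsu components. Returns c(mean, sd);
# on a constant image the sd is 0 and the mask covers everything.
.backgroundStats <- function(m) {
    rng <- range(m)
    if (rng[1] == rng[2])
        return(c(mean = rng[1], sd = 0))
    norm <- (m - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(norm))
    fg <- norm > thr
    if (any(fg)) {
        fg <- EBImage::dilate(EBImage::Image(fg),
                              EBImage::makeBrush(5L, "disc")) > 0
        fg <- as.matrix(fg)
    }
    bg <- m[!fg]
    if (!length(bg)) bg <- as.vector(m)
    c(mean = mean(bg), sd = stats::sd(bg))
}

# Extract one 2D plane (y, x) from an ImageStack.
.getPlane <- function(stack, t = 1L, z = 1L, channel = 1L) {
    a <- stack@imgData
    d <- dim(a)
    if (t > d[1] || z > d[2] || channel > d[3])
        stop("requested (t, z, channel) outside the stack dimensions")
    matrix(a[t, z, channel, , ], d[4], d[5])
}

# Extract a (z, y, x) volume for one time point and channel.
.getVolume <- function(stack, t = 1L, channel = 1L) {
    a <- stack@imgData
    d <- dim(a)
    if (t > d[1] || channel > d[3])
        stop("requested (t, channel) outside the stack dimensions")
    array(a[t, , channel, , ], d[c(2, 4, 5)])
}

# 3D connected components (6-connectivity along z, 8 in-plane): label each
# z-plane with EBImage::bwlabel, then merge labels that overlap between
# adjacent planes with union-find.
.label3d <- function(vol) {
    d <- dim(vol)
    nz <- d[1]
    planes <- vector("list", nz)
    offset <- 0L
    for (z in seq_len(nz)) {
        lab <- as.matrix(EBImage::bwlabel(EBImage::Image(matrix(vol[z, , ] > 0,
                                                                d[2], d[3]))))
        lab[lab > 0] <- lab[lab > 0] + offset
        offset <- offset + max(lab)
        planes[[z]] <- lab
    }
    nlab <- offset
    if (nlab == 0L) return(array(0L, d))
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
    if (nz > 1) for (z in seq_len(nz - 1L)) {
        a <- planes[[z]]; b <- planes[[z + 1L]]
        both <- a > 0 & b > 0
        if (any(both)) {
            pairs <- unique(cbind(a[both], b[both]))
            for (i in seq_len(nrow(pairs))) union(pairs[i, 1], pairs[i, 2])
        }
    }
    roots <- vapply(seq_len(nlab), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    out <- array(0L, d)
    for (z in seq_len(nz)) {
        lab <- planes[[z]]
        lab[lab > 0] <- relab[lab[lab > 0]]
        out[z, , ] <- lab
    }
    out
}

# Binary 3D dilation by an approximate Euclidean ball of radius r (pixels),
# brute-force over the offset set; adequate for the small shells used here.
.dilate3d <- function(vol, r) {
    d <- dim(vol)
    out <- array(FALSE, d)
    rr <- ceiling(r)
    idx <- which(vol, arr.ind = TRUE)
    if (!nrow(idx)) return(out)
    for (dz in -rr:rr) for (dy in -rr:rr) for (dx in -rr:rr) {
        if (dz^2 + dy^2 + dx^2 > r^2) next
        z <- idx[, 1] + dz; y <- idx[, 2] + dy; x <- idx[, 3] + dx
        ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
        out[cbind(z[ok], y[ok], x[ok])] <- TRUE
    }
    out
}

#' Describe granule ground truth for the image generator
#'
#' Builds the granule-truth table consumed by [simulateGranuleImage()]. Each
#' row is one granule: centroid (0-based pixel coordinates), radius in nm,
#' shell fraction (0 for a solid granule, in (0, 1] for a hollow granule
#' whose bright shell occupies that fraction of the radius), fold enrichment
#' over background, and channel index.
#'
#' @param y,x centroid coordinates in pixels (0-based, pixel centres at
#'   integers).
#' @param radius granule radius in nm.
#' @param shellFraction 0 = solid; s in (0, 1] renders a bright shell of
#'   relative thickness s with a dimmer interior.
#' @param enrichment fold enrichment over background, >= 1.
#' @param channel channel index (1-based).
#' @return A data.frame with class \code{"GranuleTruth"}.
#' @examples
#' granuleTruth(y = c(20, 40), x = c(20, 44), radius = 300, enrichment = 21)
#' @export
granuleTruth <- function(y, x, radius, shellFraction = 0, enrichment = 10,
                         channel = 1L) {
    df <- data.frame(y = y, x = x, radius_nm = radius,
                     shell_fraction = shellFraction,
                     enrichment = enrichment, channel = as.integer(channel))
    if (any(df$enrichment < 1)) stop("enrichment must be >= 1")
    if (any(df$radius_nm <= 0)) stop("radius must be > 0")
    if (any(df$shell_fraction < 0 | df$shell_fraction > 1))
        stop("shellFraction must lie in [0, 1]")
    class(df) <- c("GranuleTruth", "data.frame")
    df
}

#' Build a label matrix of circular ROIs
#'
#' Utility for placing measurement ROIs (granule or reference) on an image:
#' returns an integer matrix in which pixels of ROI i carry value i.
#' Overlapping ROIs are rejected.
#'
#' @param ny,nx image dimensions (y, x) in pixels.
#' @param y,x ROI centre coordinates (0-based pixels).
#' @param radius ROI radius in pixels (recycled).
#' @return Integer matrix of ROI labels (0 = outside all ROIs).
#' @export
roiDiscs <- function(ny, nx, y, x, radius) {
    radius <- rep_len(radius, length(y))
    out <- matrix(0L, ny, nx)
    for (i in seq_along(y)) {
        m <- .discMask(ny, nx, y[i], x[i], radius[i])
        if (any(out[m] != 0L)) stop("ROIs overlap")
        out[m] <- i
    }
    out
}
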