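#' @include objects3d.R
NULL

#' Track granules over time and detect fusion events
#'
#' Links granule records frame to frame by greedy nearest-centroid matching
#' under a displacement cap (ties broken by smallest displacement, then
#' lowest id) and flags a fusion event when two tracks converge on a single
#' granule whose total intensity matches the sum of its two predecessors
#' within a relative tolerance. A convergence whose intensity mismatch
#' exceeds the tolerance is not recorded as fusion; a warning is emitted
#' instead.
#'
#' @param recordsPerFrame list of [segmentGranules()] tables, one per frame,
#'   in time order (at least two frames).
#' @param maxStep maximum frame-to-frame centroid displacement in nm.
#' @param intensityTol relative tolerance on |I_merged - (I_a + I_b)| /
#'   (I_a + I_b) for calling a fusion (default 0.2).
#' @return A list with \code{tracks} (data.frame: track, frame, id, y_nm,
#'   x_nm, total_intensity) and \code{fusions} (data.frame: frame,
#'   id, track_kept, track_lost).
#' @export
trackAndDetectFusion <- function(recordsPerFrame, maxStep,
                                 intensityTol = 0.2) {
    if (length(recordsPerFrame) < 2L) stop("need at least two frames")
    first <- recordsPerFrame[[1]]
    trackOf <- seq_len(nrow(first))       # track id per granule, current frame
    nextTrack <- nrow(first) + 1L
    rows <- list(data.frame(track = trackOf, frame = 1L, id = first$id,
                            y_nm = first$y_nm, x_nm = first$x_nm,
                            total_intensity = first$total_intensity))
    fusions <- list()
    prev <- first
    for (f in 2L:length(recordsPerFrame)) {
        cur <- recordsPerFrame[[f]]
        m <- if (nrow(cur)) .greedyMatch(prev$y_nm, prev$x_nm,
                                         cur$y_nm, cur$x_nm, maxStep)
             else rep(NA_integer_, nrow(prev))
        newTrackOf <- rep(NA_integer_, nrow(cur))
        if (nrow(cur)) for (i in seq_along(m))
            if (!is.na(m[i])) newTrackOf[m[i]] <- trackOf[i]
        # unmatched previous granules: candidates for fusion into a matched one
        for (i in which(is.na(m))) {
            if (!nrow(cur)) break
            d <- sqrt((cur$y_nm - prev$y_nm[i])^2 +
                      (cur$x_nm - prev$x_nm[i])^2)
            j <- which.min(d)
            if (d[j] > maxStep) next
            partner <- which(m == j)
            if (!length(partner)) next
            isum <- prev$total_intensity[i] + prev$total_intensity[partner[1]]
            if (abs(cur$total_intensity[j] - isum) <= intensityTol * isum) {
                fusions[[length(fusions) + 1L]] <-
                    data.frame(frame = f, id = cur$id[j],
                               track_kept = trackOf[partner[1]],
                               track_lost = trackOf[i])
            } else {
                warning(sprintf(
                    "frame %d: tracks %d and %d converge on granule %d but intensity sum mismatch exceeds tolerance; not recorded as fusion",
                    f, trackOf[partner[1]], trackOf[i], cur$id[j]))
            }
        }
        if (nrow(cur)) {
            fresh <- which(is.na(newTrackOf))
            if (length(fresh)) {
                newTrackOf[fresh] <- seq(nextTrack,
                                         length.out = length(fresh))
                nextTrack <- nextTrack + length(fresh)
            }
            rows[[f]] <- data.frame(track = newTrackOf, frame = f,
                                    id = cur$id, y_nm = cur$y_nm,
                                    x_nm = cur$x_nm,
                                    total_intensity = cur$total_intensity)
        }
        prev <- cur
        trackOf <- newTrackOf
    }
    list(tracks = do.call(rbind, rows),
         fusions = if (length(fusions)) do.call(rbind, fusions)
                   else data.frame(frame = integer(0), id = integer(0),
                                   track_kept = integer(0),
                                   track_lost = integer(0)))
}
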