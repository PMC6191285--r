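#' @include AllClasses.R
NULL

#' Write an ImageStack as a multi-frame TIFF
#'
#' Frames are written in (t, z, channel) order. Integer-valued data up to
#' 65535 counts are stored losslessly as 16-bit; other data are stored as
#' 32-bit float after scaling into [0, 1]. The axis lengths, pixel size,
#' frame interval and intensity scale are recorded in a JSON sidecar file
#' (\code{<path>.json}) so that [readImageStack()] restores the full
#' (t, z, channel, y, x) geometry and calibration.
#'
#' @param stack an [ImageStack-class].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeImageStack <- function(stack, path) {
    stopifnot(is(stack, "ImageStack"))
    a <- stack@imgData
    d <- dim(a)
    integerData <- all(a == round(a)) && min(a) >= 0 && max(a) <= 65535
    scale <- if (integerData) 65535 else max(abs(a), 1e-300)
    frames <- list()
    k <- 0L
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
        k <- k + 1L
        frames[[k]] <- matrix(a[t, z, ch, , ], d[4], d[5]) / scale
    }
    tiff::writeTIFF(frames, path,
                    bits.per.sample = if (integerData) 16L else 32L,
                    compression = "none", reduce = FALSE)
    meta <- list(dim = d, pixel_size_nm = stack@pixelSize,
                 frame_interval_s = stack@frameInterval,
                 scale = scale, storage = if (integerData) "uint16" else "float32")
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' Read a multi-frame TIFF into an ImageStack
#'
#' Restores the (t, z, channel, y, x) geometry from the JSON sidecar written
#' by [writeImageStack()] when present; a plain TIFF without a sidecar is
#' read as (t = frames, z = 1, channel = 1), with pixel size taken from the
#' TIFF resolution tags when available and defaulting to 1 nm/px with a
#' warning otherwise.
#'
#' @param path TIFF path.
#' @return An [ImageStack-class].
#' @export
readImageStack <- function(path) {
    if (!file.exists(path)) stop("cannot read image: no such file: ", path)
    frames <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                       error = function(e)
                           stop("failed to read TIFF '", path, "': ",
                                conditionMessage(e)))
    if (!is.list(frames)) frames <- list(frames)
    sidecar <- paste0(path, ".json")
    ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
    for (i in seq_along(frames))
        if (!is.numeric(frames[[i]]) || nrow(frames[[i]]) != ny ||
            ncol(frames[[i]]) != nx)
            stop("non-numeric or inconsistent frame ", i, " in '", path, "'")
    if (file.exists(sidecar)) {
        meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        d <- as.integer(meta$dim)
        scale <- meta$scale
        a <- array(NA_real_, d)
        k <- 0L
        for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
            k <- k + 1L
            m <- frames[[k]] * scale
            if (identical(meta$storage, "uint16")) m <- round(m)
            a[t, z, ch, , ] <- m
        }
        return(new("ImageStack", imgData = a,
                   pixelSize = meta$pixel_size_nm,
                   frameInterval = meta$frame_interval_s))
    }
    info <- attributes(frames[[1]])
    ps <- 1
    if (!is.null(info$x.resolution) && info$x.resolution > 0 &&
        identical(info$resolution.unit, "cm")) {
        ps <- 1e7 / info$x.resolution   # pixels/cm -> nm/pixel
    } else {
        warning("no pixel-size metadata in '", path,
                "'; defaulting to 1 nm/px")
    }
    a <- array(NA_real_, c(length(frames), 1L, 1L, ny, nx))
    for (t in seq_along(frames)) a[t, 1, 1, , ] <- frames[[t]]
    new("ImageStack", imgData = a, pixelSize = ps, frameInterval = 1)
}

#' Write recovery traces to CSV
#'
#' Long format with columns \code{time_s, roi_id, role, intensity, n_pre};
#' roles are \code{bleach}, \code{reference} and \code{background}.
#'
#' @param traces list of [RecoveryTrace-class] (names become roi_ids).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTraces <- function(traces, path) {
    if (is(traces, "RecoveryTrace")) traces <- list(traces)
    ids <- names(traces)
    if (is.null(ids)) ids <- paste0("roi", seq_along(traces))
    rows <- list()
    for (i in seq_along(traces)) {
        tr <- traces[[i]]
        rows[[length(rows) + 1L]] <-
            data.frame(time_s = tr@time, roi_id = ids[i], role = "bleach",
                       intensity = tr@roi, n_pre = tr@nPre)
        if (length(tr@reference))
            rows[[length(rows) + 1L]] <-
                data.frame(time_s = tr@time, roi_id = ids[i],
                           role = "reference", intensity = tr@reference,
                           n_pre = tr@nPre)
        if (length(tr@background))
            rows[[length(rows) + 1L]] <-
                data.frame(time_s = tr@time, roi_id = ids[i],
                           role = "background", intensity = tr@background,
                           n_pre = tr@nPre)
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' Read recovery traces from CSV
#'
#' Inverse of [writeTraces()]: expects columns \code{time_s, roi_id, role,
#' intensity} and optionally \code{n_pre}; rows are grouped by
#' \code{roi_id}, the \code{bleach} (or \code{region}) role becomes the ROI
#' series and \code{reference}/\code{background} roles attach to the same
#' trace. Duplicated (time, roi, role) rows and non-uniform time grids are
#' errors.
#'
#' @param path CSV path.
#' @param nPre pre-bleach frame count used when the file has no
#'   \code{n_pre} column.
#' @return A named list of [RecoveryTrace-class].
#' @export
readTraces <- function(path, nPre = 5L) {
    if (!file.exists(path)) stop("cannot read traces: no such file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("time_s", "roi_id", "role", "intensity")
    if (!all(need %in% names(df)))
        stop("trace CSV must have columns: ", paste(need, collapse = ", "))
    key <- paste(df$time_s, df$roi_id, df$role)
    if (anyDuplicated(key)) {
        i <- which(duplicated(key))[1]
        stop("duplicated (time, roi, role) row at line ", i + 1L,
             " of '", path, "'")
    }
    out <- list()
    for (id in unique(df$roi_id)) {
        sub <- df[df$roi_id == id, ]
        main <- sub[sub$role %in% c("bleach", "region", "control"), ]
        if (!nrow(main))
            stop("roi '", id, "' has no bleach/region/control rows")
        main <- main[order(main$time_s), ]
        tgrid <- main$time_s
        dt <- diff(tgrid)
        if (length(dt) && (any(dt <= 0) ||
                           max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))) {
            bad <- which(abs(dt - dt[1]) == max(abs(dt - dt[1])))[1]
            stop("non-uniform time grid for roi '", id, "' near row ", bad)
        }
        getRole <- function(role) {
            r <- sub[sub$role == role, ]
            if (!nrow(r)) return(numeric(0))
            r <- r[order(r$time_s), ]
            if (!isTRUE(all.equal(r$time_s, tgrid)))
                stop("role '", role, "' of roi '", id,
                     "' is not on the roi time grid")
            r$intensity
        }
        np <- if ("n_pre" %in% names(sub)) as.integer(sub$n_pre[1]) else
            as.integer(nPre)
        out[[id]] <- RecoveryTrace(tgrid, main$intensity,
                                   reference = getRole("reference"),
                                   background = getRole("background"),
                                   nPre = np, label = id)
    }
    out
}

#' Write granule records or other tables to CSV
#'
#' Thin wrapper fixing the column schema and row-name policy so repeated
#' runs with identical inputs produce byte-identical files.
#'
#' @param df data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRecords <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
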