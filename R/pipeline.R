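#' @include io.R
NULL

.defaultPipelineConfig <- list(
    pipeline = "morphometry",
    seed = 1L,
    out_dir = ".",
    image = list(n_granules = 23L, radius_nm = 300, enrichment = 21,
                 background = 200, image_dim = c(192L, 192L),
                 pixel_size_nm = 50, psf_sigma = 0, poisson = TRUE,
                 gaussian_sigma = 0),
    segment = list(threshold_k = 2, min_area_nm2 = 10000),
    enrich = list(reference_kind = "intergranular", n_reference = 20L,
                  reference_radius_px = 4),
    frap = list(n_traces = 10L, mobile_fraction = 0.436, half_time_s = 10.5,
                bleach_depth = 0.8, k_img = 0, n_pre = 5L,
                frame_interval_s = 1, duration_s = 240,
                gaussian_sigma = 0.02, mode = "full_scale"),
    traces_csv = NULL)

.mergeConfig <- function(base, override) {
    for (nm in names(override)) {
        if (is.list(base[[nm]]) && is.list(override[[nm]]))
            base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
        else base[[nm]] <- override[[nm]]
    }
    base
}

#' Resolve a pipeline configuration
#'
#' Merges a user configuration (a list, or a path to a YAML or JSON file)
#' over the documented defaults, so that the effective parameter set of
#' every run is fully explicit. The resolved configuration is written
#' alongside every [runPipeline()] output.
#'
#' @param config list, path to a YAML/JSON file, or NULL for pure defaults.
#' @return The fully resolved configuration list.
#' @export
resolvePipelineConfig <- function(config = NULL) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- if (grepl("\\.ya?ml$", config))
            yaml::read_yaml(config)
        else jsonlite::read_json(config, simplifyVector = TRUE)
    }
    if (is.null(config)) config <- list()
    .mergeConfig(.defaultPipelineConfig, config)
}

#' Run an end-to-end analysis pipeline
#'
#' Two pipelines are provided. \code{"morphometry"}: simulate (or read) a
#' granule image, segment it, measure fold enrichment against reference
#' ROIs, and write the granule table, the enrichment result and the
#' resolved configuration. \code{"frap"}: simulate (or read) FRAP traces,
#' normalize them full-scale, average, fit the single-exponential recovery
#' and write the fit as JSON. Every output directory also receives
#' \code{config.json}, the fully resolved parameter set including the seed,
#' so identical configurations reproduce byte-identical outputs.
#'
#' @param config list or YAML/JSON path, see [resolvePipelineConfig()].
#' @return Invisibly, a list of the in-memory results; files are written to
#'   \code{config$out_dir}.
#' @export
runPipeline <- function(config = NULL) {
    cfg <- resolvePipelineConfig(config)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(cfg, file.path(cfg$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    if (cfg$pipeline == "morphometry") {
        im <- cfg$image
        sim <- stage("simulate", {
            scfg <- simulationConfig(seed = cfg$seed,
                                     pixelSize = im$pixel_size_nm,
                                     psfSigma = im$psf_sigma,
                                     gaussianSigma = im$gaussian_sigma,
                                     poissonNoise = im$poisson)
            ny <- im$image_dim[1]; nx <- im$image_dim[2]
            pos <- .gridPositions(im$n_granules, ny, nx,
                                  im$radius_nm / im$pixel_size_nm)
            tr <- granuleTruth(y = pos$y, x = pos$x, radius = im$radius_nm,
                               enrichment = im$enrichment)
            simulateGranuleImage(scfg, tr, backgroundLevel = im$background,
                                 imageDim = c(ny, nx))
        })
        rec <- stage("segment",
                     segmentGranules(sim$image,
                                     thresholdK = cfg$segment$threshold_k,
                                     minArea = cfg$segment$min_area_nm2))
        enr <- stage("enrich", {
            ny <- dim(sim$image)[4]; nx <- dim(sim$image)[5]
            rpx <- cfg$enrich$reference_radius_px
            gRois <- roiDiscs(ny, nx, rec$y, rec$x,
                              sqrt(rec$area_nm2 / pi) / pixelSize(sim$image))
            ref <- .referencePositions(cfg$enrich$n_reference, ny, nx, rpx,
                                       sim$truths, seed = cfg$seed)
            rRois <- roiDiscs(ny, nx, ref$y, ref$x, rpx)
            foldEnrichment(sim$image, gRois, rRois,
                           referenceKind = cfg$enrich$reference_kind)
        })
        writeRecords(rec, file.path(cfg$out_dir, "granules.csv"))
        jsonlite::write_json(
            list(fold_enrichment = enr@foldEnrichment,
                 granule_mean = enr@granuleMean,
                 reference_mean = enr@referenceMean,
                 reference_kind = enr@referenceKind,
                 n_granules = enr@nGranules,
                 n_reference = enr@nReference),
            file.path(cfg$out_dir, "enrichment.json"),
            auto_unbox = TRUE, digits = NA)
        return(invisible(list(config = cfg, records = rec, enrichment = enr)))
    }
    if (cfg$pipeline == "frap") {
        fr <- cfg$frap
        traces <- stage("traces", {
            if (!is.null(cfg$traces_csv)) readTraces(cfg$traces_csv)
            else {
                truth <- kineticTruth(mobileFraction = fr$mobile_fraction,
                                      halfTime = fr$half_time_s,
                                      bleachDepth = fr$bleach_depth,
                                      acquisitionBleachRate = fr$k_img,
                                      nPre = fr$n_pre)
                lapply(seq_len(fr$n_traces), function(i)
                    simulateFrapTrace(truth,
                                      simulationConfig(
                                          seed = (cfg$seed * 131L + i) %% .Machine$integer.max,
                                          frameInterval = fr$frame_interval_s,
                                          gaussianSigma = fr$gaussian_sigma),
                                      duration = fr$duration_s))
            }
        })
        curves <- stage("normalize",
                        lapply(traces, normalizeFrap, mode = fr$mode))
        avg <- stage("average", aggregateCurves(curves))
        fit <- stage("fit", fitRecovery(avg))
        writeRecords(avg, file.path(cfg$out_dir, "mean_curve.csv"))
        jsonlite::write_json(
            list(mobile_fraction_percent = fit@mobileFraction,
                 rate_per_s = fit@rate, half_time_s = fit@halfTime,
                 se_a_percent = fit@se[["a"]], se_b_per_s = fit@se[["b"]],
                 r_squared = fit@rSquared, n_curves = fit@nCurves),
            file.path(cfg$out_dir, "fit.json"), auto_unbox = TRUE,
            digits = NA)
        return(invisible(list(config = cfg, curves = curves, mean = avg,
                              fit = fit)))
    }
    stop("unknown pipeline: ", cfg$pipeline)
}

# Deterministic, well-separated granule positions on a jittered grid.
.gridPositions <- function(n, ny, nx, radiusPx, margin = NULL) {
    if (is.null(margin)) margin <- radiusPx + 3
    side <- ceiling(sqrt(n))
    gy <- seq(margin, ny - 1 - margin, length.out = side)
    gx <- seq(margin, nx - 1 - margin, length.out = side)
    g <- expand.grid(y = gy, x = gx)[seq_len(n), ]
    if (min(diff(gy)) < 2 * radiusPx + 2)
        stop("too many granules for the image size")
    g
}

# Reference ROI centres placed on background, away from all granules.
.referencePositions <- function(n, ny, nx, roiRadius, truths, seed = 1L) {
    set.seed(seed + 7L)
    ys <- numeric(0); xs <- numeric(0); tries <- 0L
    while (length(ys) < n) {
        tries <- tries + 1L
        if (tries > 20000L) stop("could not place reference ROIs")
        cy <- stats::runif(1, roiRadius + 1, ny - 2 - roiRadius)
        cx <- stats::runif(1, roiRadius + 1, nx - 2 - roiRadius)
        dGr <- sqrt((truths$y - cy)^2 + (truths$x - cx)^2)
        if (any(dGr < truths$radius_px + roiRadius + 2)) next
        if (length(ys) &&
            min(sqrt((ys - cy)^2 + (xs - cx)^2)) < 2 * roiRadius + 1) next
        ys <- c(ys, cy); xs <- c(xs, cx)
    }
    list(y = ys, x = xs)
}
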