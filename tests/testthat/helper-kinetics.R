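# Simulate n noisy FRAP traces with given truth, run the full pipeline
# (full-scale normalization, averaging, single-exponential fit).
fitSimulatedFrap <- function(mobileFraction, halfTime, n, seed0,
                             sigma = 0.02, duration = 240,
                             bleachDepth = 0.8, kImg = 0) {
  truth <- kineticTruth(mobileFraction = mobileFraction, halfTime = halfTime,
                        bleachDepth = bleachDepth,
                        acquisitionBleachRate = kImg)
  curves <- lapply(seq_len(n), function(i) {
    cfg <- simulationConfig(seed = seed0 + i, gaussianSigma = sigma)
    normalizeFrap(simulateFrapTrace(truth, cfg, duration = duration))
  })
  fitRecovery(aggregateCurves(curves))
}

# Well-separated granule centres on a grid covering an ny x nx image.
gridCentres <- function(n, ny, nx, marginPx) {
  side <- ceiling(sqrt(n))
  g <- expand.grid(y = seq(marginPx, ny - 1 - marginPx, length.out = side),
                   x = seq(marginPx, nx - 1 - marginPx, length.out = side))
  g[seq_len(n), ]
}
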