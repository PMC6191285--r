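# GranuleKinetics

Quantitative analysis of phase-transitioned germ granules — and biomolecular
condensates generally — from fluorescence microscopy, in R.

Germ granules are non-membrane-bound ribonucleoprotein condensates of germ
cells. Whether such a condensate behaves as a freely exchanging liquid
droplet or as a more polymerized, hydrogel-like body is decided
quantitatively: by the mobile fraction and half-time of fluorescence
recovery after photobleaching (FRAP), by fluorescence loss in photobleaching
(FLIP) across neighbouring regions, by photoconversion retention, and by
morphometry — how strongly granule proteins are enriched over the
surrounding compartment, how large the granules are, and whether they are
hollow. This package implements that analysis pipeline end to end, together
with a synthetic-data module that generates images, photobleaching traces,
3D nuclei stacks and DNA-content histograms of *known ground truth*, so
every stage is validated by parameter recovery rather than by eye.

## The models at the core

**FRAP.** After background subtraction, each recovery trace is
double-normalized against an unbleached reference ROI and rescaled
full-scale so the pre-bleach mean is 1 and the first post-bleach frame is
exactly 0. Normalized curves are averaged and fit to the single-term
exponential

> f(t) = a · (1 − e^(−b·t))

where *a* is the percent mobile fraction, *b* the recovery rate constant,
and the half-time to full recovery is t<sub>1/2</sub> = ln 2 / *b* (derived,
never fitted independently).

**FLIP.** Region traces are expressed as percent fluorescence remaining
relative to time 0; endpoint depletion per region is corrected by the
depletion of a control bleached outside the specimen (unintentional imaging
bleach), floored at zero. The forward simulator integrates a linear
compartment model dF<sub>i</sub>/dt = Σ<sub>j</sub> k<sub>ij</sub>(F<sub>j,mobile</sub> −
F<sub>i,mobile</sub>) − [i = bleached]·k<sub>bleach</sub>·F<sub>i</sub> −
k<sub>img</sub>·F<sub>i</sub>, with the immobile fraction excluded from
exchange.

**Morphometry.** Granules are segmented above
background mean + k·SD, measured on their equatorial plane, and their
per-area intensity compared to reference ROIs (intergranular space,
cytoplasm, nucleoplasm) to give concentration fold enrichment. Diameters
use the convention d = 2√A by default (which reproduces published
area–diameter pairs such as 91797 nm² → 606.0 nm), with the circular
d = 2√(A/π) available. Hollow/small/big classification, two-channel
colocalization, 3D counting of germ-plasm-associated nuclei, granule
tracking with fusion detection, and a Dean–Jett–Fox-style cell-cycle
deconvolution of DNA-content histograms round out the toolkit.

## Worked example

Simulate ten noisy FRAP traces with a known ground truth (43.6 % mobile,
t<sub>1/2</sub> = 10.5 s), then run the full pipeline:

```r
library(GranuleKinetics)

truth <- kineticTruth(mobileFraction = 0.436, halfTime = 10.5,
                      bleachDepth = 0.8)
curves <- lapply(1:10, function(i) normalizeFrap(
    simulateFrapTrace(truth,
                      simulationConfig(seed = 100 + i, gaussianSigma = 0.02),
                      duration = 240)))
fitRecovery(aggregateCurves(curves))
#> Single-exponential recovery fit (10 curve(s) averaged)
#>   mobile fraction a: 43.3 % (SE 0.05)
#>   rate b: 0.0653 /s (SE 0.0005);  t1/2 = ln(2)/b = 10.61 s
#>   R-squared: 0.9934
```

The fitted mobile fraction (43.3 %) and half-time (10.61 s) recover the
simulation truth within the noise of the experiment. Morphometry works the
same way — simulate a field of 21-fold-enriched granules under Poisson
noise, segment, and measure:

```r
sim <- simulateGranuleImage(
    simulationConfig(seed = 3, pixelSize = 50, poissonNoise = TRUE),
    granuleTruth(y = c(40, 40, 100, 100), x = c(40, 100, 40, 100),
                 radius = 300, enrichment = 21),
    backgroundLevel = 200, imageDim = c(144, 144))
rec <- segmentGranules(sim$image, minArea = 10000)
gRois <- roiDiscs(144, 144, rec$y, rec$x, sqrt(rec$area_nm2 / pi) / 50)
refRois <- roiDiscs(144, 144, c(70, 70, 20, 120), c(20, 120, 70, 70), 4)
foldEnrichment(sim$image, gRois, refRois)
#> Fold enrichment: 20.53 (granule mean 4145 over intergranular mean 201.9)
#>   4 granule ROI(s), 4 reference ROI(s)
```

The estimate (20.5×) recovers the simulated 21× enrichment to within the
shot noise. `runPipeline()` chains these stages from a single YAML/JSON
configuration and writes CSV/JSON reports plus the fully resolved parameter
set, so every number in a report is reproducible from its config file.

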