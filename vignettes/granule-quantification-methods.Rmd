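---
title: "Methods: quantifying condensate morphometry and photobleaching kinetics"
author: "GranuleKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying condensate morphometry and photobleaching kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GranuleKinetics)
```

This vignette is the package's own account of its methods: the models it
fits, the forward models it simulates, the parameters that matter, the
numerical choices taken where the underlying protocols are qualitative, and
what the synthetic-data validation does and does not establish about real
microscopy data.

## The scientific setting

Germ granules — ribonucleoprotein condensates of the germ line — and
similar biomolecular condensates are characterised by how their components
exchange with the surroundings. A liquid-like condensate formed by
liquid–liquid phase separation shows a high mobile fraction and fast
recovery after photobleaching; a phase-transitioned, hydrogel-like
condensate retains an immobile scaffold and recovers only partially. The
package quantifies this distinction from three kinds of raw data:
time-lapse fluorescence traces (FRAP, FLIP, photoconversion), fluorescence
images and z-stacks (morphometry, colocalization, 3D counting), and
DNA-content histograms (cell-cycle composition of sorted cell
populations).

## FRAP: normalization and fitting

A recovery experiment acquires `nPre` pre-bleach frames (default 5, at 1 s
intervals), applies a single instantaneous bleach pulse, and follows
recovery. `normalizeFrap()` background-subtracts the ROI and reference
series, forms the double-normalized ratio, and by default rescales it
*full-scale*:

$$F_{fs}(t) = \frac{F_n(t) - F_n(t_{bleach})}{1 - F_n(t_{bleach})},$$

so that the pre-bleach mean maps to exactly 1 and the bleach frame to
exactly 0. Full-scale normalization corrects for bleach-depth differences
between sessions, which is what makes curves from different experiments
averageable. Because the reference ROI enters as a ratio, acquisition
bleaching that affects ROI and reference equally cancels identically — a
property the test suite asserts to 1e-9.

The bleach frame is identified as the minimum of the normalized trace
within the first three post-bleach frames; a single-pulse protocol puts the
true minimum immediately after the pulse, and the window tolerates a
one-frame detection wobble under noise. When curves are averaged,
`aggregateCurves()` re-locates the bleach frame on the *averaged* curve
from the shared `nPre` rather than trusting any single trace's detection;
per-trace detections can differ by a frame at low recovery rates, and an
inconsistent anchor would corrupt the fit.

`fitRecovery()` fits $f(t) = a\,(1 - e^{-bt})$ to the post-bleach frames,
time re-zeroed at the bleach, by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), with derivative-free initial values: $a_0$ is the
mean of the last 10 % of the curve and $b_0 = \ln 2 / t_{a_0/2}$. The
mobile fraction is reported in percent (0–100 scale everywhere in output;
fitting happens on the 0–1 scale internally), the half-time is *derived*
as $t_{1/2} = \ln 2 / b$ — the identity $t_{1/2} \cdot b = \ln 2$ holds
exactly for every `FitResult` — and standard errors come from the fit
covariance. The package reports the fit SE and labels it as such; it does
not claim it equals an across-ROI spread. Averaging-then-fitting is the
default; fitting traces individually and averaging parameters is possible
by mapping `fitRecovery()` over the curves, and is what the round-trip
property test does at n = 100.

Non-recovery (a monotone-decreasing curve, or a fitted rate that is not
positive) raises an explicit "no recovery" error carrying the initial
guesses; it never returns a silently meaningless fit.

## FLIP: percent remaining and the unintentional-bleaching control

`flipAnalysis()` expresses each region trace as percent of its raw time-0
value (configurable to the pre-bleach mean; the raw anchor is the default
because continuous-bleach protocols define "100 %" at the first frame).
Endpoint depletion per region is corrected by the mean endpoint depletion
of control traces acquired with the bleach target outside the specimen —
pure unintentional imaging bleach — and floored at zero, since depletion
below the control is noise by construction; negative corrections are
logged. No reference-ROI normalization is applied in FLIP mode, matching
the protocol convention that FLIP curves are reported raw.

The forward simulator integrates the linear compartment system

$$\frac{dF_i}{dt} = \sum_j k_{ij}\,(F_{j,m} - F_{i,m})
  - [i = b]\,k_{bleach} F_i - k_{img} F_i$$

with mobile amounts $F_{i,m} = a F_i$ exchanging through a symmetric
coupling matrix and the immobile remainder bleached in place but excluded
from exchange. The integrator takes ten explicit sub-steps per frame,
advancing the exchange term by an Euler step and applying the (diagonal)
decay terms exactly. For a symmetric coupling matrix the Euler exchange
step conserves total fluorescence to machine precision, so conservation
when $k_{bleach} = k_{img} = 0$ is exact, and the whole trajectory agrees
with the matrix-exponential solution of the stacked system to a few parts
in $10^4$ at the default resolution (asserted against `Matrix::expm` in
the tests at 2e-3). Photoconversion uses the same machinery with two
species: at $t = 0$ the converted channel carries all the signal of the
targeted regions, and both species redistribute through the same coupling.

The acquisition-bleaching rate $k_{img}$ is a free parameter of
`kineticTruth()`, not an asserted constant: published protocols report its
*effect* (5–24 % control depletion) rather than a rate, and the correction
logic is what the package commits to.

## Synthetic data: what it emulates, and what it does not

`simulateGranuleImage()` renders round, optionally hollow granules as
indicator discs: pixel intensity is
`background × (1 + (enrichment − 1) × indicator)`, convolved with a
Gaussian PSF, then noised — Poisson first (photon shot noise), then
additive Gaussian read noise with standard deviation expressed as a
fraction of the noiseless signal. That order matches photon-then-read-noise
physics. A hollow granule carries the full enrichment only in an outer
shell of relative thickness `shellFraction`; its interior increment is
scaled by `hollowInteriorLevel` (default 0.3), strictly dimmer than the
shell before noise. Axis order is fixed as (t, z, channel, y, x)
throughout, with 0-based pixel indices and pixel centres at integer
coordinates; one convention, no off-by-one ambiguity. Overlapping granule
footprints are rejected unless explicitly allowed, because overlap
corrupts per-granule ground truth.

The FRAP trace generator adds a constant background offset (a detector
property, not fluorescence) to the ROI and reference series and reports it
as the background ROI; the offset does not decay with imaging bleach,
which is exactly why background subtraction must precede the reference
ratio.

Default study conditions mirror the experiments the package models:
5 pre-bleach frames, 1 s frame interval, 240 s sessions, bleach depth 0.8,
Gaussian noise sigma 0.02 for kinetics; 50 nm/px, 300 nm granule radius,
background 200 counts with Poisson noise for imaging; cell-cycle
histograms with G1 mean 200 channels, CV 0.05, 128 bins, 20 000 cells.
Where a published protocol states a value (pre-bleach count, frame
interval, granule numbers such as 23 and 18, enrichment ratios 21 and 25,
kinetic truths 43.6 %/10.5 s, 86.3 %/4.3 s, 38.8 %/13.9 s) the generator
defaults or the validation scripts use it; remaining values are fixed once
at magnitudes typical of confocal imaging of germ plasm.

What passing these validations shows: the estimators are unbiased and
precise under the stated noise model, at realistic signal levels, across
seeds. What they do not show: robustness to structured backgrounds, drift,
depth-dependent attenuation in thick specimens, non-Gaussian PSFs, or
segmentation of touching granules — real-data effects the generator
deliberately does not model (no reaction–diffusion spatial FRAP either;
the compartment model is the scope).

## Morphometry: thresholds and conventions

Background statistics are estimated over pixels outside a 2-px dilation of
all supra-Otsu components — a protocol-free choice, since published
methods rarely state background ROI placement. Segmentation keeps
connected components above `background mean + k·SD` (k = 2 by default, as
"starts to increase relative to background" is qualitative) and at least
`minArea`. For z-stacks, each granule is measured on its *equatorial*
plane — the z-plane of maximal supra-threshold cross-sectional area —
matching the convention of analysing the plane where the granule is most
in focus. Total intensity can be summed over a dilated mask
(`measureDilation`) to capture PSF tails; the undilated mask defines area
and per-area intensity.

Two area-to-diameter conventions coexist. The default, d = 2√A,
reproduces published (area, diameter) pairs exactly (91 797 nm² → 606.0 nm,
44 533 nm² → 422.1 nm); the standard equivalent-circle d = 2√(A/π) is
provided and labelled. The discrepancy is documented, not silently
corrected, and the size-class boundary (1.2 µm) applies to whichever
convention is active.

Hollowness is decided by a radial dip ratio: mean intensity of a central
disk (30 % of the equivalent radius) divided by the peak of the radial
mean-intensity profile, hollow below 0.7. All three thresholds are
configurable; they put explicit numbers on a classification that is
visual in the source protocols. Granules under 3 px across are
`unclassified` rather than guessed at.

Fold enrichment is a ratio of per-area means — each ROI contributes its
own mean, the ROI sets are averaged, then divided — so it is exactly
invariant under global intensity rescaling. On blurred images the
supra-threshold mask includes partial-intensity edge pixels, which biases
the per-area mean low by an amount set by the ratio of the PSF sigma to
the granule radius (roughly 2σ/r at threshold levels near background).
The enrichment validation therefore runs on Poisson-noised, unblurred
fields, isolating the estimator from this known, separately-documented
dilution; the PSF path is validated where it belongs, in the
total-intensity (within 1 % with a 4-px mask dilation) and profile-size
(edges at half-maximum within one PSF sigma of the true diameter)
checks.

Colocalization and tracking use greedy one-to-one nearest-centroid
matching ordered by ascending distance — deterministic, testable, and
adequate at germ-granule densities; ambiguous track links break by
smallest displacement, then lowest id. A fusion event requires two tracks
converging on one granule *and* intensity conservation within a relative
tolerance (default 0.2); convergence without conservation warns instead
of recording an event. 3D nuclei counting labels supra-Otsu voxels by
per-plane connected components merged across adjacent z-planes
(union-find), and calls a nucleus "associated" when the mean germ-plasm
intensity in a surrounding shell (dilation minus all nuclei, default
2 px) exceeds background mean + 2 SD — deliberately permissive, since
even a small amount of associated signal counts.

## Cell-cycle deconvolution

`fitCellCycle()` decomposes a DNA-content histogram in the Dean–Jett–Fox
tradition: a G1 Gaussian, a G2/M Gaussian constrained to exactly twice the
G1 mean (ploidy constraint, enforced structurally rather than fitted), and
an S-phase component modelled as 10 equally spaced Gaussian
sub-populations strictly between the two means — the same discretisation
the generator uses — all sharing one CV (the standard DJF assumption; it
reduces degeneracy between G1 and early-S). For fixed (G1 mean, CV) the
three component masses are solved by non-negative least squares
(`pracma::lsqnonneg`), and the outer two parameters by Nelder–Mead on the
residual sum of squares, initialised at the histogram mode and CV 0.05.
Giving S a single pooled coefficient, rather than ten free ones, avoids
G1↔S leakage through the heavily overlapping first sub-population.
Fractions are reported in percent and sum to 100 within 0.01. A fit whose
G2/M mass falls below 0.1 % warns that the histogram looks unimodal but
still reports fractions.

## Numerical conventions and degenerate inputs

Percents are carried on the 0–100 scale in all outputs. Raw precision is
retained in CSV/JSON; rounding (1 d.p. for percents and sizes) is for
display only. Uniform time grids are validated to 1e-9 relative tolerance
and never resampled — mismatched grids are an error. Empty or
all-background images segment to an empty table, not an error; non-finite
pixels are an error. A zero reference mean, a zero initial FLIP intensity,
zero total nuclear signal, and an unbleached FRAP trace all raise explicit
errors naming the condition. Degenerate statistics follow convention:
t = 0, p = 1 for identical groups; sd = 0 with a warning for single
values.

Every generator is bit-reproducible given an identical
`simulationConfig()` including its seed, and `runPipeline()` writes the
fully resolved configuration next to its outputs, so any reported number
can be regenerated from its config file alone.

## Problem sizes used in validation

The shipped validations run at deliberately modest sizes — 5–10 simulated
traces per kinetic regime at 240 one-second frames, 192×192 px fields of
18–23 granules, 20-nucleus 3D stacks (with one 36/22-nucleus contrast
field), 20 000-cell histograms, 100-seed round-trip loops, and 2000-draw
null-uniformity checks — sizes a desk machine handles in seconds while
still leaving Monte-Carlo error well inside the asserted tolerances.

## Known limitations

Single-term exponential recovery only (no two-component or
diffusion-equation FRAP models); compartment kinetics only (no spatial
PDE); Gaussian PSF only, with no camera-specific noise calibration; no
machine-learned segmentation, deconvolution, or drift correction beyond
nearest-centroid tracking; no multiple-testing machinery (the tests
exposed are the single pairwise comparisons and one-way ANOVA the
analyses call for). ROI geometry for enrichment references is a
configuration input, not an inferred quantity, because published ROI sizes
for that measurement are stated only for the photobleaching assays.
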