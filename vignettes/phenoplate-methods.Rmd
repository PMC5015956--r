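---
title: "phenoplate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenoplate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoplate)
```

## Scope

`phenoplate` turns time series of transmissive grayscale images of pinned
microbial colony arrays into three successively refined quantities: calibrated
colony population-size growth curves, minimum population doubling times with
per-curve quality indices, and spatially normalized relative phenotypes. A
synthetic plate simulator generates ground truth for every stage, so the whole
pipeline is testable without instrument data. Hardware control, fixture and
orientation-marker detection, and multi-plate image carving are out of scope:
images are assumed pre-cropped to a single plate region of known format.

## Plate geometry and the reference grid

Plates follow the SBS doubling series: 96 = 8 x 12, 384 = 16 x 24,
1536 = 32 x 48 (rows x columns, 0-based indices, row 0 at the image top).
When an array is replicated four-fold onto the next density, each source
position becomes a 2 x 2 tetrad; `phenoplate` reserves the lower-right
position of every tetrad — the (odd row, odd column) positions — for isogenic
control colonies. Controls are therefore exactly one quarter of all positions,
evenly distributed, and absent from row 0 and column 0, which is why the
normalization surface is necessarily an extrapolation along those two edges.
Adjacency, wherever the diagnostics need it, is the 8-neighbor Moore
neighborhood.

## Calibration model

Two polynomial calibrations connect raw pixels to cell counts.

* **Opacity calibration** (default degree 3): least squares from mean segment
  intensities of a transmissive gray-scale strip to the manufacturer's opacity
  values. The fit must be strictly monotone over the data range — calibration
  may never reorder pixel intensities — and requires at least `2 * (degree+1)`
  segments (real strips have 20-25). Out-of-range pixels are clamped, not
  rejected, with a warning tally: plates can contain specular artifacts.
* **Cell calibration** (default degree 5, zero intercept): least squares from
  background-subtracted pixel opacity to cells per pixel. The zero-intercept
  constraint encodes that zero opacity above background means zero cells;
  predictions are clipped at zero on evaluation.

The degrees are configurable defaults, declared here rather than asserted as
canonical; any strictly monotone low-order polynomial behaves equivalently on
the fitted range.

## Image analysis

Analysis is reverse-chronological: the virtual grid is detected on the *last*
image of the series, where colonies are largest, and reused verbatim for all
earlier images. Grid detection thresholds the plate (Otsu on a 256-bin
histogram), labels connected components, and collapses their centroids per
axis; each axis gets a robust 1-D lattice fit (circular-mean phase, rounding
index assignment, Huber M-estimator refinement of pitch and offset). The
fitted lattice is complete by construction, so positions with no visible
colony still receive a window. Detection fails loudly — rather than returning
a wrong grid — if too few blobs are found, the fitted pitch deviates more than
20% from the geometric expectation, or the centroids are not periodic
(median lattice residual above 0.15 pitch).

Within each window, segmentation uses hysteresis thresholding: an Otsu
threshold seeds bright cores, and each core grows to its connected component
above a low threshold (estimated local background + the contrast guard,
default 5 opacity units). The growth step matters because colony rims are dim;
a single hard threshold clips them and systematically underestimates
populations. The component nearest the window center is the focal colony;
other components and a safety-margin ring (default 2 px dilation) around the
colony are *trash* — pixels confidently assignable to neither colony nor
background — and the remainder is local background. The three masks partition
the window exactly. A window whose opacity range is below the contrast guard
is declared colony-free.

Measurement subtracts the median background opacity from every colony pixel,
converts through the cell calibration (negatives clip to zero per pixel), and
sums to the colony population. The median is robust to residual bright pixels
in the background set; on noiseless synthetic renders the procedure returns
the integrated rendered opacity exactly.

## Growth curves and the minimum doubling time

Raw curves are smoothed in two stages: a running median (window 5) removes
single-scan spikes, then a Gaussian filter (sigma 1.5 samples) averages the
remaining noise. The Gaussian stage operates on log2 population whenever the
median-filtered curve is strictly positive: measurement noise is
multiplicative, and in log space exponential growth is locally linear, so the
smoother does not bend it. Edges are padded by antisymmetric reflection
(mirroring around the endpoint value), which passes linear log-trends through
unchanged; plain symmetric reflection would bias the first and last few
points of every growing curve.

The minimum population doubling time is extracted exactly as a sliding-window
regression: for every run of 5 consecutive timepoints with positive smoothed
population, the OLS slope of log2(population) against time; the maximum slope
s_max wins and `dt_min = 1/s_max` hours. Ties break to the earliest window.
The estimate is deliberately model-free — no growth law is imposed on the
curve. Three quality indices accompany it:

* `t_at_dt_min`, the winning window's center time (a boundary value flags a
  truncated curve);
* `regression_se`, the standard error of the slope refitted on the *raw*
  log2 values of the winning window. Smoothing hides local scatter, so the
  raw points carry the honest error estimate; on an exact exponential it is
  zero either way.
* `cr_rmse`, the RMSE (log2 units) of a bounded Levenberg-Marquardt fit of an
  initial-value-extended Chapman-Richards sigmoid
  `y(t) = y0 + (K - y0) (1 - b e^(-r t))^nu` to the log2 curve, started from a
  fixed deterministic grid of 8 initial values. The fit is a quality index
  only — no feature is ever extracted from it — so non-convergence simply
  yields an infinite RMSE and a flag. A perfectly flat curve short-circuits to
  `K = y0` with zero RMSE.

Quality flagging is threshold-per-index (`regression_se` > 0.1 log2/hr,
`cr_rmse` > 0.5 log2, total growth span < 1 doubling, boundary extraction,
non-growth). The thresholds are configuration, not science: they are set so
that clean simulated plates flag well under 1% of curves while pure-noise
curves are always caught, and operators are expected to review flagged curves
rather than trust automated rejection.

Because the estimator takes a *maximum* over noisy window slopes, it carries
a small selection bias: slow-growing colonies have broad slope plateaus with
many near-maximal windows, so their doubling times are slightly
underestimated relative to fast growers. At the simulator's default noise
this differential stays inside the +/-0.1 log2 band used in the acceptance
checks; it is a property of the window-maximum definition itself, shared with
any implementation of it.

## Spatial normalization

Control doubling times are filtered (median +/- 3 scaled-MAD on log2(dt);
an abort if more than half would be removed) and interpolated into a
normalization surface evaluated at every position. Interpolation happens in
log2 space, where multiplicative bias is additive.

The default surface is a thin-plate regression spline over (row, col) with
REML smoothness selection (basis dimension half the number of retained
controls, between 12 and 60). This choice was made after measuring the
obvious alternative: a Gaussian-kernel weighted mean of bandwidth two tetrad
spacings attenuates even a one-cycle-per-plate cosine field to roughly
0.3-0.6 of its amplitude (the Nadaraya-Watson attenuation factor
`exp(-2 pi^2 sigma^2 / lambda^2)`), leaving most of a smooth bias field in
the "normalized" data. The spline tracks such fields essentially exactly,
shrinks checkerboard-like control noise toward a flat surface instead of
propagating it, and extrapolates mildly over the control-free row 0/col 0
edges, where the correction is accordingly weaker. The kernel smoother
remains available (`method = "kernel"`) for comparison.

The relative phenotype is `log2(surface_dt / observed_dt)`: a colony growing
exactly as its local controls predict scores 0, and slower-than-expected
growth (a growth defect) scores negative. Between-plate alignment shifts each
plate additively so its raw control mean (log2 hours) matches the grand
control mean; after spatial normalization these shifts are expected to be
very small. Condition-specific effects subtract the basal-environment
phenotype from the stress-environment phenotype per strain, removing general
growth defects from the condition call.

## Bias diagnostics

The adjacency false-positive test quantifies residual spatial bias without
assuming its shape: for every experimental focal colony, a one-sample
Student's t-test compares its adjacent experimental values against the mean
of all nonadjacent experimental values (controls excluded throughout, alpha
0.05). Under no bias the rejection fraction equals alpha; smooth bias makes
neighbors covary and inflates it severalfold. Using the pooled nonadjacent
mean as the null constant is a first-order approximation justified by its
averaging over >1000 positions; whether the original construction paired
neighbors with matched nonadjacent colonies is not recoverable from the
method description, and the pooled form is the variant whose null calibration
we can verify exactly by simulation. Zero-variance neighborhoods are skipped,
not counted as non-rejections. Plate CV (100 sd/mean, sample sd) and the
neighbor CV distribution complete the report.

A practical note from the implementation: the residual false-positive rate
after normalization is floored by surface estimation error, which scales as
`sigma * sqrt(edf / n_controls)` against a test SE of `sigma / sqrt(~5)`.
Both scale with the noise level sigma, so the floor depends only on the
number of controls: the 1536 format (384 controls) comes back to within twice
alpha, while a 384-format plate (96 controls) plateaus somewhat above it.
This is a structural property of reference-grid normalization, not of the
smoother.

## The synthetic plate simulator

The simulator emulates exactly the error structure the pipeline is built to
remove, and nothing more:

* **Growth**: every colony follows a Chapman-Richards sigmoid in log2 cells,
  `y(t) = y0 + A (1 - e^(-r t))^nu` with shape nu = 3 and total span A = 5
  doublings (carbon-limited colonies typically span 4.5-5.5). The rate r is
  solved in closed form from the colony's target minimum doubling time via
  the model's maximal log2 slope `A r (1 - 1/nu)^(nu-1)`, so truth is exact
  by construction. The default plate mean doubling time is 2.0 hr with mean
  initial populations of 5e4 cells.
* **Spatial bias**: a smooth random field (three low-frequency cosine waves,
  standardized) multiplies growth rate with log-amplitude 0.15 — a softly
  undulating landscape, not a rugged one.
* **Pinning noise**: lognormal initial population sizes, CV 0.10.
* **Measurement noise**: lognormal multiplicative noise per observation,
  CV 0.025; the renderer draws the *observed* populations so this noise
  propagates through the image path.
* **Rendering**: colonies are radially symmetric paraboloid domes truncated
  at 70% depth, so the colony edge is a step above background — segmentable
  without an arbitrary cutoff — and the integrated opacity equals the
  cell-calibration inverse of the population. The radius grows with the cube
  root of population, so area doublings are two-thirds of population
  doublings and endpoint areas understate growth, as they do on real plates.
  Scan scheduling runs from 0 to 72 hr at 20-minute intervals by default
  (217 timepoints), with a 7-minute floor.

Not simulated: competition for nutrients between neighboring colonies (the
minimum doubling time is extracted near the time of maximal growth precisely
because competition effects are weakest there; modelling them would require a
reaction-diffusion substrate), scanner optics, light-stress growth
inhibition, agar drying, or pH fields. Passing the pipeline's tests on
simulated plates therefore demonstrates correctness of the measurement and
normalization chain under this noise model — it does not certify behaviour
under late-growth competition or multiphasic curves.

## Problem sizes in the test suite

The test suite exercises the full image pipeline at 96- and 384-format with
series of 5-50 images and 24 px per colony, and the value-level diagnostics
at 1536-format with up to 200 simulated plates; these sizes were chosen to
keep the whole suite around a minute while leaving every statistical check
with comfortable Monte-Carlo margins. The acceptance script reruns the null
calibration of the adjacency test (200 plates of 1536) from scratch.

## Known limitations

* The window-maximum doubling-time estimator is upward-biased in rate for
  noisy, slowly-growing colonies (selection over many near-maximal windows).
* Surface accuracy — and with it the residual false-positive floor — is set
  by the number of controls; sparse formats normalize less sharply.
* Curves containing zeros are smoothed in linear space, where the Gaussian
  stage can bend strong growth; such curves are flagged anyway.
* 8-bit source images are used as-is; no interpolation-based de-digitization
  is attempted.
* Lag time and growth efficiency are not extracted.
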