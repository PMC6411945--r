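---
title: "Quantifying cytoskeletal and motility phenotypes in epithelial monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytoskeletal and motility phenotypes in epithelial monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cytoquant` quantifies four cytoskeletal/motility phenotypes of cultured
epithelial monolayers from fluorescence microscopy, of the kind used to
characterize partial epithelial-mesenchymal transitions in colorectal
epithelial cell lines: the shape of EB1 plus-end comets in fixed
two-channel images, the density of the microtubule network in maximum
projections, the speed of EB1-GFP comets in time-lapse movies, and the
lateral sliding of cells inside epithelial islands from kymographs. A
synthetic-microscopy module generates calibrated images with serialized
ground truth so that every stage is validated by parameter recovery rather
than by eye.

This vignette explains the models and procedures, the parameters that
matter, and the choices made where the design was genuinely open.

## Image model and conventions

All images are carried as `ImageStack` objects: non-negative intensity
arrays with named axes (`t`, `z`, `channel`, `y`, `x`), a pixel size in
micrometres and, for time series, a frame interval in seconds. Calibration
is attached once at load time and consumed downstream; no function asks
for it twice. Pixel coordinates are 0-based with pixel centres on integer
coordinates, `y` growing downward.

## Preprocessing

* **Maximum projection** collapses `z` by a per-pixel maximum, the standard
  way to flatten a thin adherent monolayer imaged as a confocal z-stack.
* **Rolling-ball background subtraction** estimates background as the
  grayscale morphological opening by a ball-shaped structuring element
  (spherical-cap height profile, 1:1 intensity scaling) and subtracts it,
  clipping at zero. The exact definition — not the classic 8-bit
  shrink/enlarge approximation — is used so the operation can be verified
  against a brute-force oracle to machine precision. The radius must
  exceed the half-width of any structure that should survive; defaults are
  50 px for tubulin images and 15 px for comet images at the upscaled
  resolution.
* **Integer upscaling** is bilinear; 3-fold for comet morphometry so that
  particle masks of diffraction-limited comets contain enough pixels for a
  stable ellipse fit.
* **Stabilization** removes rigid translation: the integer shift comes
  from Hann-windowed phase correlation (the window suppresses the spurious
  edge response of non-periodic frames), the sub-pixel residual from one
  Lucas–Kanade least-squares step on the interior overlap. Injected
  integer drifts are recovered exactly and sub-pixel drifts to better than
  0.05 px/frame on textured scenes. The model is translation-only by
  design; rotation and deformation are out of scope.
* **Temporal running average** uses a centred window truncated at the
  sequence ends (no data are invented). For kymograph analysis the
  truncated leading/trailing frames are dropped afterwards (see below).

## Microtubule density by ridge detection

Curvilinear bright structures are extracted with a Hessian-based line
detector: the image is convolved with Gaussian derivative kernels at scale
$\sigma$; a pixel is a ridge point when the principal Hessian eigenvalue is
negative and large and the directional derivative along its eigenvector
vanishes within half a pixel (sub-pixel localization along the ridge
normal). Points above an upper strength threshold seed polylines which are
extended by hysteresis through 8-neighbours while strength stays above the
lower threshold and orientation stays continuous. For a line of full width
$w$ the conventional scale is $\sigma = w/(2\sqrt{3}) + 0.5$;
`ridge_params_from_contrast()` converts an expected line peak into
absolute strength thresholds via the response of a Gaussian-profile line,
$\text{strength} = c\,s_l/(s_l^2+\sigma^2)^{3/2}$ for contrast $c$ and
line cross-section $s_l$.

The **density score** renders all detected polylines as 1-px white (255)
lines on a black canvas and reports the mean pixel value, i.e. exactly
$255 \times (\text{ridge pixels}/\text{total pixels})$, in arbitrary
units in $[0, 255]$ — a length-per-area proxy that is monotone in true
filament coverage. Width 1 keeps the proxy unbiased; junctions split
lines, which is irrelevant to the rendered area.

On synthetic filament fields (bounded-curvature random walks, Gaussian
cross-section, additive Gaussian noise at SNR 8) the detector achieves
point recall and precision above 0.9 at 2 px matching distance, length
errors below 5% and sub-pixel localization better than 0.3 px RMS.

## EB1 comet morphometry

Cells are segmented from the junction channel by seeded region growing:
the smoothed junction image is thresholded (Otsu), connected
below-threshold basins of at least `min_cell_area` become markers, and
markers grow to the boundary ridges (`EBImage::propagate`). Segmentation
runs at acquisition resolution — interpolated pixels add nothing — and the
label map is expanded to the upscaled grid.

The comet channel is upscaled 3-fold, background-subtracted, thresholded
(Otsu by default; a fixed threshold is available for regression tests),
and 8-connected components become particles. Ellipse axes come from the
central second moments of the member pixel coordinates (full axes
$= 4\sqrt{\lambda_{1,2}}$ of the coordinate covariance); the aspect ratio
AR $= \text{major}/\text{minor}$ is the proxy for comet length, comet
width being approximately constant. Particles are assigned to the cell
containing their centroid; centroids on no cell are discarded. Cells with
zero comets are excluded (their mean AR is undefined), and the condition
summary is the mean of per-cell means with its SEM, the cell being the
experimental unit.

Two size gates bracket the particles: `min_area` (default 4 px² at the
upscaled resolution; recovery analyses on 2-px-wide synthetic comets use
20 px²) rejects noise speckle, and an optional `max_area` rejects merged
comet doublets, whose ellipse fit reports a spurious elongation — the same
role as the upper end of an Analyze-Particles size range.

**Known limitation.** The max/min eigenvalue ratio is a folded estimator:
for a truly isotropic spot the measured AR exceeds 1 with probability one,
and at moderate noise (peak SNR around 10) the bias reaches about +10%.
The bias shrinks quickly with elongation — recovery is within a few
percent at true AR 1.5–3 — and is common to both arms of a comparison, so
condition differences are unaffected; absolute AR values near 1 should be
read with this in mind. Two simulated conditions with true AR 1.93 vs 1.97
(the magnitude of difference this assay is expected to resolve), at least
250 cells per arm spread over five 52-cell fields each, yield the correct,
significant direction in well over 90% of seeded replicates.

## EB1-GFP comet tracking

Spots are detected per frame by a scale-normalized Laplacian-of-Gaussian
filter with 8-neighbour maxima and quadratic sub-pixel refinement, then
linked frame-to-frame by greedy mutual nearest neighbours under a
displacement gate. There is no gap closing, merging or splitting: EB1
comets are short-lived, near-linear movers, and the simplest defensible
linker is used and documented. Tracks shorter than 3 frames are dropped —
speed from fewer points is noise-dominated.

Per track: `duration` $= (n-1)\,\Delta t$, `path_length` the sum of
Euclidean steps in µm, `displacement` the net start-to-end distance, and
`mean_speed` $=$ path length / duration (the mean frame-to-frame speed,
the usual "track speed mean" convention). On constant-velocity movies at
2-s frame intervals the mean track speed is recovered within 5% for true
speeds 0.05–0.20 µm/s, and within 10% with 0.3 px localization error —
the residual positive bias being the expected $\sqrt{d^2+2\varepsilon^2}$
inflation of noisy step lengths.

## Kymograph analysis of lateral cell movement

A region inside an epithelial island is sliced into kymographs — one per
sampled row (`line_axis = "x"`) and column (`line_axis = "y"`), rows of
the kymograph being time — after optional stabilization and a 50-frame
running average that suppresses fast, zero-mean jiggling of intracellular
features. Streaks are traced with the same ridge detector, and each trace
is scored by the **Feret angle** of its points: the orientation of the
maximum-caliper diameter, measured from the position axis, so that a
stationary feature is vertical and the deviation $|90^\circ - $ Feret
angle$|$, clipped to $[0^\circ, 90^\circ]$, is the absolute angle away
from the vertical. A feature moving steadily at $s$ px/frame scores
$\arctan(s)$. Deviations are pooled over both slicing directions and
averaged per region.

Numerical choices that matter here:

* **Full-window frames only.** Near the sequence ends the centred
  truncated averaging window bends streaks toward the vertical (the
  window mean lags the frame index), which biases Feret angles; frames
  without a full window are dropped before slicing.
* **Trace persistence filter.** Features crossing the sampled line
  transiently (anything moving perpendicular to it) smear into short or
  time-localized ridges whose orientation does not measure steady drift;
  a trace must span at least 60% of the kymograph's time axis to be
  scored.
* **Adaptive trace thresholds.** Temporal averaging attenuates streak
  contrast by an amount that depends on the drift itself, so per-kymograph
  thresholds are derived from the observed ridge-strength distribution
  (upper = half the 99.5th percentile).
* **Streak scale.** A feature drifting at $s$ px/frame under a $w$-frame
  average smears into a band roughly $w\,s\cos(\arctan s)$ px across;
  the tracing scale should match it, and the generator's feature spacing
  must exceed about three times this smear or neighbouring streaks merge.
* **Column downscaling for steep streaks.** When the drift exceeds about
  1 px/frame the streaks run closer to the position axis than to the time
  axis, and the large tracing kernels they require are corrupted by the
  kymograph's short time extent. Box-averaging the columns by an integer
  $k$ (chosen so $s/k \lesssim 0.5$) moves the streak back into the
  shallow-slope regime; measured deviations are converted back exactly via
  $\arctan(k\,\tan\varphi)$, a transform whose nonlinearity also
  compresses tracing error at steep angles.

The synthetic drift movie renders a mesh of slightly wavy bright lines
(the cell-junction network that dominates island movies) on a noisy
baseline, translated by a constant drift plus per-frame uniform jitter.
Extended lines are what make streaks persistent: a junction line
perpendicular to the sampled direction stays on the line for the whole
movie while drifting along it. With 2-px jitter and window-50 averaging,
recovered mean deviations fall within 5° of $\arctan(s)$ for drifts of
0.5–2 px/frame (the 2 px/frame case uses a 180-frame movie, 560-px
regions, 500-px line spacing and 4-fold column downscaling so that the
100-px motion smear leaves streaks resolvable), and a static movie scores
below 2°. For real movies
— drifts far below 1 px/frame — the defaults (window 50, trace scale 2 px)
apply directly.

## Island scoring and statistics

The epithelial/mesenchymal call for each peripheral cell is manual input
— it is a judgement about morphology and microtubule orientation that the
pipeline does not attempt; the package only validates the annotations,
applies the exclusion rule (islands with fewer than 5 scored cells are
dropped) and aggregates: per-island percent mesenchymal (by cell count or
by perimeter length) and the mean ± SEM across islands.

Summary statistics are mean ± SEM with the sample standard deviation.
The two-condition test is Welch's unequal-variance two-sided t-test by
default; because descriptions of "non-parametric t-tests" are ambiguous,
a Mann–Whitney U alternative is exposed behind the same interface
(`method = "wilcoxon"`). qPCR fold changes use the
$2^{-\Delta\Delta C_t}$ method, normalizing each gene of interest to the
reference gene within condition and the treated condition to control;
condition means of $C_t$ are used by default, with a per-replicate mode
(replicates paired by index) for SEMs. Folds are invariant to any
constant $C_t$ offset.

## Synthetic data: what it does and does not emulate

The generators emulate: Gaussian-profile filaments with bounded curvature;
Voronoi cell tessellations with blurred junction boundaries; anisotropic
Gaussian comets with uniform orientations, optional AR dispersion
(truncated at 1) and a packing guard; constant-velocity spots with
staggered nucleation and finite lifetimes; drifting junction-mesh scenes
with fast jitter. Noise is additive Gaussian with SNR defined as
peak/noise-sd on a baseline of three noise SDs (so zero-clipping barely
distorts it); the PSF is an isotropic Gaussian. The default comet width
(`sigma_minor_px = 2`) corresponds to a diffraction-limited comet imaged
at ~0.1 µm pixels with a high-NA oil objective.

Not emulated: Poisson shot noise (available conceptually but off —
additive Gaussian is sufficient for recovery testing), uneven
illumination, photobleaching, out-of-focus haze, cell shape change over
time, and comet curvature. Passing recovery tests therefore demonstrates
correctness of the measurement chain, not robustness to every artefact of
real acquisitions; the rolling-ball and stabilization stages exist
precisely to handle the main real-world deviations (background gradients,
stage drift).

Every generator takes a mandatory seed, never touches global RNG state
(seeds are applied via `withr::with_seed`), and reproduces its output
bit-identically; ground truth is serialized as JSON alongside the images.

## Problem sizes

The validation suite runs entirely on synthetic data at desk scale:
256-px filament fields, 20–52-cell comet fields (five fields of 52 cells
per condition, at least 250 cells per arm, for the sensitivity analysis),
45-frame spot movies, and 120–180-frame drift movies with regions of
384–560 px. These sizes were chosen so the full suite completes in tens
of minutes on one core while keeping every statistical criterion at its
stated sample size.

## Reproducing the numbers

`scripts/acceptance.R --seed <n> --out <file>` regenerates all synthetic
inputs from the seed, runs every pipeline end to end and writes the
recovered quantities (densities, aspect ratios, speeds, deviations,
island fractions, fold changes and oracle deviations) as a flat JSON
object. The `simulate` pipeline plus the JSON run manifest written by
`run_pipeline()` make any individual analysis reproducible from its
manifest alone.
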