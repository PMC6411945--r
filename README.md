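# cytoquant

Quantification of cytoskeletal and motility phenotypes in cultured
epithelial monolayers from fluorescence microscopy.

When an epithelium undergoes a partial epithelial–mesenchymal transition —
for example after knockdown of a junction-stabilizing receptor in a
colorectal epithelial cell line — the change shows up in subtle,
quantifiable image phenotypes: microtubule plus-end (EB1) comets become
slightly longer and faster, the microtubule network becomes sparser, and
cells slide laterally inside their islands. `cytoquant` implements the
four measurement pipelines for these phenotypes, for microscopists and
image analysts who want them as reproducible, scriptable functions rather
than one-off macros:

* **EB1 comet morphometry** — cells segmented from a junction channel
  (marker-based watershed), comet particles thresholded and measured by
  moment-fit ellipse; the aspect ratio AR = major/minor is the proxy for
  comet length, aggregated as the mean of per-cell means ± SEM with the
  cell as experimental unit.
* **Microtubule density** — Steger-style Hessian ridge detection with
  sub-pixel localization; detected polylines are re-rendered as 1-px white
  lines on black and the score is the mean canvas value,
  `255 × ridge pixels / total pixels` (a.u.).
* **EB1-GFP comet tracking** — Laplacian-of-Gaussian spot detection,
  mutual-nearest-neighbour linking under a displacement gate, per-track
  mean speed (path length / duration), duration and displacement in
  calibrated units.
* **Kymograph motility** — island regions are time-sliced in x and y after
  stabilization (Hann-windowed phase correlation + Lucas–Kanade
  refinement) and a 50-frame running average; streaks are ridge-traced
  and scored by the Feret angle's absolute deviation from the vertical
  time axis, `atan(drift)` for steady drift.

Island-level aggregation of manual epithelial/mesenchymal cell calls,
mean ± SEM summaries, Welch/Mann–Whitney two-sided tests and
2^−ΔΔCt qPCR fold changes round out the analysis, and a
synthetic-microscopy module (`gen_filaments`, `gen_comet_field`,
`gen_comet_movie`, `gen_drift_movie`) generates calibrated images with
serialized ground truth so that every stage is validated by parameter
recovery.

## Worked example

Generate a synthetic two-channel comet field with known true aspect ratio
2.0 and run the full morphometry pipeline:

```r
library(cytoquant)

sim <- gen_comet_field(n_cells = 20, comets_per_cell = 8, true_ar = 2,
                       snr = 10, shape = c(300, 300), seed = 42)
res <- comet_morphometry(sim$junction, sim$comet, upscale_factor = 3,
                         rolling_ball_radius = 15, min_area = 20)
condition_summary(res$per_cell$mean_ar, "synthetic")
#>   condition     mean        sem  n
#> 1 synthetic 2.075546 0.02483439 20
```

All 20 cells are recovered by the watershed, 160 comet particles are
measured, and the condition mean AR (2.076 ± 0.025 over 20 cells) sits
within 4% of the simulated truth — the summary has exactly the
mean-of-cell-means ± SEM shape used to compare knockdown and control
conditions.

Tracking a simulated EB1-GFP movie (2-s frames, true speed 0.13 µm/s):

```r
mv <- gen_comet_movie(n_spots = 60, speed_um_s = 0.13, snr = Inf, seed = 42)
tm <- track_movie(mv$stack, sigma = 1.3, min_prominence = 10,
                  max_displacement = 6)
mean(tm$metrics$mean_speed_um_s)
#> [1] 0.1290614
```

69 tracks with a mean track speed of 0.129 µm/s (0.7% from truth) and a
mean duration of 20.9 s.

A command-line front end wraps the same pipelines
(`inst/cli/cytoquant.R`): subcommands `comets`, `mtdensity`, `track`,
`kymo`, `islands`, `qpcr` and `simulate` read TIFF/CSV inputs plus a YAML
config and write tidy CSV tables, a human-readable log and a JSON run
manifest from which `rerun_from_manifest()` reproduces the outputs
bit-identically.

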