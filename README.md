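# fiberseg

Semi-automated segmentation and size-distribution analysis of skeletal-muscle
fibers in single-channel fluorescence micrographs of muscle cross-sections.

Muscle mass changes mostly through atrophy or hypertrophy of individual
myofibers, so per-fiber size distributions from stained cross-sections are a
standard readout in injury, disease and regeneration studies. The preferred
size measure is the **minimum Feret diameter** `min_θ (max caliper width at
orientation θ)`, the statistic least distorted by oblique sectioning;
cross-sectional area (CSA, µm²) is reported alongside. Real sections are hard
on conventional edge- or threshold-based segmenters: weak and regionally
drifting staining, non-specific interior signal, noise.

`fiberseg` approaches the problem with *line* detection — the stained
boundaries are bright curvilinear structures — in a five-stage pipeline:

1. **Intensity leveling** — divide by a 45 µm median-filter background
   estimate; fiber interiors normalise to ~1.0, boundaries stay > 1.
2. **Contrast enhancement** — Perona–Malik anisotropic diffusion with
   conductance threshold `k = σ²/resolution²` (σ = 3 µm default), then a
   4th-power boost.
3. **Ridge detection** — Steger's curvilinear-structure detector at scale
   `σ_px = w/(2√3) + 0.5` for a target boundary width w (6 µm default),
   with hysteresis linking; output is a 1-px boundary-centreline skeleton.
4. **Seed generation** — disk dilation (6 µm), Gaussian blur (3 µm),
   threshold (default 70 on 0–255): sub-threshold components seed the
   watershed.
5. **Marker-based watershed** — deterministic Meyer flooding of the blurred
   ridge topography; watershed lines are excluded from fiber area; CSA and
   min/max Feret (rotating calipers on the pixel-corner convex hull) are
   measured per fiber, and fibers outside 200–10 000 µm² or touching the ROI
   edge are excluded.

The package also provides a **staining-contrast map** (boundary-to-interior
intensity ratio sampled at detected centrelines, averaged in a 27 µm window;
ratios ≥ 2.25 indicate staining adequate for reliable segmentation), a
**synthetic phantom generator** with exact ground truth for validation, and
**accuracy metrics** (mean minimum-Feret percent error, signed fiber-count
error, Bland–Altman agreement). All length parameters are given in µm and
scaled by the image resolution, so one configuration transfers across
magnifications. See `vignettes/fiberseg-methods.Rmd` for the full model,
parameter rationale and limitations.

## Worked example

```r
library(fiberseg)

# a synthetic section: irregular ~55 µm fibers, 6 µm boundaries at 2.5x
# interior intensity, 20% illumination gradient, 5% noise
ph <- generate_phantom(phantom_spec(
  width_px = 500, height_px = 500, resolution = 0.924,
  layout = "voronoi", mean_fiber_diameter_um = 55, diameter_cv = 0.15,
  boundary_width_um = 6, contrast_ratio = 2.5,
  illumination_gradient = 0.2, noise_sd = 0.05, rng_seed = 14))

seg <- segment_fibers(ph$image)
summary(seg)
#> Myofiber segmentation summary
#>   detected objects:        89
#>   kept fibers:             60
#>   excluded below 200 um^2:  2.25%
#>   excluded above 10000 um^2:  0.00%
#>   mean min Feret:          48.21 um
#>   SD min Feret:            5.52 um

tt <- truth_table(ph)
mean_feret_error(seg$fibers, tt)   # 2.95 (% error of mean min Feret)
count_error(seg$fibers, tt)        # 3.45 (% over-count vs ground truth)

write_results(seg, "out/")   # labels.tif, overlay.png, fibers.csv,
                             # summary.json, feret_histogram.csv
plot(seg, type = "overlay")
```

The summary says: 89 objects were segmented; 60 survived the exclusion rules
(2.25 % were sub-200 µm² artifacts, the rest of the exclusions touch the ROI
edge); the kept fibers have mean minimum Feret diameter 48.2 µm (SD 5.5).
Against the generator's ground truth the mean diameter is recovered to ~3 %
and the fiber count to ~3.5 %.

For real images: `read_image("section.tif", resolution = 0.462)`, then
`segment_fibers()` with a `pipeline_config()` tuned to the staining (line
width, seed threshold), optionally a mask excluding connective-tissue areas.
A thin command-line front end with `segment`, `contrast`, `phantom` and
`evaluate` subcommands is installed at `inst/cli/fiberseg.R`.

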