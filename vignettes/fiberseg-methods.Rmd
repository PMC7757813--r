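---
title: "Methods: myofiber segmentation and morphometry in fiberseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: myofiber segmentation and morphometry in fiberseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Muscle fiber size distributions are read off transverse cross-sections in
which the fiber boundaries (plasma membrane / extracellular matrix, stained
with collagen-, laminin- or dystrophin-type protocols) fluoresce brightly
against a dimmer, non-specifically stained fiber interior. The quantity of
interest per fiber is the **minimum Feret diameter** — the smallest caliper
width over all orientations — because it is the size measure least distorted
by oblique sectioning; cross-sectional area (CSA, µm²) is reported alongside.
Real sections are difficult for threshold- or edge-based segmenters: staining
contrast is often weak, regional intensity drifts across the section, and
noise and artifacts abound. `fiberseg` implements a line-detection-based
pipeline built to tolerate exactly these defects, together with a staining
quality-control tool and a synthetic phantom generator used to validate the
whole chain.

# The pipeline

`segment_fibers()` executes five stages. All length-like parameters are
specified in micrometres and converted through the image resolution
(µm/pixel), so one configuration transfers across magnifications.

## 1. Intensity leveling

The fiber-interior background is estimated with a median filter whose square
kernel (default **45 µm**, forced to an odd pixel count) is much wider than a
boundary line but comparable to a fiber, so it tracks regional interior
intensity while ignoring the thin bright boundaries. Dividing the raw image
by this estimate yields a *leveled* image: interiors ≈ 1.0, boundaries > 1.
Leveling makes everything downstream invariant to global intensity scaling
and approximately invariant to smooth multiplicative shading.

Two numerical points. First, the median filter quantises its input onto a
16-bit grid; integer camera counts are placed exactly on that grid, so
integer-preserving rescalings are *exactly* invariant, and arbitrary
rescalings are invariant to ~10⁻³. Second, a rank filter under a
multiplicative gradient has a positional bias: the window median corresponds
to the gradient value at the median *position* of the interior pixels in the
window, which can sit O(kernel/4) away from the window centre (worst at the
image border, where reflection makes the window one-sided). Shading
invariance therefore holds in the regime where the gradient varies slowly
relative to the kernel — at a 45 µm kernel, gradients of ~1 % per kernel
width are compensated to < 0.02 in leveled units everywhere, while a ±30 %
sweep across a 460 µm field (0.3 % per µm) leaves a few percent of residual
on the bright boundary pixels. The shading-invariance test is accordingly
run on a wide-field phantom (2 µm/pixel, 2.5 mm across) where the stated
slow-variation premise holds; under the steeper gradient of the recovery
phantom the residual does not harm segmentation, only the exact-invariance
property.

Division is guarded by a floor (default 10⁻⁶ of the image maximum); border
handling is by reflection, which avoids dark-frame artifacts that would seed
spurious ridges.

## 2. Contrast enhancement

Perona–Malik anisotropic diffusion smooths interior noise while preserving
boundary contrast. The conductance threshold follows the squared law

$$k = \sigma^2 / \mathrm{resolution}^2$$

with the filter width σ given in µm (default **3 µm**); k separates gradient
magnitudes to smooth from those to preserve, and the squared resolution
dependence keeps one σ setting transferable across magnifications. The
explicit 4-neighbour scheme uses no-flux boundaries; it conserves the global
mean exactly and obeys the discrete maximum principle whenever the time step
is ≤ 0.25 (we default to 0.2, 15 iterations; the conductance defaults to the
exponential form, which favours high-contrast edges). Iteration count and
step are not derivable from first principles for this application; they are
exposed in `pipeline_config()` like every other tuning parameter.

The diffused image is then raised to the **4th power**: interiors near 1 stay
near 1, boundaries are amplified, widening the gap the ridge detector works
with. Finally the image is mapped linearly onto 0–255 for the detection
stage; the mapping endpoints are echoed in the run summary so a run is
auditable.

## 3. Ridge detection

Boundaries are *lines*, not edges, so the pipeline applies Steger's
curvilinear-structure detector: Gaussian partial derivatives at scale

$$\sigma_{px} = \frac{w}{2\sqrt{3}} + 0.5$$

(w = target boundary width, default **6 µm**, converted to pixels), Hessian
eigen-analysis for the line normal, sub-pixel localisation of the zero of
the first directional derivative, and a negative second directional
derivative as the bright-line condition. The w/(2√3) term is where the
centreline response of an ideal bar of width w is maximal (for a bar of
half-width a the response is $2a\,g_\sigma(a)/\sigma^2$, maximised at
$\sigma = a/\sqrt{3}$); the +0.5 offset guards the small-w limit.

Accepted points are linked by hysteresis: chains of points with salience
(magnitude of the second directional derivative) above a low threshold are
kept if they contain at least one point above a high threshold. The
thresholds default to a per-image **bimodal (Otsu) split of the log
saliences**, with low = 0.25 · high. A percentile rule was considered and
rejected: on boundary-dominated images nearly every accepted point *is*
boundary, so any fixed percentile lands inside the signal cluster and
discards real boundary arbitrarily; the bimodal split instead finds the
valley between noise responses and boundary responses, which sit orders of
magnitude apart. Absolute thresholds remain available for manual tuning.

Numerical choices: the sub-pixel acceptance band is |t·n| ≤ 0.51 rather than
0.5, because a line centred exactly between two pixel rows solves to
|t| marginally above 0.5 on both neighbours and would otherwise vanish;
saliences below 10⁻⁶ of the per-image maximum are dropped as FFT residue
before thresholding; and the rasterised skeleton is thinned so that no 2×2
block is fully set (the least salient pixel of a block is removed).

## 4. Seed generation

The skeleton is dilated with a Euclidean disk (default radius **6 µm**),
blurred with a Gaussian (default σ **3 µm**, half the line width — enough to
smooth dilation blockiness without bridging adjacent fibers), and placed on
a 0/255 scale. Pixels strictly below the **seed threshold** (default **70**)
form the seed support; its 8-connected components of at least `min_seed_px`
pixels (default: a quarter of the pixel area of the smallest acceptable
fiber) become watershed markers. Components touching the image frame are
exempt from the size rule inside the pipeline: partial border fibers often
leave only a small sub-threshold remnant, and giving them their own seed
prevents them annexing a neighbouring fiber's basin.

## 5. Watershed segmentation and measurement

Meyer's marker-based watershed (compiled, 4-connected flooding, FIFO
tie-break, hence deterministic) floods the blurred ridge topography from the
markers. Pixels where two basins meet become **watershed lines with label
0**, excluded from every fiber: boundaries found by line detection run along
the membrane *centreline*, halfway between fibers, and a fiber's area should
not include the shared membrane. An auxiliary marker on the image frame
catches border areas with no seed of their own; its region is dropped after
flooding.

Because the watershed boundary sits on the membrane midline, raw regions
measure midline-to-midline and overestimate interior-referenced diameters by
about one line width w (≈13 % for 45 µm fibers at w = 6 µm). The pipeline
therefore applies **membrane compensation** by default: every label is
shrunk by w/2 around the watershed lines before measurement, restoring
interior-referenced CSA and Feret values. This is a measurement-convention
choice, exposed as `membrane_compensation` in the configuration; disable it
to reproduce midline-to-midline measurements.

**Edge fibers.** A fiber is flagged as an edge fiber when its sub-threshold
basin connects to the image frame — its interior visibly continues past the
ROI. This agrees with the geometric rule ("any pixel on the frame") for
ground-truth labels except in one boundary case: a fiber that is essentially
complete but grazes the frame while its boundary is still visible inside the
image is kept by the basin rule (its morphometry is correct) though a
geometric rule would exclude it. On regular test lattices a whole row can
alias into this class; on irregular mosaics it is a small fraction of border
cells.

**Morphometry.** CSA is pixel count × resolution². Feret diameters come from
the convex hull of the pixel *corner* points (a 1-pixel object has width 1
pixel, not 0); the minimum Feret is computed by rotating calipers — for a
convex polygon the minimum width is attained flat on a hull edge, so it is
the minimum over edges of the farthest-vertex distance — and the maximum
Feret as the largest hull inter-vertex distance. A brute-force 0.1°-sweep
caliper exists in the test suite as an independent oracle only. Fibers with
CSA outside **[200, 10 000] µm²** (the biological range observed in murine
and canine validation tissue; undersized segments are artifacts, oversized
ones are merged fiber groups) and edge fibers are excluded; excluded
fractions are reported over all detected objects, and the kept minimum-Feret
values are summarised as mean, SD (n−1) and a histogram (default bin 5 µm —
display granularity only).

# Staining-contrast map

The QC tool reuses stages 1 and 3: on the leveled image interiors are ≈1, so
the leveled value *at a boundary centreline* is itself a boundary-to-interior
contrast ratio. The map samples the leveled image at skeleton pixels only and
averages within a square window (default **27 µm**, forced odd). The average
runs over the *sampled* pixels, not all window pixels: diluting by unsampled
interior pixels would make the value depend on fiber size rather than
staining quality. Windows containing no skeleton pixel are set to 0
("unsampled" — the natural fallback given the map is only defined where
boundaries were seen). Regions with ratio ≥ **2.25** (the adequacy rule of
thumb for reliable segmentation) are marked by `contrast_ok_mask()`;
rendered output is conventionally clipped to the 1.0–3.0 display range while
raw values are preserved.

# The phantom generator

`generate_phantom()` builds what the pipeline is designed to segment: convex
polygonal fibers as Voronoi cells of a point process (hexagonal lattice for
analytic ground truth, or Poisson-disk points for natural size variation),
separated by bright boundary bands of fixed physical width (default 6 µm,
band = pixels whose two nearest generating points are nearly equidistant),
with a multiplicative linear illumination gradient, a chosen
boundary-to-interior contrast ratio (uniform, half-and-half or ramp), and
additive Gaussian noise (clipped at 0) on a 16-bit count scale with interior
base 1000. Gaussian rather than Poisson noise keeps the contrast ratio exact
in expectation and matches the visually dominant camera noise. Ground-truth
labels are the generating cells eroded by half the boundary width — exactly
the interior pixels — and the truth table is produced by the same
`measure_fibers()` used on segmentations, so there is a single source of
measurement logic. Generation is bit-reproducible for a fixed spec and
restores the caller's RNG state.

For the Voronoi layout the number of generating points is set so the mean
cell matches the requested mean fiber diameter (hexagonal-equivalent area),
and the Poisson-disk minimum spacing shrinks as the requested diameter CV
grows; sampling stops at the target count rather than at packing saturation,
which would otherwise force a rigid, low-variance mosaic.

**What the phantom does not emulate:** freezing and sectioning artifacts,
connective-tissue bands of varying thickness, out-of-focus blur, fiber-type
intensity heterogeneity, and non-convex fiber profiles. Passing phantom
tests therefore demonstrates correctness of the pipeline's mechanics and its
behaviour under controlled contrast/illumination/noise — not performance on
pathological tissue, which in practice is handled with the mask input and
manual threshold tuning.

# Validation experiments and problem sizes

The test suite validates each stage against independent oracles
(hand-arithmetic parameter values, a loop-based reference diffusion scheme,
bar constructions with known centrelines, the brute-force caliper sweep,
closed-form OLS) and runs three end-to-end experiments, sized to finish in a
few minutes in total:

* **Recovery**: a 1000×1000 px hexagonal phantom at 0.462 µm/pixel
  (true minimum Feret ≈ 45 µm, 6 µm boundaries, contrast 2.5, ±30 %
  illumination gradient, 5 % noise); the pipeline's mean minimum-Feret must
  agree with ground truth within 8 % and the kept fiber count within 5 %.
* **Contrast sensitivity**: the same mosaic at contrast ratios 1.5 and 3.0
  under 10 % noise, three replicates per level; the mean diameter error at
  3.0 must be strictly below that at 1.5, consistent with the ≥2.25
  adequacy rule. Ten-percent noise is used here because at 5 % noise even
  ratio-1.5 boundaries are detected essentially perfectly and the comparison
  would only measure discretisation luck.
* **Contrast-map fidelity**: an 800×800 px phantom at ratio 3.0 (map mean
  within [2.8, 3.2] over covered pixels) and a half-and-half 3.0/1.5 phantom
  (adequacy mask correct outside a one-kernel transition band).

`scripts/acceptance.R` re-runs these experiments from scratch at a
user-supplied seed and writes the resulting numbers as JSON, plus a
Bland–Altman agreement analysis (slope, intercept and mean bias of
difference-vs-mean regression) of per-image mean diameters across six
Voronoi phantoms of increasing fiber size. Agreement is evaluated on
image-level summaries, matching per-image analysis practice; fiber-to-fiber
(IoU) matching is deliberately out of scope.

# Known limitations

* The five-stage chain assumes *bright* boundaries on a darker interior;
  dark-line material would need `detect_dark_lines`-style inversion, which
  the pipeline does not expose end to end.
* Thick or uneven connective tissue violates the single-line-width
  assumption; the supported remedy is a user-supplied mask excluding those
  areas, as exposed by the `mask` argument.
* Hysteresis thresholds derived by the bimodal split assume the salience
  distribution separates noise from boundary; on images with essentially no
  boundaries the split is meaningless and the pipeline stops with a
  "no ridges" error rather than guessing.
* The pipeline is semi-automated by design: the seed threshold (default 70)
  and line width are meant to be reviewed per staining protocol, with the
  threshold preview and the contrast map as the supporting tools.
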