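---
title: "Methods: canopy structure and light regime from hemispherical photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy structure and light regime from hemispherical photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemicanopy)
```

## The estimation problem

An upward-looking fisheye photograph records, for every direction of the sky
hemisphere within the lens field of view, whether the view from the forest
floor is open sky or blocked by vegetation. From the resulting binary gap
map this package estimates:

* **Total Gap (TG)** — the unweighted proportion of sky pixels in a
  rectangular image. Cheap, but it confounds image geometry with canopy
  structure.
* **Canopy Openness (CO)** — the fraction of *hemisphere surface area* that
  is unobstructed. Because the fisheye projection compresses the horizon
  into the image periphery, sky pixels must be weighted by the area of
  hemisphere they represent.
* **Indirect Site Factor (ISF)** — annual transmittance of diffuse
  skylight, relative to open sky, under the Standard Overcast Sky (SOC)
  radiance model.
* **Direct Site Factor (DSF)** — annual transmittance of direct beam
  radiation, obtained by overlaying the sun's annual track on the gap map.
* **Global Site Factor (GSF)** — the weighted combination
  `GSF = 0.65 ISF + 0.35 DSF`. The 0.65/0.35 split reflects the
  diffuse-dominated annual radiation climate of the UK; both weights are
  arguments to `global_site_factor()` and should be reconsidered for
  sunnier climates.

All five are proportions in [0, 1]. Smartphone fisheye lenses produce
*diagonal* rather than circular images: the image diagonal spans the lens
FOV (150° here), so the frame sees a rectangular slice of the hemisphere
and none of the zenith band beyond 75°.

## Projection geometry

All imaging uses the azimuthal equidistant model: the zenith angle of a
pixel is proportional to its distance from the optical-axis pixel,
`θ = (r / R) · θ_max`. Conventions, chosen once and used everywhere:

* Continuous pixel coordinates put the origin at the raster's top-left
  corner; the centre of the pixel in row *i*, column *j* is
  `(i − 0.5, j − 0.5)`. This removes half-pixel ambiguity from round trips,
  which are tested to stay within 0.5 px.
* Sky azimuth is compass-style: 0° = North, clockwise, East = 90°. An
  as-captured upward-looking image is mirror-reversed relative to a map:
  with image-up = North, East appears on the image *left*. A `mirror` flag
  covers images that were flipped during preprocessing.
* A diagonal frame's projection puts `θ_max = FOV/2` at the half-diagonal,
  so true frame corners sit at exactly 75° for a 150° lens; the frame's
  long axis is aligned to its recorded compass bearing.
* Lenses wider than 180° (e.g. a 183° converter) are handled by calibrating
  the radius at which θ reaches 90°; the analysis never uses directions
  below the horizon.

### Merging a diagonal pair

Two frames shot at the same point, one N–S and one E–W, are merged
geometrically: the output is a full-hemisphere circle whose diameter in
frame-pixel units is the frame diagonal times 180/150, i.e. the frames'
150° diagonals are inscribed in a larger 180° disk. Each output pixel looks
up its direction in the E–W frame first (the reference image), then the
N–S frame; disk pixels seen by neither have coverage 0. We place frames by
their *recorded* orientations rather than by feature matching: this is
deterministic, dependency-free and testable, and handheld orientation error
is modelled explicitly as jitter in the simulator instead. The union
footprint covers 54.3% of the disk's pixels (about 57% of the hemisphere's
solid angle); the pixel fraction has a closed form
`(2wh − h²) / (π ρ²)` with `ρ = (diag/2)(90/75)`, which the tests use as an
oracle.

The diameter ratio deserves a note: multiplying the diagonal by 150/180
would *shrink* the analysis circle below the merged image, contradicting
the requirement that the circle represent the full 180° hemisphere around
the 150° frames. We therefore use 180/150 and expose the ratio as an
argument of `merge_diagonal_pair()`.

## Sky segmentation

`classify_blue_isodata()` applies Ridler–Calvard iterative selection to the
blue channel, where sky/vegetation contrast is strongest: starting from the
global mean, the threshold moves to the midpoint of the two class means it
induces until the update drops below 0.5 intensity (8-bit scale) or 100
iterations. Pixels strictly above the threshold are sky; ties go to canopy,
and uncovered pixels are always canopy. A perfectly uniform image offers no
contrast to threshold, so it is classified wholesale by brightness: all sky
above mid-scale, all canopy below — an open overcast sky and a closed
canopy are the two real-world images that produce uniform rasters.

`classify_enhanced()` scores every pixel's resemblance to sky from hue,
lightness and chroma (bi-hexcone HSL transform) and thresholds the *score*
with the same iterative selection. The memberships are deliberately simple
trapezoids:

* lightness ramp on [0.1, 0.6] (weight 0.35),
* hue: 1 on the blue sector 180–300°, 0.1 on green/yellow 60–180°, 0.3
  elsewhere; near-achromatic pixels (chroma < 0.05) use a
  lightness-dependent fallback rising 0 → 0.5 → 1 (weight 0.50),
* chroma: `max(0, 1 − C/0.3) · L`, rewarding washed-out bright pixels
  (weight 0.15).

The weights are hue-dominant by design: the failure mode this method
exists for is the *bright leaf* — sunlit foliage with high lightness and
enough blue intensity to cross a blue-channel threshold, but with a
yellow-green hue. A lightness-dominated score cannot push such pixels
below a threshold that must also admit dim horizon sky; the hue term can.
The score satisfies the contracts the package tests: monotone
nondecreasing in lightness, blue hues ≥ green/yellow hues at equal
lightness and chroma, → 1 for bright achromatic pixels, → 0 for dark ones.
On artifact-free two-tone images both methods produce identical masks; on
artifact-bearing renders the enhanced method classifies more bright leaves
as canopy, so its Total Gap is lower on average — the qualitative behaviour
expected of colour-aware thresholding. No claim of numerical parity with
any particular legacy implementation is made.

## Gap grid and estimates

Segmented rasters are reduced to a grid of 24 azimuth sectors × 18
equal-angle zenith annuli of 5°. Each pixel inside the 90° disk is assigned
to the cell containing its direction (boundary directions go to the
lower-index bin — a deterministic tie-break). The cell's gap fraction is
`sky pixels / all disk pixels in the cell`, so hemisphere regions observed
by no camera count as obstructed; this matches how merged smartphone images
are processed operationally. An alternative mode renormalising over covered
pixels only is available (`denominator = "covered"`) but off by default.

`CO` sums gap fractions against the annulus area weights
`w_i = cos θ_lower − cos θ_upper` (they sum to 1 by telescoping). `ISF`
weights each cell additionally by the SOC radiance at the annulus midpoint
and the cosine of incidence on a horizontal sensor; the midpoint
approximation across 5° annuli keeps the discretisation error of smooth
integrands near 1e-4, well inside the 0.01 band the tests enforce against
closed forms. `DSF` walks the sun track and looks up the grid cell
containing each sun sample — the same granularity at which the gap
information exists; a per-pixel mode would pretend to more angular
resolution than a 24 × 18 grid carries.

The sun track samples every day (365-day year, no leap days) every 4
minutes of solar time, keeping above-horizon samples. Beam weights are
`E0(n) · cos θ · τ^(1/cos θ)` with eccentricity
`E0 = 1 + 0.033 cos(360 n/365)` and atmospheric transmittance `τ = 0.6`
by default. Since site factors are annual *ratios*, constant factors
cancel and the choice of `τ` only mildly re-weights seasons; equation of
time and longitude are ignored for the same reason. Weights can underflow
to zero within ~0.04° of the horizon — such samples are kept but
contribute nothing.

The 150°-FOV simulation (`apply_fov_mask()`) zeroes the gap fraction of
annuli beyond 75° while leaving weights untouched: the masked area stays on
the hemisphere as obstructed surface, so CO, DSF and ISF can only decrease.

## The synthetic canopy simulator

Validation needs scenes whose true gap function is known exactly.
`generate_scene()` scatters opaque angular disks on the sky with centre
zenith density `∝ sin θ · (θ/90)^k`: the sine term makes density uniform
per solid angle, and the exponent `k` (default 1.5) concentrates
obstruction toward the horizon, emulating the longer view path through
canopy at grazing angles. Defaults are 300 disks with radii 1–6° and 3%
bright-leaf artifacts. Renderers colour sky pixels blue with brightness
following the SOC gradation (or uniform), canopy dark green, artifacts
yellow-green with deliberately high blue intensity, plus Gaussian channel
noise (SD 0.01); all randomness flows through named seed streams (scene,
jitter, noise) derived from the scene seed, so every fixture is
reproducible bit for bit. Handheld error is modelled as small rotations of
the optical axis (tilt about the north/east axes) plus an azimuth
deviation, applied to the sampled directions before querying the scene.

Ground truth (`truth_site_estimates()`) evaluates the disk geometry on a
0.5° lattice, aggregates with per-cell `sin θ` weighting to the same
24 × 18 grid, and runs the same radiative formulas — bypassing imaging
entirely, so pipeline error can be attributed to rendering, segmentation
and rasterisation.

What the simulator does *not* emulate matters for interpreting results:
disks are fully opaque (no foliage transmissivity), colours are clean
two-material palettes, exposure is ideal, and — most importantly — a few
hundred small disks cannot close the horizon the way a real forest stand
does. Near the horizon real canopies have gap fractions near zero, while
default synthetic scenes keep 30–40% open sky there. Consequently the
merged-pair protocol, which counts the unobserved 75–90° ring and the
corner regions as obstructed, loses genuinely open area on synthetic
scenes: in the packaged studies the merged-vs-circular mean |difference|
is ≈ 0.16 for CO and ≈ 0.05–0.06 for the site factors, whereas on field
data with closed horizons these differences are near zero. Passing the
circular-pipeline recovery tests therefore validates the measurement
chain; the merged-protocol comparison on synthetic scenes bounds its error
under deliberately unfavourable (open-horizon) conditions.

### Problem sizes used by the packaged studies

Chosen to exercise the full pipeline at realistic resolution while keeping
each study to a few minutes on one core: circular renders at 1024 px (512
px in module tests), diagonal frames at 1152 × 648 for merging studies and
640 × 360 for total-gap studies (geometry is scale-free: results depend on
aspect ratio and FOV, not pixel count), 20 scenes for recovery and
fidelity, 40 for the bias direction, 100 replicates of n = 200 for
calibration simulations.

## Calibration models

Paired smartphone/circular estimates are related by fixed-effects linear
models. Six nested structures are compared, from `y ~ x` up to
overstory-specific slopes and intercepts plus camera-type and
height-from-ground covariates, ranked by `AIC = n ln(RSS/n) + 2(k+1)`
(equivalent to the Gaussian-likelihood AIC up to an additive constant; the
ranking is cross-checked against `stats::AIC` in the tests). The field
design that motivates these models groups points within stands and
forests; the package deliberately fits *fixed effects only* — the
predictive transformation surface lives in the fixed effects, and
estimating nested random effects would add machinery without changing the
calibrated predictions. Predictions are clipped to [0, 1] with a flag.

Simulation studies (`calibration_bias_study()`, `aic_selection_study()`)
confirm that at n = 200 and residual SD 0.03 the coefficients are recovered
with bias below 0.005, AIC keeps the generating structure first in ≥ 80%
of homogeneous replicates (it may legitimately prefer the interaction
structure when sampling noise rewards it), and picks the interaction
structure over the base line in essentially all replicates generated with
heterogeneous slopes.

## Known limitations

* Only the equidistant projection is implemented; equisolid or
  stereographic lenses need external remapping first.
* The enhanced segmentation score is a documented stand-in with fixed
  membership shapes; it reproduces the qualitative behaviour of
  colour-attribute thresholding, not any specific tool's output.
* Site factors are annual ratios; instantaneous or absolute irradiance,
  leap years and topographic shading are out of scope.
* Merged-protocol estimates inherit the obstructed-by-convention treatment
  of unobserved sky; on scenes with genuinely open horizons this biases
  openness downward (see above).
* Calibration models describe the conditions they were fitted under;
  transferring them across sites, lenses or exposure protocols is not
  supported by the package's validation.
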