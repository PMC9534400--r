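---
title: "The crown-health color-space model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The crown-health color-space model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownhealth)
library(dplyr)
```

## The problem and the model

High-resolution (sub-meter to ~1 m) aerial RGB imagery lets a human photo
interpreter judge the condition of individual tree crowns: healthy crowns
look green, dying crowns look red/orange/brown, dead crowns look gray, and
between-crown shadows look near-black. `crownhealth` implements an
equation-based supervised classifier that formalizes exactly this judgment as
a partition of HSV color space into four classes — **green**, **red**,
**gray**, and **shadow** — plus an *unclassified* outcome for pixels that fit
none of them (water, soil, pavement). Because the model is four closed-form
curves with four constants, it is cheap to calibrate, easy to inspect, and
transfers across imagery sources in a way that heavier supervised models
often do not.

A raw pixel passes through this pipeline:

1. **Max-normalization.** Channels are divided by $2^{bits}-1$ so the same
   equations apply to any unsigned bit depth (8 for NAIP-style imagery).
2. **Blue-channel adjustment.** If $b = r$ with $g \ge r$, or $b = g$ with
   $r \ge g$, the pixel sits exactly on the green ($H = 1/3$) or red
   ($H = 0$) hue anchor *regardless of its saturation or value* — a washed-out
   near-gray pixel like (100, 101, 100) would score a perfect green. Such
   pixels have their blue channel lowered by one quantization step
   ($1/2^{bits}$, floored at 0), nudging them off the anchor. All other
   pixels are untouched. The trigger includes fully achromatic pixels
   ($r=g=b$): under the achromatic hue convention $H=0$ they would otherwise
   score a perfect red.
3. **HSV conversion.** The textbook hexcone transform (delegated to
   `grDevices::rgb2hsv`), $H \in [0,1)$ with red at 0 and green at $1/3$,
   $S = (\max - \min)/\max$, $V = \max$. Ties on the maximum channel resolve
   red, then green; achromatic pixels take $H = 0$.
4. **Hue rescaling.** $H_g = 1 - |H - 1/3|/(1/6)$ and
   $H_r = |1/2 - H|/(1/6) - 2$. Each peaks at 1 on its anchor and falls
   below 0 outside a $\pm 1/6$ hue window, so green support is
   $(1/6, 1/2)$ (yellow-green through cyan-green) and red support is
   $[0, 1/6) \cup (5/6, 1)$ — deliberately wide enough to catch the orange
   and brown hues of declining crowns.
5. **Score curves.** With constants $c \ge 2$,
   $$G = \frac{c_g^{H_g} - 1}{c_g - 1},\quad
     R = \frac{c_r^{H_r} - 1}{c_r - 1},\quad
     Y = \frac{c_y^{1-S} - 1}{c_y - 1},\quad
     D = \frac{c_d^{1-V} - 1}{c_d - 1},$$
   with $G$ and $R$ clamped to 0 off their supports. Each curve is 0 at the
   far edge and exactly 1 at its anchor ($H$ on the anchor; $S = 0$; $V = 0$).
   Larger constants concentrate the score near the anchor — they set how
   *strict* each class is.
6. **Zero-saturation recalculation.** A truly achromatic pixel ($S = 0$) has
   $Y = 1$ no matter how dark it is, which would label black shadows as gray.
   When $S = 0$ the gray score is recalculated as $Y - D$ — and, because hue
   is undefined at zero chroma, the hue-based scores $G$ and $R$ are vacated
   to 0. (With the blue adjustment active this branch is reachable only for
   pure black, where the adjustment floors at 0.)
7. **Assignment.** $X = \max\{G, R, Y, D\}$. If $X > t$ (strictly), the pixel
   takes the argmax class; otherwise it is unclassified. Ties — possible only
   on quantized inputs — resolve by the fixed precedence green > red > gray >
   shadow.

`plot_class_space()` draws the resulting partition of the hue-saturation
plane at chosen value levels:

```{r class-space, fig.width = 7, fig.height = 3, eval = FALSE}
plot_class_space(tch_constants(), v = c(0.12, 0.35, 0.75))
```

### A note on the achromatic branch

Two design points interact here and were resolved deliberately. First, the
blue-adjustment trigger *includes* $r=g=b$ pixels: under $H=0$ they satisfy
the red-anchor condition, and adjusting them (e.g. (128,128,128) to
(128,128,127)) lands them at $H=1/6$, where both hue scores are exactly 0 and
the gray/shadow competition proceeds on a tiny positive saturation. Second,
for pixels that still reach HSV with $S=0$ (pure black, or any achromatic
pixel when the adjustment is disabled), $G$ and $R$ are set to 0 rather than
evaluated at the $H=0$ convention. Evaluating them would give $R=1$ for every
achromatic pixel — black would tie red with shadow and the precedence rule
would call it red. Hue carries no information at zero chroma, so vacating the
hue scores is the only reading under which the two special cases do what they
are for: (128,128,128) classifies gray, (10,10,10) and (0,0,0) classify
shadow.

## Calibration: exhaustive grid search

`optimize_constants()` evaluates every combination of a fixed candidate grid
(`tch_grid()`: 13 values for each hue constant, 10 for each decay constant;
$13 \times 13 \times 10 \times 10 = 16\,900$ combinations), classifies every
training point under each, and selects the combination maximizing the mean of
the four per-class sensitivities (TPR). Unclassified predictions count
against sensitivity. A calibration is **retained** only if its minimum class
TPR is at least 0.7 — the screen used to discard imagery whose quality
defeated consistent photo interpretation.

Scores are cached: HSV and the rescaled hues are constant-independent, and
each curve depends on a single constant, so the search computes 13+13+10+10
score vectors and scans the $16\,900$ max/argmax combinations. The test suite
verifies combination-by-combination equality with naive re-evaluation.

Two numerical details:

- **Tie-break.** Equal mean-TPR combinations resolve to the first in
  ascending lexicographic order of $(c_g, c_r, c_y, c_d)$, making the scan
  deterministic. On training data whose classes are *perfectly* separable —
  as with this package's default synthetic generator — thousands of
  combinations tie at mean TPR 1 and the tie-break returns the smallest
  constants. Those constants are correct on the training support but can be
  badly uncalibrated off-support (with $c_y = 100$, moderately unsaturated
  background scores gray). Real photo-interpreted data carry enough class
  overlap that the optimum is interior and unique in practice; for projecting
  rasters whose pixels range far outside the training support, prefer the
  transferable median constants below.
- **Threshold.** $t$ is held at its default 0.1 during optimization (it is a
  classification parameter, not a searched constant), and is configurable.

`median_constants()` reports the per-parameter median of the selected
constants across imagery strata — the construction of a single transferable
"global" calibration. The package's defaults, `tch_constants(c_g = 5,
c_r = 5, c_y = 1e7, c_d = 1e4, t = 0.1)`, are the median optimal constants
from a large national calibration across NAIP state-by-year imagery, and
behave nearly as well as per-stratum fits while transferring across imagery.

## Training data handling

Training tables are labeled points: `class`, raw `r`, `g`, `b`, and optional
`nir` plus stratum metadata (`state`, `year`, `ecocode`, `digitizer`,
`lon`/`lat`). `split_train_test()` partitions them 90/10 *within each
stratum-class cell* (stratum defaults to state-by-year, matching how aerial
campaigns are flown): a class with at least 50 points in a stratum withholds
`round(0.1 n)` (at least 1) testing points; a smaller class contributes all
its points to training and none to testing. The split is seeded and the seed
recorded in the partition manifest; the rounding rule is this package's
choice, as is class-within-stratum (rather than also ecoregion-level)
stratification — ecoregion codes are carried as metadata only.

## Evaluation

`evaluate_model()` classifies withheld points and reports overall accuracy,
Cohen's kappa ($\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the
marginals), and per-class TPR — but only when every class has at least 5
testing points; otherwise the report is flagged ineligible and metrics are
withheld while the confusion matrix remains inspectable. Unclassified
predictions count as errors in accuracy and enter the kappa marginals as an
extra prediction category (a switch restores the classified-only 4x4
computation, since either convention is defensible). `confusion_pattern()`
reports, for the weakest class, where its errors went — the diagnostic that
shadow tends to be mistaken for gray, and gray and red for each other.
`summarize_evaluations()` aggregates reports across strata to medians and
percentiles.

## Raster projection and masking

`classify_raster()` applies the pixel model across a 3-band raster in one
vectorized pass (bit-identical to per-pixel evaluation and to any tiling),
emitting the fixed codes 0 = unclassified, 1 = red, 2 = gray, 3 = green,
4 = shadow, 255 = nodata/masked. Since the model knows nothing about what is
a tree, `build_forest_mask()` reclassifies a coarse categorical land-cover
raster (NLCD-style; forest codes 41, 42, 43, 90 by default) to binary, and
`apply_mask()` sets every fine pixel whose *center* falls in a non-forest
coarse cell to the masked code. Pixel-center containment (nearest-neighbor
lookup) was chosen over any-overlap because it is unambiguous, idempotent,
and exact under the 30 m / 1 m grid ratios involved; pixels whose centers
fall outside the mask's extent pass through unchanged.

Rasters live in a minimal in-memory container (`tch_raster`: matrix or
3-band array, upper-left corner, square pixel size, CRS label, nodata) with
plain-text ESRI ASCII grid I/O and TIFF I/O with a JSON georeference
sidecar.

## Damaged-tree objects

`extract_components()` takes rook-adjacency (4-connected) components of red
and of gray pixels — independently, never merged — and traces each into a
polygon on exact pixel boundaries, holes preserved (a hole's ring is kept
with opposite orientation; containment uses the even-odd rule).
`filter_by_area()` retains components between 4 and 50 m^2 inclusive, a crown
size range corresponding to radii of roughly 1-4 m; both bounds are
configurable since they depend on imagery resolution and forest type.
`interior_points()` emits one representative point per object, the polygon
centroid when it is strictly inside, otherwise the center of a component
pixel near the centroid — guaranteed interior even for C-shaped crowns.
Geographic (degree-unit) rasters are rejected since areas in m^2 are
undefined there. Objects export to GeoJSON as polygon or point layers.

## The synthetic generator: what it emulates, what it does not

`sample_class_colors()`, `render_scene()` and `make_training_set()` produce
colors, scenes, and labeled point tables from per-class uniform HSV boxes:

```{r boxes}
str(class_color_defaults())
```

The boxes were chosen once, to match the class semantics the model assumes:
green hues straddle the green anchor at working saturations; red hues straddle
the red anchor including the orange/brown allowance; grays are near-achromatic
at blue-ish hues (where both hue scores vanish — real grays have arbitrary
weak hue, but a hue-uniform gray box would place ~20% of grays under the green
or red anchors, which is a property of the *model*, not a generator bug worth
baking into every test); shadows are very dark ($V \le 0.05$). The default
scene background is an unsaturated blue ("water") that scores below threshold,
exercising the unclassified outcome. Colors are quantized to 8 bits *before*
classification so channel-equality special cases arise naturally; clustered
draws (`cluster_size > 1`) mimic digitizing several pixels per crown.

What passing tests on these fixtures shows: the equations, search, metrics,
and geoprocessing are implemented correctly, and the pipeline recovers known
truth under clean class structure. What it does not show: performance on real
imagery, with sensor noise, color balancing differences, phenology, mixed
pixels, and interpreter disagreement — the published calibration on national
photo-interpreted data is the evidence for that, and re-running this package
on those deposited point tables is the natural external check (not part of
the desk-scale test suite).

## Problem sizes and runtime choices

The test suite and the acceptance script run at deliberately modest sizes
chosen to exercise every code path: equation-fidelity comparison on $10^6$
random pixels; calibration on 4 x 100-point synthetic strata over the full
16 900-combination grid (about 2 s with caching); evaluation on 90/10
partitions of six strata; and an end-to-end 256 x 256 m scene with 13 planted
patches, of which exactly 9 survive the 4-50 m^2 object filter. All
randomness flows from explicit seeds.

## Known limitations

- The model classifies *color*, not *trees*: anything red, gray, green or
  dark is classified. Everything depends on a separate forest/tree mask, and
  the bundled 30 m masking is extremely coarse against ~1 m pixels.
- No species, causal-agent, or damage-type attribution; no change detection.
- The near-infrared band, though often present, is deliberately unused.
- Constants calibrated on saturated (perfectly separable) training data are
  non-unique; see the tie-break note above.
- The raster container deliberately supports only axis-aligned square-pixel
  grids with a CRS label; it does not reproject.
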