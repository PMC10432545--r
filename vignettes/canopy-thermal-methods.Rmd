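---
title: "Methods: canopy patches, LST retrieval, and cooling-rate analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy patches, LST retrieval, and cooling-rate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopytherm)
```

`canopytherm` packages the analysis chain that links urban tree canopy
(UTC) geometry to the urban thermal environment: land surface temperature
(LST) retrieval from a single thermal band, landscape metrics on canopy
patches, cooling rates against a bare-land baseline, and the statistics
relating the two. This vignette explains each model, the tunable
parameters and their defaults, the numerical conventions, and what the
synthetic scenes used in testing do and do not establish about real data.

## The retrieval model

The single-channel atmospheric-correction method treats the at-sensor
thermal radiance as surface emission attenuated by the atmosphere plus two
path terms:

$$L_\lambda = \left[\varepsilon\, B(T_s) + (1-\varepsilon)\,
L^{\downarrow}\right]\tau + L^{\uparrow},$$

where $\tau$ is the band transmittance, $L^{\uparrow}$ and
$L^{\downarrow}$ the up- and downwelling path radiances, and
$\varepsilon$ the surface emissivity. Solving for the blackbody radiance
and inverting the band-effective Planck relation gives

$$B(T_s) = \frac{L_\lambda - L^{\uparrow} - \tau(1-\varepsilon)
L^{\downarrow}}{\tau\,\varepsilon}, \qquad
T_s = \frac{K_2}{\ln\!\left(K_1/B(T_s) + 1\right)}.$$

Defaults are the values used for the Luoping County scene: $\tau = 0.91$,
$L^{\uparrow} = 0.75$ and $L^{\downarrow} = 1.29$ W/m²/sr/μm (an
atmospheric-profile tool output for the acquisition time and location,
treated here as configuration constants), and the Landsat 8 TIRS band-10
calibration $K_1 = 774.89$ W/m²/sr/μm, $K_2 = 1321.08$ K. The
Celsius–kelvin offset is fixed at 273.15 exactly.

Emissivity is linear in vegetation fraction,
$\varepsilon = 0.004\,P_v + 0.986$, with
$P_v = (\mathrm{NDVI} - \mathrm{NDVI}_{soil}) /
(\mathrm{NDVI}_{veg} - \mathrm{NDVI}_{soil})$. Two conventions here are
package decisions: the NDVI endpoints default to 0.05 / 0.70 (common
Landsat practice; the analysis this reproduces does not state them, so
both are exposed in `emissivity_params()`), and $P_v$ is clipped to
$[0, 1]$ outside the endpoints. With the default coefficients
$\varepsilon$ is confined to $[0.986, 0.990]$, so retrieval is insensitive
to moderate NDVI error — the round-trip tests exercise exactly this
chain.

Degenerate inputs are masked, not fudged: cells whose corrected radiance
is non-positive (at-sensor radiance at or below the path radiance) become
nodata with a reported count, as do zero-sum reflectance cells in NDVI.
Nodata (`NA`) propagates through every stage.

## Temperature levels

LST maps are divided into five levels (low, mild-low, medium, sub-high,
high) by Jenks natural breaks: the contiguous partition of the sorted
values minimizing total within-class sum of squared deviations.
`jenks_breaks()` implements the exact Fisher–Jenks dynamic programme
(O(kn²) with O(1) prefix-sum segment costs), not the common iterative
heuristic; ties between equally optimal partitions go to the smallest
upper bound of the lower class. The tests verify optimality against
brute-force enumeration of all break placements for n ≤ 25. Because the
DP is quadratic in n, the analysis scripts fit breaks on a fixed-seed
subsample of 4000 cells and then classify the full grid — at that sample
size the break values are stable to well under the 0.01 °C the maps are
reported at.

Classification is lower-closed/upper-open with the top class closed, so a
value exactly on a break goes to the upper class; the published level
ranges share endpoints, and this convention makes the assignment
deterministic.

## Patch extraction and metrics

Canopy patches are maximal connected components of the tree-canopy class.
Connectivity defaults to 8 (diagonally touching crowns are one canopy, as
object-based delineations treat them) and is configurable to 4. Area is
cell count × cell area; perimeter is exposed-edge counting: every edge of
a member cell adjacent to a non-member cell *or the grid boundary*
contributes one cell side. The shape index is

$$A = \frac{E}{2\sqrt{\pi S}},$$

dimensionless and scale-free: 1 for a disc, $2/\sqrt{\pi} \approx 1.1284$
for any square. Note one systematic caveat: a raster exposed-edge
perimeter exceeds the smoothed vector perimeter of the same region, so
shape indices computed from rasterized masks are compared against
synthetic geometry with known E and S, while reproductions of the
published 63-patch table use that table's printed area and perimeter
columns directly (the original patches were vector objects from
object-based segmentation, which the package deliberately does not
re-implement — land cover arrives as an input raster).

Size classes use the canopy-patch thresholds small ≤ 0.05 hm² < medium ≤
0.20 < large ≤ 1.00 < super-large ≤ 5.00 < extra-large, inclusive on the
lower class as printed.

## Cooling rate and coverage arithmetic

The cooling rate of a patch is
$100\,(\bar T_{bare} - \bar T_{patch})/\bar T_{bare}$, with both means in
°C. Two conventions are worth stating plainly. First, the ratio is taken
on the Celsius scale; that is physically arbitrary (a kelvin ratio would
differ) but it is the convention under which the published rates —
including the negative ones for patches warmer than bare land — are
reproducible, so the package adopts it. Second, the defining expression
is dimensionless while the quantity is reported in percent; the
implementation multiplies by 100, the only scaling consistent with
reported magnitudes near 10%. The baseline is the single scene-wide
bare-land mean, not a per-patch neighbourhood mean. Patch mean LST is
taken over the patch's cells after nearest-neighbour alignment of the LST
grid to the land-cover grid.

Coverage arithmetic is plain proportion work on class areas: current
canopy share, possible additional canopy (bare land + grassland, the
plantable classes), and their sum as the maximum achievable coverage. The
identity max = current + potential holds exactly before rounding and is
asserted in tests.

## Association analysis

Pearson correlations use the product-moment formula with two-tailed
p-values from $t = r\sqrt{(n-2)/(1-r^2)}$. Stepwise selection is backward
elimination on coefficient p-values at α = 0.05: fit the full multiple
regression, drop the predictor with the largest p-value above α, refit,
repeat. The selection criterion is a package decision — the source
analysis names stepwise regression (SPSS) without stating the rule, and
elimination by coefficient significance is the variant consistent with
discarding "the least significant" predictor. On the packaged table it
removes perimeter, then shape index, and retains area. Because the
published headline equations are two *simple* regressions, the stepwise
result also reports a simple fit per retained predictor; the
perimeter-on-cooling fit is reported alongside for comparison.

The Durbin–Watson statistic $\sum(e_t - e_{t-1})^2 / \sum e_t^2$ is
computed on residuals in patch-number order. It is order-dependent by
construction, so `luoping_reference_report()` refuses a re-sorted table
rather than silently reproducing the wrong statistic.

Tolerances for reproducing the published values are ±0.005 on
correlations, slopes and intercepts and ±0.01 on R² and Durbin–Watson:
the packaged table carries values rounded to two decimals, while the
original statistics were computed on unrounded data, and propagation of
that rounding through the estimators motivates the band.

## The synthetic scenes

`generate_scene()` exists so that every downstream stage is testable with
known ground truth. A scene is a painted mosaic (rectangles and discs,
later shapes overwriting earlier) over the five-class urban legend; each
class draws LST and NDVI per cell from Gaussian distributions, and red/NIR
reflectance are synthesized as $nir = 0.3(1+\mathrm{NDVI})$,
$red = 0.3(1-\mathrm{NDVI})$, which reproduces the target NDVI exactly —
only the ratio matters downstream. Radiance is forward-modelled through
the same radiative transfer the retrieval inverts.

The default scene uses the Luoping class mean LSTs (impervious 31.44 >
bare land 30.21 > grassland 30.09 > tree canopy 29.98 > water 28.43 °C)
with a within-class sd of 0.3 °C. The sd is a package choice (no
within-class dispersion is published); 0.3 °C keeps adjacent class means
(0.1–0.2 °C apart) statistically distinguishable at the default 320 × 320
size, where every class has at least 10⁴ cells and class means are
recovered to < 0.05 °C. Class NDVI means (water −0.10, canopy 0.70,
grassland 0.45, bare land 0.10, impervious 0.05) are typical
Landsat-scale values chosen once for realism. All draws are independent
per cell under a single integer seed; identical specs give bit-identical
scenes.

What the generator does *not* emulate bounds what passing tests show:
there is no spatial autocorrelation, no mixed pixels at class boundaries,
no sensor PSF or quantization, no atmospheric variability across the
scene, and no cloud. Round-trip retrieval errors near machine precision
therefore validate the algebra and its implementation, not the behaviour
of the chain under real sensor noise and emissivity misspecification.
Likewise the published scene-wide LST range (24.73–37.63 °C) and mean
(30.83 °C) depend on the original Landsat scene and are not reproduced
here; the reproducible quantities are the ones derived from the printed
63-patch table, the class-mean structure, and the coverage arithmetic.

## Problem sizes and runtime choices

The test suite uses 320 × 320 scenes for zonal recovery (the smallest
size giving 10⁴ cells per class), a 512 × 512 scene for the round-trip
property, 200 random instances with n ≤ 25 for the Jenks-vs-enumeration
check (the enumeration oracle is exponential in k), and the 63-row table
for all statistical reproductions. The whole suite runs in well under a
minute; `scripts/acceptance.R` recomputes the headline quantities in a
few seconds.

## Known limitations

- Land cover must be supplied (or simulated); the package contains no
  image segmentation or classification. The multi-scale segmentation
  parameters used to produce the original land-cover map are
  documentation, not code, here.
- Raster perimeters are not vector perimeters (above); shape indices from
  coarse rasters are biased high relative to smooth outlines.
- The cooling-rate baseline is global; scenes without bare land have no
  baseline and the rate is undefined.
- The 63-patch sample is small, and the published analysis notes its
  limits; the package reproduces the statistics, it does not strengthen
  them.
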