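# canopytherm

Urban tree canopy (UTC) is one of the few levers a dense city has against
the urban heat island. `canopytherm` implements, as a tested R pipeline,
the canopy–thermal-environment analysis of the urban built-up area of
Luoping County (Yunnan, southwest China): retrieval of land surface
temperature (LST) from a thermal band, extraction of canopy patches from a
land-cover map with landscape metrics, patch cooling rates against bare
land, and the correlation/regression analysis linking patch geometry to
cooling. It is aimed at landscape-ecology and urban-forestry researchers
who want each stage of such an analysis as a reusable, verifiable function
rather than a chain of GIS-software steps.

## What it computes

**LST retrieval (single-channel atmospheric correction).** At-sensor
thermal radiance is modelled as

    L_lambda = [ eps * B(T_s) + (1 - eps) * L_down ] * tau + L_up

with transmittance `tau`, path radiances `L_up`, `L_down`, and emissivity
`eps = 0.004 P_v + 0.986`, where the vegetation fraction `P_v` scales NDVI
between bare-soil and full-vegetation endpoints. Inverting for the
blackbody radiance `B(T_s)` and applying the Planck relation
`T_s = K2 / ln(K1 / B + 1)` (K1 = 774.89 W/m²/sr/μm, K2 = 1321.08 K for
Landsat 8 TIRS band 10) yields LST. The package also provides the exact
forward model, so retrieval is verified by round trip against synthetic
scenes with known ground truth (max error < 0.01 °C).

**Patch metrics.** Canopy patches are maximal connected components
(4- or 8-connectivity) of the tree-canopy class. Each patch gets area S,
perimeter E, the shape index

    A = E / (2 * sqrt(pi * S))

(1 for a circle, 2/√π ≈ 1.128 for a square), and one of five size classes
(small ≤ 0.05 hm² < medium ≤ 0.20 < large ≤ 1.00 < super-large ≤ 5.00 <
extra-large).

**Cooling rate.** Per patch,
`100 * (mean LST of bare land − mean LST of patch) / mean LST of bare land`
— the percentage by which a patch undercuts the bare-land baseline
(negative for patches warmer than bare land).

**Association.** Pearson correlations (two-tailed), backward stepwise
elimination on coefficient p-values (α = 0.05), and simple OLS fits with
R² and the Durbin–Watson statistic computed in patch-number order.

**Classification and coverage.** Exact Fisher–Jenks natural breaks
(dynamic programming, verified against brute-force enumeration) for the
five temperature levels, zonal LST statistics by land-cover class, and the
coverage-potential arithmetic (current coverage, possible additional
canopy from bare land + grassland, maximum achievable coverage).

The package ships the published table of all 63 super-large and
extra-large Luoping canopy patches (`load_patch_table()`) and a seeded
synthetic-scene generator (`generate_scene()`) that emulates the study
area's class structure.

## Worked example

```r
library(canopytherm)

pt <- load_patch_table()          # 63 patches: area, perimeter, shape index, cooling rate
sw <- backward_stepwise(pt$cooling_rate_pct,
                        pt[c("area_hm2", "perimeter_km", "shape_index")])
sw
#> backward stepwise elimination
#>   step 1: removed perimeter_km (p = 0.947)
#>   step 2: removed shape_index (p = 0.714)
#>   retained: area_hm2

ols_simple(pt$cooling_rate_pct, pt$area_hm2)
#> y = 0.1179 x + 0.1485   (R2 = 0.102, slope p = 0.01079, DW = 1.955, n = 63)
```

Area is the only predictor that survives elimination: every extra hm² of
canopy raises a patch's cooling rate by ≈ 0.12 percentage points, and a
Durbin–Watson of 1.955 shows no autocorrelation along the patch ordering.
`luoping_reference_report()` reruns all twenty published-value checks
(correlations, both regressions, coverage arithmetic, shape-index
recomputation) and reports pass/fail at each stated tolerance.

The `analysis/` directory holds the five-stage narrative workflow —
`01_simulate_scene.R` (seeded five-class scene), `02_retrieve_lst.R`
(retrieval + Jenks levels), `03_patch_metrics.R` (patch extraction and
metrics), `04_association.R` (correlation/stepwise/OLS), and
`05_coverage_report.R` (coverage potential + reference checks) — each a
thin `Rscript` driver over the package that writes its tables under
`results/`.

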