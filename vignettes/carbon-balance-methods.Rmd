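---
title: "Methods: carbon-balance assessment, trend attribution and driver detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon-balance assessment, trend attribution and driver detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tercab)
```

## The model and its assumptions

`tercab` treats the terrestrial carbon balance of a region as a per-pixel
composite of a *stock* and a *flux*:

$$CB_y = CS_y + NEP_y \cdot \Delta t, \qquad \Delta t = 1\ \mathrm{yr},$$

in Mg/hm², with NEP converted from g C m⁻² yr⁻¹ by the factor 0.01.
Three assumptions are inherited from the bookkeeping tradition and worth
stating plainly:

1. **Carbon density is constant per land-cover class.** Storage changes
   only when classes change; climate does not modulate the density table.
   Consequently the storage trend map is a re-expression of land-cover
   change, and its F-test significance reflects step changes, not gradual
   physiology.
2. **NEP is climate-sensitive through respiration only.** NPP enters as an
   input grid; the model adds the respiration response
   $Rs = 1.55\,e^{0.031T}\frac{P}{P+0.68}\frac{SOC}{SOC+2.23}$ (kg C m⁻²
   yr⁻¹) and the heterotrophic partition $Rh = 0.6163\,Rs^{0.7918}$.
3. **Each year stands alone.** $CB_y$ uses that year's NEP, not a
   cumulative sum. An accumulation variant (carrying NEP forward) would
   change the interannual series' level but not the per-pixel trend tests,
   which operate on any yearly series; we implement the literal
   single-year form and leave accumulation to the caller.

The power-law partition of $Rs$ into $Rh$ was fitted on field data whose
unit convention is not recorded with the equation. We apply it in
kg C m⁻² yr⁻¹ — the unit $Rs$ is produced in — and convert to grams
afterwards. This is the only choice for which tropical NPP of
1200–1800 g C m⁻² yr⁻¹ yields heterotrophic respiration of several
hundred grams and hence sink-scale NEP (at T = 25 °C, P = 2 m,
SOC = 5 kg C m⁻²: Rs ≈ 1.736 kg, Rh ≈ 0.954 kg, NEP ≈ 546 g for
NPP = 1500). Applying the power law in grams instead would produce Rh an
order of magnitude too large.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| precipitation | m yr⁻¹ | — | the Rs saturation constant 0.68 is in metres; `nep(..., precip_unit = "mm")` divides by 1000 |
| $\Delta t$ | yr | 1 | single-year accumulation (assumption 3) |
| significance thresholds | — | 0.01 / 0.05 | define the five trend and six correlation classes |
| t-test $m$ | — | 2 | temperature and precipitation are the two controlled climate variables, df $= n - 3$; configurable because a one-variable convention (df $= n-2$) also circulates |
| no-change tolerance | slope units | 1e-12 | the contribution ratio is undefined at zero observed slope |
| detector strata $k$ | — | 5, quantile | continuous drivers are stratified by quintile; categorical drivers pass through |

## Numerical choices

- **Trend statistics** are computed in the closed summation form of the
  OLS slope with the year index $i = 1..n$ as regressor, vectorised over
  pixels. Degenerate pixels are classified, not dropped: zero total
  variance (constant series) gets slope 0 and $p = 1$; zero residual
  variance with nonzero slope (an exact linear series) gets $p = 0$. The
  exact-fit cutoff is a relative residual share of $10^{-12}$.
- **Partial correlations** use the three-pairwise-coefficient identity;
  pixels where the control variable is collinear with either series
  ($|r| \ge 1 - 10^{-12}$) are flagged undefined rather than propagating
  infinities.
- **Attribution** solves the per-pixel regression $CB = aT + bP + c$ from
  the centred 2×2 normal equations; rank deficiency (constant or
  collinear climate) flags the pixel. Because the slope operator is
  linear, $slope_{CC} + slope_{HA} = slope_{obs}$ holds to rounding, and
  the contribution ratios of the mixed scenarios sum to exactly 100 %.
  Two guards keep the criterion table well defined: observed slopes below
  the no-change tolerance are scenario "no-change", and component slopes
  smaller than $10^{-9} |slope_{obs}|$ are snapped to zero so that an
  exact climate fit lands in the climate-only row (100 % / 0 %) instead
  of a ratio polluted by floating-point dust. Mixed-row ratios can exceed
  [0, 100] when component slopes nearly cancel; they are clipped and the
  clipping is reported.
- **The q statistic** uses population (N-weighted) variances, the form
  under which $\sum_h N_h \sigma_h^2$ telescopes and refining a
  stratification can never decrease q. Empty overlay strata simply do not
  arise as factor levels (`interaction(..., drop = TRUE)`); the
  interaction typing treats $q_{12} = \max(q_1, q_2)$ — the idempotent
  overlay boundary — as the single-factor class, and uses a $10^{-12}$
  tolerance for the independence boundary $q_{12} = q_1 + q_2$.
- **Contribution levels** are left-closed bins [0,20), …, [60,80),
  [80,100]; exactly 20 falls in the second bin, exactly 100 in the fifth.
- **Transfer-matrix change accounting** uses row/column totals minus the
  diagonal. For matrices computed from grids this equals the off-diagonal
  sums exactly; for *printed* matrices, whose cells and totals are
  independently rounded, keeping the printed totals reproduces published
  change numbers to their last digit more often than re-summing rounded
  cells, so `read_transfer_matrix()` preserves printed totals when
  present.
- **Nodata policy**: a pixel enters a multi-year statistic only if every
  required input is finite in every year (one common mask, no per-year
  sample-size drift). Grid alignment is nearest-neighbour only, so class
  grids never acquire interpolated codes.

## The synthetic world

The generator (`scene_config()` / `generate_scene()`) emulates the
statistical structure the analysis assumes, with defaults fixed once to a
tropical-monsoon-island reading: mean temperature 24.5 °C lapsed on a
smooth elevation field at −6 °C/km, precipitation 1.75 m with smooth
spatial structure, a warming trend of 0.03 °C/yr and wetting of
0.002 m/yr, interannual noise of 0.3 °C and 0.15 m, NPP responding as
$200 + 40T + 200P + \mathcal N(0, 80^2)$ g C m⁻² yr⁻¹ (≈1530 at the base
climate), a static log-normal SOC field (mean 5, sd 1.5 kg C m⁻²), land
cover 65 % forest / 29 % cropland evolving by near-diagonal annual Markov
transitions (~0.5 %/yr turnover), and deterministic human-disturbance
patches with recorded footprints. One root seed feeds deterministic
per-variable child streams, so adding a variable does not perturb the
others.

What the generator does **not** emulate: realistic landscape pattern
(patch geometry, fragmentation), spatially correlated noise (fields are
low-order polynomials plus white noise), climate teleconnections, or any
feedback from land cover to climate. A green test therefore establishes
that the *statistical machinery* is correct — slopes, tests, decomposition
and recovery of injected signals — not that the defaults reproduce any
particular region's published magnitudes, which depend on real rasters.

## Open design points, decided

- The common working resolution, unstated in the source tradition, is the
  land-cover grid; synthetic scenes are born co-registered and
  `align_stack()` covers mixed-resolution input.
- Water pixels are *not* force-masked from NEP: masking is the caller's
  decision via nodata, keeping the model function total.
- Human-activity trend maps reuse the five-class trend scheme on the
  residual series; the six-row scenario table and the five trend classes
  answer different questions and both are exposed.
- Raster serialisation is the plain-text ESRI ASCII grid with an optional
  `.prj` sidecar — the portable "equivalent single-band grid" this
  environment supports without binary formats.
- Significance testing of q (noncentral F) is out of scope; magnitudes
  and ranks only.

## Known limitations

Carbon densities are regional means — classes with locally atypical pools
(mangrove, salt marsh) are misrepresented by construction. The residual
convention attributes *everything* the climate regression cannot explain
to "human activity", including model error and unmodelled natural
variability; contribution rates should be read as a decomposition
convention, not a causal estimate. The Rs model's coefficients are taken
as printed and not refitted.
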