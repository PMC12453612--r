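---
title: "Methods: measuring vole-dandelion habitat selection from drone imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring vole-dandelion habitat selection from drone imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(volescape)
```

## The measurement problem

Fossorial water voles are strictly subterranean, but their digging ejects
soil mounds that are conspicuous in aerial RGB imagery of short meadow
swards; dandelion, the vole's key stored winter food, flowers in a brief
synchronized pulse during which each flower head (~7 cm², 3 cm diameter)
is a bright yellow disc. Flying a UAV over fixed 80 m × 60 m quadrats
three times a year (March: over-wintered colonies; May: dandelion bloom;
October: colonies at the end of the breeding season) therefore yields
co-registered maps of a herbivore and its resource. `volescape` turns
those maps into three statistical answers:

* **Q1 (colonization)** — do voles preferentially settle where dandelions
  are dense?
* **Q2 (reuse)** — are old burrows re-occupied when dandelions are still
  present?
* **Q3 (depletion)** — does dandelion density drop after colonization, and
  over what distance around the mounds?

## Pixel classification

A pixel is a dandelion flower when `R > 0.9 & G > 0.9 & B < 0.1`, strict
inequalities, on reflectances scaled to `[0, 1]` (8-bit imagery must be
divided by 255; the function errors on out-of-range bands rather than
guessing the scale). Earth colour varies with soil humidity, so the brown
rule is calibrated per image: `calibrate_brown_window()` takes user-marked
bare-earth pixels and returns the per-band 1st-99th percentile envelope;
`classify_brown()` then tests all three bands against the closed
intervals. Buttercups are also yellow but only ~2 cm²; at 1 cm resolution
`filter_small_components()` removes 4-connected components below 4 pixels,
which cannot be a dandelion head. Head counts are yellow area divided by
7 cm² — a density estimate, deliberately not a component count, so that
touching flowers are not undercounted; the fractional value is preserved.

Component labelling is a two-pass union-find in C++ (no installed R image
package provides it); centroids are unweighted means of member pixel
centres. Raster convention: row 1 is the north edge, point coordinates are
metres from the south-west corner, and a pixel belongs to the tile
containing its centre.

## Tile metrics

Tiles are half-open 2 m squares — 1200 per quadrat, much smaller than a
burrow system (20-60 m²) — and partition the raster exactly, so per-tile
pixel sums conserve whole-quadrat totals; non-divisible quadrat dimensions
are an error rather than a silent partial tile. A tile is *colonized* when
mound cover strictly exceeds 2.5 % (ten small mounds of 5 cm radius).

The dandelion anomaly compares a tile with its quadrat on a
variance-stabilized scale:

$$\mathrm{Anom} = (D_t / D_q)^{1/4} - 1,$$

zero at the quadrat mean and ≈ 0.5 at five times it. The ratio (not
difference) reading is fixed by that anchor. `D_q` is the unweighted mean
of the 1200 tile densities, so the quadrat-mean identity
`mean(D_t) = D_q` holds by construction; quadrats with no flowers at all
have an undefined anomaly and their tiles are excluded from anomaly-based
models. The growth rate `DPGR = ln(flowers_2/flowers_1)` is undefined when
either year has zero flowers (excluded, the conservative choice); an
optional per-year scalar correction for flowering stage (mean heads per
plant) is exposed and defaults to 1, since no correction value is part of
the tile data.

Transition labelling mirrors the campaign design: Q1 uses only tiles
uncolonized in March, scoring October colonization; Q2 uses only tiles
colonized in both October year 1 and March year 2, scoring October year 2.

## Broad-scale models

All broad-scale models carry the quadrat identifier `Q` as a fixed
categorical — including the null rows of the candidate ladders — because
quadrats differ systematically (region, soil, management). The fits are
ordinary IRLS GLMs / OLS:

* `Col ~ Anom * D_q + Q`, binomial logit;
* `Reuse ~ D_t + D_t:D_q + Q`, binomial logit (no `D_q` main effect: with
  one campaign it is absorbed by `Q`; the interaction is what carries
  information);
* `DPGR ~ log(Cover + 1) + Q`, OLS, with `Cover` in **percent** (the
  `log(x+1)` transform is scale-dependent, and the percent scale is the
  one the cover model is defined on).

`D_q` is constant within a quadrat-campaign, so its main effect is only
separable from `Q` because two annual transitions are pooled; the
pipeline stacks both years, and the direct tile generator
(`simulate_colonization_tiles()`) likewise gives every quadrat two
year-transitions. Model selection is forward-stepwise by AIC; the explicit
published ladders (9 colonization models, 6 reuse, 3 growth, 5 depletion)
are also evaluated verbatim by `colonization_ladder()` etc., with
non-converging candidates reported as missing rather than dropped. Ties
break toward fewer parameters.

"Explained variance" is not defined unambiguously for a GLM; we report the
deviance-based pseudo-R² `1 − D_res / D_null` with the null being
intercept-only *without* `Q`, and keep raw deviances in the fit object so
any alternative can be recomputed. Prediction curves (probability against
anomaly at the 10/50/90 % quantiles of quadrat density, over the 1st-99th
percentile of the observed anomaly) average the quadrat effects on the
linear-predictor scale, making them invariant to factor relabelling.

## Fine-scale depletion

Each of the (field: 46) subplots is a 20 m window centred on one isolated
colony with every mound and flower mapped as a point. Distances are
flower-to-nearest-mound-centroid (mounds are mapped as points, not
polygons). Twenty buffers span 5 cm to 5 m with constant edge ratio
$100^{1/20} \approx 1.2589$; a buffer's representative distance `DM` is
the geometric mean of its edges. The depletion ratio is

$$DD = \frac{\text{flowers in buffer} / \text{buffer area}}
            {\text{total flowers} / \text{subplot area}},$$

i.e. counts are **area-normalized** before division — the only reading
under which `DD = 1` everywhere when flowers are uniform, which is what a
depletion *ratio* must do under the null. The buffer area is the area of
the distance-to-nearest-mound band (union of per-mound annuli minus
overlaps, clipped to the subplot), computed by rasterizing the distance
field at 1 cm; a naive per-mound ring area (`area_method = "ring"`) is
kept as an option for comparison. Flowers closer than 5 cm fold into the
innermost buffer, whose area band likewise starts at 0, keeping the
normalization consistent.

The depletion model is `dd ~ s(log(dm), bs = "cr") + s(subplot, bs = "re")`
fitted by `mgcv::gam(..., method = "REML")`: a penalized cubic spline in
log distance plus a ridge-penalized subplot random intercept that absorbs
the dependence among a subplot's 20 buffers. The reported curve excludes
the random effect and carries a pointwise ±1.96 SE band. "Depletion
measurable up to *x* m" is operationalized as the largest distance at
which that band still excludes 1 from below — the criterion is not fixed
by the field protocol, so we chose the simplest interval-based one.

## The synthetic world

The generator is first-class, tested code; its defaults state a world:

| parameter | default | rationale |
|---|---|---|
| quadrat | 80 m × 60 m at 1 cm/px | field layout |
| flower pattern | Thomas process, κ = 0.05 parents/m², μ = 60, σ = 1.5 m | density varies "on a scale of a few square metres"; ~3 heads/m², inside the observed 0-58 range |
| flower head | 3 cm disc (~7 px) | field size; `"stamp7"` renders exact 7-pixel crosses |
| buttercups | 0.2 /m², 1-2 px dots | distractors the size filter must reject |
| colony | 15-30 mounds, radii 5-25 cm, on a 4 m territory disc | field colony definition; ~50 m² territory |
| colonization logit | (−4, 1.803, 0.0115, −0.0195) | slopes are the published fit; the intercept gives a seed rate of a few percent so that, after the ~12-tile territory footprint, the cover-based colonized fraction brackets the observed ~18 % |
| reuse logit | (−0.6, −0.0263, 9e−4) | slopes from the published fit; intercept gives ~35 % baseline reuse |
| depletion kernel | retain with prob `1 − δ·max(0, 1 − d/4 m)`, δ = 0.8 | simplest monotone kernel with the observed ~4 m range |
| sensor noise | Gaussian, SD 0.02, background and mounds only | flowers saturate the sensor; noise exercises the per-image brown calibration |

A survey series draws, in fixed order from one seeded RNG stream: year-1
flowers, buttercups, March colonies, October colonizations (on tiles not
already colonized), over-winter persistence, year-2 depletion around
active colonies, per-colony reuse from year-2 density at the colony's seed
tile, then year-2 colonizations. Identical parameters and seed give
bit-identical ground truth and rasters.

Ground truth stores the colonized-tile set **twice**: the tiles the logit
seeded, and the tiles whose rasterized mound cover exceeds 2.5 % — a
colony's territory spills over several 2 m tiles, so only the cover-based
set is recoverable from imagery, and that is the set the lossless
round-trip test demands exactly. What the generator does *not* emulate:
photogrammetric distortion, shadows, vignetting, stitching seams, grass
phenology, mole or boar disturbance, or any vole demography beyond
presence/absence — a green round-trip test therefore establishes the
correctness of the analysis chain, not the field performance of the
thresholds on real imagery.

The fine-scale generator uses homogeneous Poisson flowers inside
subplots (so the null profile is flat by construction) and draws each
subplot's depletion deficit around δ with SD 0.15, creating the
between-subplot heterogeneity the GAM's random intercept absorbs. For
model-*selection* experiments, `simulate_depletion_records()` instead
draws buffer records directly from the selected structure — a curve
linear in log distance up to the 4 m range plus subplot offsets — since
selection consistency is a statement about data generated from the model
being compared.

## Numerical choices and degenerate inputs

* Strict vs closed inequalities follow the stated rules exactly: yellow
  thresholds strict, brown window closed, colonization cover strict.
* Thomas parents are simulated with a 6σ guard margin so the expected
  clipped count equals κAμ up to a negligible edge term.
* IRLS non-convergence is an error *unless* residual deviance is ~0
  (a constant/saturated response is degenerate, not separated); quadrats
  with a single outcome level are flagged.
* `d_q = 0` (anomaly), zero-flower years (DPGR), empty mound sets
  (distance profile) and zero-flower subplots (DD) all signal rather than
  silently producing numbers.
* Rcpp is used only where R has no vectorized form (component labelling);
  everything else is vectorized base R plus `mgcv`.

## Known limitations

* Colour thresholds are the field protocol, not a trained segmenter; real
  imagery with specular grass, dew or mixed pixels will need the brown
  window re-trained per image, as designed, and may still misclassify.
* Mound centroids stand in for mound polygons in the distance profile;
  distances are therefore biased slightly upward for large mounds.
* The series generator keeps a colony's mound set fixed between surveys
  (no within-season growth is described for the field system) and lets
  all colonies survive the winter; reuse is drawn per colony, not per
  tile.
* With GeoTIFF tooling absent from the target environment, rasters live
  in memory (arrays with a resolution attribute) and interchange formats
  are plain CSV; the coordinate contract matches the GIS convention so a
  reader/writer can be bolted on without touching the analysis.
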