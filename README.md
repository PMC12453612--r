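# volescape

Drone-based measurement of habitat selection by the fossorial water vole
(*Arvicola amphibius*) on dandelion (*Taraxacum officinale*) density in
mountain meadows.

In mid-altitude grasslands, water voles reach outbreak densities and eject
soil mounds that are clearly visible from the air, while dandelions — a key
winter food the voles store as roots — flower in a short synchronized pulse.
Repeated UAV orthomosaics of 80 m × 60 m meadow quadrats at 1 cm/pixel
therefore capture both species at once. `volescape` reimplements that
analysis chain as a tested R pipeline, for ecologists studying
plant–herbivore interactions and for anyone who needs tile-level habitat
selection statistics from RGB threshold imagery:

- **Pixel classification** — dandelion flower heads as yellow pixels
  (`R > 0.9`, `G > 0.9`, `B < 0.1` on reflectances in [0, 1]), earth mounds
  as brown pixels inside a per-image calibrated RGB window; buttercup
  distractors (~2 cm²) removed by a connected-component size filter; heads
  counted as yellow area / 7 cm².
- **Tile metrics** — 2 m × 2 m tiles (1200 per quadrat); mound cover with
  the strict 2.5 % colonization rule; tile density `D_t`, quadrat mean
  `D_q`, and the fourth-root **dandelion anomaly**
  `Anom = (D_t / D_q)^{1/4} − 1` (0 at the quadrat mean, ≈ 0.5 at 5× it).
- **Habitat models** — new-colonization logit
  `Col ~ Anom * D_q + Q`, burrow-reuse logit `Reuse ~ D_t + D_t:D_q + Q`,
  growth-rate regression `DPGR ~ log(Cover + 1) + Q` with
  `DPGR = ln(flowers_2 / flowers_1)`; forward-stepwise AIC selection over
  the published candidate ladders, always with the quadrat identifier `Q`
  as a fixed factor.
- **Fine-scale depletion** — 20 logarithmic distance buffers from 5 cm to
  5 m around mound points; depletion ratio
  `DD = (buffer density) / (subplot mean density)`; penalized-spline GAM
  `DD ~ s(log DM) + s(Subplot, bs = "re")` (mgcv, REML).
- **Synthetic scenes** — a generator with exact ground truth (Thomas-cluster
  flowers, colonies of 15–30 mounds on ~4 m territories, logistic
  colonization, linear-ramp flower thinning to 4 m, 3-band rendering), so
  the whole chain is testable without field imagery.

## Worked example

```r
library(volescape)

params <- scene_params(quadrat_width = 40, quadrat_height = 30)
ser <- simulate_series(params, seed = 42)          # 6 survey dates, rendered
tiles <- tile_table_from_series(ser, quadrat_id = "Q01")
mean(tiles$col_october_y1)                         # 0.283: colonized fraction

d <- simulate_colonization_tiles(seed = 42)        # 24,000 tile records
fit_colonization_model(d)
#> <vole_fit: col ~ anom * d_q + quadrat>
#>   n = 24000, df = 23, AIC = 18570.0, explained variance = 0.054
#>             Estimate Std. Error  z value Pr(>|z|)
#> (Intercept)  -1.4954     0.0788 -18.9784        0
#> anom          1.7751     0.0936  18.9722        0
#> d_q           0.0104     0.0018   5.7048        0
#> anom:d_q     -0.0204     0.0042  -4.8928        0
```

The anomaly slope (generated at 1.8) is the habitat-selection signal: tiles
locally richer in dandelions than their quadrat are preferentially
colonized, and the negative interaction says local anomalies matter most
where the quadrat as a whole is poor. The full candidate ladder ranks the
generating structure first:

```r
colonization_ladder(d)
#>                    model df     aic delta_aic explained_variance
#>              col ~ 1 + Q 20 19157.1     587.1              0.024
#>           col ~ anom + Q 21 18634.6      64.6              0.051
#>  ...
#>     col ~ anom * d_q + Q 23 18570.0       0.0              0.054
```

Fine-scale depletion around colonies:

```r
sp  <- simulate_subplots(20, scene_params(), seed = 42)
rec <- depletion_profiles(sp, resolution = 0.02)
fit_depletion_gam(rec)
#> <depletion_fit: AIC = 44.4, edf = 19.2, depletion measurable to 3.07 m>
```

i.e. flower density rises with distance from the mounds and the pointwise
interval of the fitted curve stops excluding 1 at ~3 m (the generator thins
flowers out to 4 m).

An end-to-end run (simulate → classify → tiles → fits → depletion, with a
JSON manifest of artifacts and checksums) is one call:

```r
run_pipeline(run_config(out_dir = "run1", seed = 1))
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on the synthetic world —
simulated quadrat series, classification, tile tables, the three model
fits with their AIC ladders, and the depletion GAM — and writes the JSON
report to `--out`.
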