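# aavrange

Estimating how far an AAV-delivered therapeutic factor reaches beyond the
cells it transduces — and what that reach means for the minimum viral dose.

## The problem

AAV cardiac gene therapy conventionally needs a 30–40% transduction mosaic
for organ-level effect, forcing high vector doses. When the cargo works
through a *secreted* effector (here: a microRNA repressing CTGF, a paracrine
driver of extracellular-matrix remodelling and cardiomyocyte hypertrophy),
each infected cell also treats its uninfected neighbours — a
non-cell-autonomous effect — and far fewer infected cells should suffice.
`aavrange` implements the quantitative chain from single-cell morphometry to
that minimum infection rate:

1. **Effective paracrine range.** OLS of uninfected-cell cross-sectional
   area *Y* (μm²) on distance *X* (μm) to the nearest infected cell,
   `Y = b0 + b1 X`, intersected with the lower 95% confidence bound *L* of
   the mean hypertrophic cell area:

   `X* = (L − b0) / b1`

   With the published coefficients (`Y = 202.723 + 1.193 X`, *L* = 304.7 μm²)
   this gives `X* = 85.48` μm.

2. **Minimum infection rate.** Cardiomyocytes as 120 × 20 × 20 μm cuboids in
   a 3D lattice; count the neighbours *N* of one infected cell covered
   within radius `X*` of its margins (whole-cell, half-volume, or centre-in
   criteria). One infected cell per block of *N* + 1 cells covers the
   tissue:

   `f = 1 / (N + 1)`

A calibrated synthetic morphometry generator (noise SD solved from the
target Pearson correlation via `R² = b1²Var(X) / (b1²Var(X) + σ²)`) stands
in for the study's animal data, so the whole chain is testable offline.

## Worked example

```r
library(aavrange)
report <- run_pipeline(pipeline_config(seed = 1))
report
#> == Paracrine range / minimum dose pipeline ==
#> Distance-area regression: area = 203.272 + 1.309 * distance
#>   Pearson R = 0.294, p = 7.441e-08, n = 322, residual SD = 134.3 um^2
#> Hypertrophic area threshold: mean 333.7 um^2, 95% CI [310.2, 357.3] (n = 100)
#> Effective paracrine range X* = 81.65 um (line crosses the 310.2 um^2 bound from below)
#> Coverage radius used: 81.65 um
#> Coverage at radius 81.6 um (whole_cell): N = 48 affected neighbours
#>   minimum infection rate 1/49 = 2.04% (neighbours alone: 1/48 = 2.08%)
#> Coverage at radius 81.6 um (half_volume, voxel 1 um): N = 142 affected neighbours
#>   minimum infection rate 1/143 = 0.70% (neighbours alone: 1/142 = 0.70%)
#> Coverage at radius 81.6 um (center_in): N = 142 affected neighbours
#>   minimum infection rate 1/143 = 0.70% (neighbours alone: 1/142 = 0.70%)
#> Non-cell-autonomy index: 0.181
```

Reading the output: one seeded synthetic run recovers a regression close to
the generating line (slope 1.309 vs true 1.193 — single-replicate sampling
noise), estimates the paracrine range at 81.65 μm from its own fit (not a
hard-coded radius), and converts it into minimum infection rates around
0.7–2% depending on the coverage criterion. The non-cell-autonomy index says
uninfected cells in the treated arm are 18% smaller than uninfected
pressure-overload controls. The coverage stage always consumes the range the
regression stage estimated; pass `radius_um = 84.5` to evaluate the
published radius instead, and `convention_sweep()` to compare packing and
classification conventions against the published coverage totals (see the
methods vignette, `vignettes/paracrine-range-model.Rmd`, for what matches
and what does not).

Stage functions are usable on their own — `simulate_cells()`, `fit_ols()`,
`mean_lower_ci()`, `effective_range()`, `count_affected()`,
`summarize_animals()`, `compare_groups()` — and a thin CLI wraps them:

```sh
Rscript inst/scripts/aavrange-cli.R coverage --radius 84.5 --criterion whole_cell
Rscript inst/scripts/aavrange-cli.R all --seed 1 --out results/
```

File formats: cell tables are plain CSV with header
`cell_id, animal_id, arm, gfp_positive, gfp_intensity, area_um2, distance_um`
(one row per cell, empty distance for GFP+/sham cells); pipeline configs are
YAML or JSON with keys `seed`, `conf_level`, `radius_um`, `criteria`,
`synthetic`/`aac` (generator parameters), `lattice` (`cell_dims`, `packing`);
reports are JSON and round-trip byte-stably via `write_report()` /
`read_report()`.

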