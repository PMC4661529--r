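# mtbench

Quantifying protein–protein interactions on the microtubule bench:
expression-corrected colocalization analysis for two-channel fluorescence
micrographs, with a ground-truthed synthetic-cell simulator.

## The problem

In a microtubule-bench relocation assay, a bait protein fused to the
microtubule-associated protein Tau decorates the microtubule network of a
living cell. Recruitment of a fluorescent prey onto the filaments reveals
a bait:prey interaction as shared filamentous structure in the two
channels. The platform is effectively unsaturable — treating microtubules
as 25 nm cylinders, ~70 µm² of lateral surface per cell anchors
`floor(70e6 / 10) = 7e6` bait copies at a 10 nm² footprint — but the
readout has a serious confound: at high bait expression, nonspecific
recruitment inflates apparent colocalization even for non-interacting
pairs.

## The method

Per cell, with bait image *B* and prey image *G* (registered to subpixel
precision by phase correlation):

1. High-pass filter both channels in the frequency domain, removing
   structures larger than 2 µm, so only filament-scale features remain.
2. Select three fixed-area ROIs (64 × 64 px) where microtubules are
   clearly visible in the bait channel (highest filtered-signal SD,
   non-overlapping, deterministic).
3. In each ROI compute the Spearman rank correlation
   ρ = cor(rank *B*, rank *G*) — with no ties,
   ρ = 1 − 6Σd²/(n(n²−1)) — and average the three values.
4. Estimate the cell's bait expression *E* as its background-subtracted
   mean intensity, and fit ρ = ρ₀ + s·E across cells by ordinary least
   squares. The intercept **ρ₀, the coefficient extrapolated to zero
   bait expression**, estimates colocalization in an unperturbed cell and
   cancels the expression-driven false positive.
5. Compare conditions with a two-tailed t-test on the intercepts
   (`**` p < 0.01, `*` p < 0.05).

The simulator (`sim_config()`, `simulate_cell()`, `simulate_condition()`)
grows persistent-random-walk microtubule networks, renders bait/prey
channels with a known interaction strength κ and a nonspecific term
η·E_b, applies PSF blur and Poisson–Gaussian camera noise, and keeps the
ground truth, so the whole pipeline is testable end to end.

## Worked example

Three simulated prey conditions — strong (κ = 0.8), moderate (κ = 0.3)
and null (κ = 0), all with the same nonspecific confound η = 0.02 —
20 cells each across a lognormal expression design:

```r
library(mtbench)
conds <- data.frame(name = c("strong", "moderate", "null"),
                    kappa = c(0.8, 0.3, 0), eta = 0.02)
measurements <- purrr::map_dfr(seq_len(3), function(i) {
  cfg <- sim_config(interaction_strength = conds$kappa[i],
                    nonspecific_coefficient = conds$eta[i])
  measure_cells(simulate_condition(cfg, expression_grid(20),
                condition = conds$name[i], seed = 5037 + i))
})
condition_report(measurements, control = "null")
```

which prints (seed-exact):

```
  condition intercept intercept_sd n_cells  p_value stars
1  moderate    0.0361      0.01133      20 1.19e-01
2      null    0.0129      0.00915      20       NA  <NA>
3    strong    0.0784      0.00829      20 6.01e-06    **
```

Reading: the extrapolated zero-expression coefficients order with the
simulated interaction strength (0.078 > 0.036 > 0.013); the strong
condition is decisively separated from the null (`**`), while the null's
intercept is statistically indistinguishable from 0 even though its
*raw* coefficients reach ~0.25 in the brightest quartile of cells — the
inflation the extrapolation removes. `autoplot(fit_zero_expression(measurements))`
draws the per-cell scatter with the fitted lines;
`plot_condition_report()` draws the intercept bars with stars.

A disk-backed pipeline (`bench_simulate()` → `bench_analyze()` →
`bench_fit()`, also wrapped by `inst/cli/mtbench.R`) exchanges 16-bit
TIFFs and CSV tables with metadata headers and is byte-reproducible per
seed.

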