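# bcpbudget

Carbon export and sequestration budgets for the three pathways of the
ocean's biological carbon pump (BCP) in a coastal upwelling biome:
**sinking particles**, **active transport** by diel vertically migrating
zooplankton and fish, and the **physical pump** (subduction + vertical
mixing of particles). The package is written for marine biogeochemists who
have depth-resolved flux observations — sediment-trap profiles,
day/night-paired zooplankton tows, modelled subduction profiles, Lagrangian
float fates — and want a tested, reproducible route from those tables to
areal and regional carbon-sequestration stocks with uncertainty.

## What it computes

**Sinking flux attenuation.** Trap fluxes are fit to a Martin-type power
law `F_i(z) = f_i,100 (z/100)^-b` with one shared regional exponent `b`
and a free 100-m flux per deployment, by random-walk Metropolis MCMC on
the misfit

```
SSNM = Σ_i Σ_j (F_ST,i,j − f_i,100 (z_ij/100)^−b)² / σ_ij²
```

with likelihood kernel `exp(−SSNM/2)`, prior `b ~ N(1.2, 0.5)` and uniform
priors on `(0, 5000)` mmol C m⁻² d⁻¹ for the fluxes. The regional curve
`F̄_z = F̄_100 (z/100)^−b̄` is anchored by an e-ratio × NPP extrapolation
(`e-ratio = 0.056·SST − 0.698`, clipped to [0, 1]) and differentiated into
a remineralization density `r(z) = b̄ F̄_100 100^b̄ z^−b̄−1`.

**Active transport.** Night-minus-day biomass differences above each 50-m
horizon (floored at zero per taxon × size class) give the daytime residence
distribution of migrant biomass; allometric respiration at residence-depth
temperature plus 31% excretion, and a fish term distributed as a
N(450 m, 50 m) residence density, yield flux-across-horizon profiles that
are bootstrap-averaged across experiments.

**Sequestration time.** Mean time `g(z)` before carbon remineralized at
depth `z` returns to the mixed layer is estimated from float fate records
by the iterative censored-mean fixed point

```
g(z) = ( Σ t_mld + Σ (t_f + g(z_final)) + Σ (t_b + g(z_final)) ) / n_z
```

with a shape-preserving piecewise-cubic interpolant between release depths
and a constant extension below 1000 m.

**Budget.** Each pathway's areal stock is `∫ g(z) r(z) dz` plus the deep
tail, converted to mol C m⁻²; regional stocks use the 1.7 × 10⁵ km² domain
and 12.011 g mol⁻¹. Export-efficiency metrics (EZ-ratio, T₁₀₀), pathway
shares by horizon, and a Spearman screen of export proportions against
ecosystem metrics round out the outputs. Synthetic generators with known
ground truth emulate all six input tables, so every stage has a
parameter-recovery test and nothing requires a download.

## Worked example

```r
library(bcpbudget)

# regional sinking-flux curve from the regional mean export and exponent
curve <- flux_curve(F100_mean = 9.0, b_mean = 0.72)
flux_at_depth(curve, c(200, 500, 1000))
#> flux at 200/500/1000 m: 5.5 / 2.8 / 1.7 mmol C m-2 d-1

# sequestration-time curve (here: an illustrative knot set rising from
# 102 yr at 100 m to 1335 yr at 1000 m) integrated against r(z)
g <- fit_g_interpolant(c(100, 150, 200, 300, 400, 500, 750, 1000),
                       c(102, 170, 240, 380, 520, 660, 1000, 1335))
z <- seq(100, 4000, 1)
areal <- sequestration_integral(z, remineralization_density(curve, z),
                                flux_at_depth(curve, 4000), g,
                                region_config(deep_g_value = 1335))
areal
#> areal sinking sequestration: 1799 mol C m-2
mean_duration(areal, 9.0);  regional_total(areal)
#> mean duration: 547 yr; regional stock: 3.7 Pg C

pathway_fractions(c(sinking = 9.0, active = 2.9, subduction = 3.8))["sinking"]
#> sinking share of 100-m export: 57%
```

Reading: with a 100-m export of 9.0 mmol C m⁻² d⁻¹ attenuating as
`z^-0.72`, flux reaching 1000 m is 1.7 mmol C m⁻² d⁻¹; weighting each metre
of remineralization by its sequestration time gives ~1.8 kmol C m⁻² held in
the ocean interior at steady state, i.e. a mean sequestration duration of
~550 yr, and sinking carries 57% of the combined 100-m export.

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline on synthetic
inputs and write tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | generate the six input tables + ground-truth sidecars |
| `02_fit_attenuation.R` | Metropolis fit of `b`, regional flux curve with Monte Carlo CIs |
| `03_active_transport.R` | migrant residence, bioenergetics, fish term, bootstrap regional mean |
| `04_physical_pump.R` | regional subduction profile, attenuation fraction, layer densities |
| `05_sequestration.R` | censored-mean `g(z)` with launch-cohort uncertainty |
| `06_budget.R` | pathway budgets, export shares, efficiency metrics, correlation screen |

`run_pipeline(pipeline_config(...))` chains the same stages in one call and
is bit-reproducible for a fixed seed.

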