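# aerohab

Interannual-to-decadal predictability of aerobic habitat viability in the
upper ocean, measured through the normalized Metabolic Index.

## The problem

Marine species need enough dissolved oxygen to meet a metabolic demand that
grows with temperature. The Metabolic Index Φ expresses this balance as the
ratio of O₂ supply to resting demand,

    Φ = A_o · pO₂ / exp{ −E_o/k_B · (1/T − 1/T_ref) }

where pO₂ is the partial pressure of dissolved oxygen (computed from the O₂
concentration via the temperature- and salinity-dependent solubility), A_o
is the hypoxic tolerance of the species, E_o its temperature sensitivity
(eV), k_B the Boltzmann constant and T_ref = 288.15 K. Working with the
normalized index φ = Φ/Φ_crit (traits normalized so A_c = A_o/Φ_crit),
habitat is viable wherever φ > 1. E_o is corrected linearly in temperature,
E_o → E_o + dE_o/dT · (T − T_ref) with dE_o/dT = 0.022 eV/K.

The package asks: how far ahead can initialized ensemble hindcasts predict
yearly φ anomalies, relative to a simple persistence forecast, and which
driver — O₂ (split into solubility and apparent oxygen utilization),
temperature, or salinity — carries that predictability for ecotypes across
the trait space? It provides, as tested reusable modules:

* **Metabolic index**: Garcia–Gordon O₂ solubility, pO₂, AOU, cellwise φ,
  annual averaging, and thickness/area-weighted layer and region averages.
* **Habitat geometry**: φ > 1 masks, ±3σ interannual envelopes, vertical
  habitable depth ranges with contraction/expansion bands.
* **Forecast verification**: lead-dependent drift adjustment, uncentered
  anomaly correlation (ACC) and normalized mean absolute error (NMAE),
  persistence baseline, significance with effective degrees of freedom,
  a dependent-correlation test for the ACC improvement, and the
  predictability timescale (longest significant run from lead year 1).
* **Taylor attribution**: analytic ∂φ/∂O₂, ∂φ/∂T, ∂φ/∂S; first-order driver
  components with exact O₂sol/AOU split; variance/covariance budget;
  per-component forecast skill.
* **Synthetic ensemble generator**: a red-noise (AR(1)) monthly
  reconstruction with coupled T/S/O₂ anomalies plus initialized ensemble
  forecasts with prescribed lead-dependent skill and drift — ground truth
  for every downstream stage.
* **Pipeline**: one config drives generate → index → skill → decompose →
  trait sweep, with deterministic seeding and a manifest.

## Worked example

```r
library(aerohab)
grid   <- grid_spec()              # 6 x 6 cells, 10 depths over 0-600 m
params <- synth_params(seed = 1)   # 64 inits x 10 members x 10 lead years
recon  <- generate_reconstruction(grid, params)
fcst   <- generate_forecasts(recon, params)

ecotype <- trait_set(A_c = 10, E_o = 0.4)        # medium-E_o species
phi    <- annual_mean(metabolic_index(recon, ecotype))
r_ser  <- layer_region_average(phi$phi, grid, layer = "upper", region = 1)
f_em   <- ensemble_mean(drift_adjust(
  layer_region_average(metabolic_index(fcst, ecotype)$phi, grid, "upper", 1)))
skill_vs_persistence(f_em, fcst$init_years, r_ser, phi$years)
```

```
<skill_comparison> timescale: forecast 10 yr, persistence 2 yr (alpha = 0.05)
 lead acc_dple acc_pers delta_acc  p_delta sig_delta
    1    0.970   0.5358     0.434 9.60e-13      TRUE
    2    0.954   0.3299     0.624 7.86e-11      TRUE
    3    0.938   0.0171     0.921 1.10e-11      TRUE
 ...
   10    0.709   0.0943     0.614 7.14e-04      TRUE
```

The initialized ensemble keeps a significant ACC through all ten lead years
(timescale 10 yr in this synthetic world, whose prescribed member skill is
0.9^τ), while persistence decays within two years — so the improvement
ΔACC is significant at every lead. The variance budget attributes φ's
interannual variance to the drivers:

```r
dr  <- annual_mean(recon)
dec <- taylor_decompose(
  layer_region_average(dr$vars$T,  grid, "upper", 1),
  layer_region_average(dr$vars$S,  grid, "upper", 1),
  layer_region_average(dr$vars$O2, grid, "upper", 1), ecotype)
variance_budget(dec)
#>           term      value
#>        var_phi  1.867e-04
#>         var_O2  1.414e-04
#>          var_T  9.539e-06
#>          ...
#>  residual_term  4.367e-08
```

Here the O₂ component carries ~76% of var(φ) directly (and more through
its covariance with T), with the AOU part dominating the solubility part —
the attribution pattern the Taylor machinery is built to expose. The full
sweep over ecotypes (E_o from −0.2 to 1.0 eV in 0.1 eV steps at
A_c = 10 atm⁻¹) runs with:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "run")
head(res$sweep)   # region, layer, E_o, lead, acc, sig, timescale, acc_O2, ...
```

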