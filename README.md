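# odormix

Predicts the perceived odor intensity (OI) of multi-component odorant
mixtures directly from gas-phase chemical concentrations, so that routine
instrumental monitoring (e.g. GC measurements of indoor aromatic VOCs) can
be translated into the perceptual quantity a trained sensory panel would
otherwise have to rate.

## Who it is for

Air-quality and odor-pollution practitioners who measure component
concentrations and need a panel-free OI estimate; sensory scientists
calibrating mixture-interaction models for a chemical family; anyone who
needs the classic Vector Model, Strongest Component Model or summation
baselines behind one consistent interface.

## The model

For component *i* with concentration *C_i* and odor threshold *C_Thr,i*
(mg/m³), the odor activity value is OAV_i = C_i / C_Thr,i, and individual
intensity follows the log-linear psychophysical law

    OI_i = k · ln(OAV_i)

The modified Vector Model predicts an n-component mixture with a single
shared pairwise interaction coefficient cos α:

    OI_mix = k · sqrt( Σ_i x_i² + 2·cos α · Σ_{i<j} x_i·x_j ),   x_i = ln OAV_i

cos α is not fitted per pair: when equal-intensity binary mixtures of a
chemical family follow one counteraction law OI_mix = β(OI_a + OI_b),
substitution into the Vector Model's cosine relation gives the closed form

    cos α = 2β² − 1

The packaged constants, calibrated on seven aromatic compounds, are
k = 1.07 and β = 0.66 ⇒ cos α = −0.129 (so the cross terms carry −0.258).
They transfer only within chemically similar families; `calibrate()` refits
both constants from panel data.

## Worked example

```r
library(odormix)

# binary toluene + ethylbenzene sample with lnOAV 3.36 and 3.54
modified_vector_model(c(3.36, 3.54))
#> [1] 4.874369
```

4.87 (4.9 at one decimal) against a panel-measured 5.4 — the mixture smells
weaker than the summation baseline 1.07·(3.36+3.54) = 7.38 because the
components counteract. Scoring both models on the shipped 15-sample
aromatic validation table:

```r
ev <- evaluate_table(aromatic_mixtures(), models = c("mvm", "scm"),
                     rounding = "table")
ev
#> Odor-intensity evaluation (15 samples, rounding mode 'table')
#> # A tibble: 15 × 6
#>    sample_id measured_oi oi_mvm ratio_mvm oi_scm ratio_scm
#>    <chr>           <dbl>  <dbl>     <dbl>  <dbl>     <dbl>
#>  1 TE-1              5.4    4.9     0.907    3.8     0.704
#>  2 TE-2              4      3.9     0.975    3.2     0.8
#>  ...
#>
#> Mean predictive coefficient (OI_pre / OI_mea):
#>   mvm  0.97   (rmse 0.53, mae 0.45)
#>   scm  0.78   (rmse 1.15, mae 1.03)
```

The mean predictive coefficient (predicted/measured; 1.0 = perfect) shows
the modified Vector Model (0.97) clearly outperforming the strongest-
component baseline (0.78), which systematically under-predicts because it
ignores every component but the largest. Calibration from (synthetic) panel
data recovers the constants:

```r
study <- generate_study(seed = 42)          # simulated 9-assessor campaign
calibrate(study$individual, study$binary)
#> Odor-mixture model calibration
#>   k         = 1.06  (psychophysical slope; 28 points, residual rms 0.097)
#>   beta      = 0.66  (counteraction slope; 32 points, residual rms 0.145)
#>   cos(alpha) = -0.118  (= 2 beta^2 - 1)
```

A command-line interface wrapping the same functions ships at
`inst/cli/odormix.R` (subcommands `predict`, `calibrate`, `evaluate`,
`simulate`).

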