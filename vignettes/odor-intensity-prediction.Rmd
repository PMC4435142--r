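---
title: "Predicting mixture odor intensity from chemical concentrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mixture odor intensity from chemical concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odormix)
```

## The problem

Odor intensity (OI) — how strong an air sample smells — is normally rated by
a trained human panel against an odor intensity referencing scale (OIRS),
which makes it expensive and confines it to specialized laboratories.
Chemical concentrations, on the other hand, are routine to measure by gas
chromatography. `odormix` bridges the two: it predicts the OI of a
multi-component odorant mixture directly from the measured concentrations of
its components, so that instrumental monitoring of, say, indoor aromatic
VOCs can be translated into a perceptual quantity without convening a panel.

Two empirical regularities make this possible for odorants of a common
chemical family:

1. **A log-linear individual psychophysical law.** Define the odor activity
   value of component $i$ as $\mathrm{OAV}_i = C_i / C_{\mathrm{Thr},i}$,
   the ratio of its concentration to its odor threshold. For single
   odorants, perceived intensity is proportional to the natural log of OAV:
   $$\mathrm{OI}_i = k \,\ln \mathrm{OAV}_i,$$
   a Weber–Fechner-type relation. The packaged default $k = 1.07$ was
   fitted on seven aromatic compounds (benzene, toluene, ethylbenzene,
   n-propylbenzene, o-xylene, m-xylene, styrene); it is family-specific and
   should be recalibrated for other chemistries.

2. **A shared pairwise interaction.** The classic Vector Model represents a
   binary mixture's OI as the diagonal of a parallelogram with sides
   $\mathrm{OI}_a$, $\mathrm{OI}_b$ and angle cosine $\cos\alpha$:
   $$\mathrm{OI}_{ab}^2 = \mathrm{OI}_a^2 + \mathrm{OI}_b^2 +
     2\cos\alpha\,\mathrm{OI}_a\mathrm{OI}_b.$$
   Classically $\cos\alpha$ must be measured per pair. But when
   equal-intensity binary mixtures of a chemical family all follow one
   proportional counteraction law
   $\mathrm{OI}_{\mathrm{mix}} = \beta(\mathrm{OI}_a + \mathrm{OI}_b)$,
   substituting that law into the cosine relation collapses every pair to a
   single constant:
   $$\cos\alpha = 2\beta^2 - 1.$$
   For the aromatic family $\beta = 0.66$, giving $\cos\alpha = -0.129$ —
   a mild, shared counteraction.

Combining both, the **modified Vector Model** predicts an $n$-component
mixture from lnOAV values alone:
$$\mathrm{OI}_{\mathrm{mix}} = k\sqrt{\sum_i x_i^2 +
  2\cos\alpha \sum_{i<j} x_i x_j}, \qquad x_i = \ln\mathrm{OAV}_i .$$
With $k = 1.07$ and $\cos\alpha = -0.129$ the cross terms carry the
coefficient $-0.258$. For $n = 1$ this reduces to the individual law; the
extension beyond $n = 4$ keeps the same quadratic form with the one shared
coefficient, the only generalization consistent with the binary, ternary
and quaternary forms.

Baselines provided for comparison: the **Strongest Component Model** (SCM),
$k\max_i x_i$, and the full-additivity **summation** $\sum_i k\,x_i$, which
is also the $\mathrm{OI}_{\mathrm{sum}}$ axis that $\beta$ is fitted
against.

## A worked example

```{r example}
library(odormix)

aromatic_odorants()

# binary toluene + ethylbenzene sample, lnOAV 3.36 and 3.54
modified_vector_model(c(3.36, 3.54))        # panel measured 5.4
strongest_component_model(c(3.36, 3.54))

# the full validation table
ev <- evaluate_table(aromatic_mixtures(), models = c("mvm", "scm"),
                     rounding = "table")
ev
```

## Calibration

`calibrate()` estimates both constants from panel data:

* `k` from individual-odorant points `(lnOAV, panel-mean OI)`;
* `beta` from binary-mixture points `(OI_sum, OI_mea)`, then
  `cos_alpha = 2*beta^2 - 1` by construction (`derive_cos_alpha()`).

Both fits are least squares **through the origin** (`slope = Σxy / Σx²`): an
odorant at its threshold (lnOAV = 0) is by definition just barely
perceivable, so the law must pass through zero, and likewise a mixture of
nothing has no intensity. A free intercept would let calibration absorb
threshold error into a nonsensical offset. Residual RMS is reported per fit;
no interval estimates are attached because the mean fit itself, not its
uncertainty, is what the prediction equations consume. Panel-mean (not
per-assessor) OI is the fitted response, matching how panel scores are
aggregated in practice.

Only *individual*-odorant samples are valid input for the `k` fit. Mixture
rows (such as the validation table's) would not raise an error — they are
numerically just points — but they would fold the interaction being
estimated by `cos_alpha` into `k`, so the two constants must come from the
two separate datasets.

The classic per-pair route stays available for users who have their own
measured binary mixtures: `cos_alpha_from_pair(oi_ab, oi_a, oi_b)` inverts
the binary Vector Model directly.

```{r calibration}
study <- generate_study(seed = 42)   # synthetic panel study, see below
calibrate(study$individual, study$binary)
```

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `k` | 1.07 | OI per ln-unit of OAV | individual psychophysical slope; family-specific |
| `cos_alpha` | −0.129 | — | shared pairwise interaction; in `[-1, 1]`; −1 total cancellation, 0 orthogonal, 1 additive |
| `subthreshold` | `"drop"` | — | policy for components with OAV < 1 |
| `rounding` | — | — | `"table"` reproduces one-decimal tabulated arithmetic; `"full"` for new data |
| `n_assessors` | 9 | — | simulated panel size |
| `rating_noise_sd` | 0.25 | OIRS units | per-assessor rating noise |
| `rating_step` | 0.5 | OIRS units | rating discretization step |

**Sub-threshold policy.** Components with OAV < 1 have negative lnOAV. The
model constants were calibrated and validated exclusively on
supra-threshold components (the validation mixtures span lnOAV 1.65–4.53),
and a negative $x_i$ entering the quadratic form flips the sign of its
cross terms so that a *weaker* component would *raise* the predicted
intensity — the opposite of the counteraction the coefficient encodes. The
default therefore excludes such components and records them in the
prediction's `warnings`; `"keep"` and `"error"` are available for users who
want the raw arithmetic or strict input checking. A component at exactly
zero concentration has no defined lnOAV at all and is always excluded.

**Negative radicand.** For many mutually counteracting components the
quadratic form can go negative — with $n$ equal components and
$\cos\alpha = -0.129$ this happens precisely when
$n - 0.129\,n(n-1) \le 0$, i.e. from $n = 9$ on. Since OI is non-negative
by construction of the rating scale, the prediction is clamped to 0, the
result is flagged `clamped = TRUE`, and a classed warning is emitted. An
error here would make large-$n$ exploration impossible; the flag keeps the
clamp visible. This is also an honest statement of the model's limits: it
was validated up to quaternary mixtures, and far beyond that regime the
shared-coefficient extrapolation, not the clamp, is the real caveat.

**Rounding.** Model outputs are always full precision. `"table"` mode in
`evaluate_table()` rounds predictions half-up to one decimal *before*
taking prediction/measurement ratios, reproducing how published comparison
tables are computed from their printed values; ties round away from zero
(`round_half_up()`), not to even. `"full"` is the scientifically preferable
mode for new data; on the shipped validation table the two modes' mean
predictive coefficients differ by well under 0.01.

## The synthetic panel: what it does and does not emulate

`generate_study()` builds a complete synthetic campaign: individual samples
whose true OI follows $k\,\ln\mathrm{OAV}$ and mixture samples whose true
OI follows the modified Vector Model with the generating constants. Every
true intensity passes through `simulate_panel_mean()`: each of
`n_assessors` perceives the true value plus Gaussian noise
(`rating_noise_sd`), reports the nearest OIRS step (`rating_step`, half-up),
negative reports clamp to 0, and the sample's measured OI is the panel
mean. Gaussian noise plus step rounding is the simplest mechanism
consistent with both panel-mean scoring and the commonly acknowledged
repeat-test fluctuation of about 0.5 OIRS units, which the default
`sd = 0.25` places at the ±2σ band. The defaults mirror the calibration
study's scale: 7 odorants × 4 individual samples, four binary designs
(B+T, B+E, T+E, E+O) × 8 samples, 9 assessors, lnOAV drawn uniformly over
1.65–4.53.

Binary calibration mixtures are generated at *equal component intensity*
(one lnOAV shared by both components), the classical protocol for
determining the interaction coefficient. This is not a convenience: under
the generating model, unequal pairs lie systematically above
$\beta(\mathrm{OI}_a + \mathrm{OI}_b)$, so an unequal design would bias
$\beta$ upward relative to the $2\beta^2 - 1$ identity that calibration
inverts. Designs with three or four components contribute validation
samples but never calibration pairs. An optional misspecification term
(`misspecification_delta`, uniform ±δ on the true mixture OI) supports
robustness studies where the data deliberately depart from the model.

Two numerical consequences of the discrete rating scale are worth knowing.
First, a noise-free panel does not reproduce truth exactly — it reproduces
truth rounded to the rating step; exact round-trip recovery (to ~1e−9)
requires shrinking the step to a negligible size, which is how the
package's noiseless recovery test is constructed. Second, calibration error
does not converge to zero as `rating_noise_sd` alone shrinks: below roughly
half the step size the discretization floor (up to a quarter step per
score) dominates, and moderate noise actually *dithers* the quantizer. The
convergence test therefore shrinks step and noise together. At the default
study scale, 200 replicates recover both constants within ±0.1 in well over
95% of runs.

What the simulator does **not** emulate: assessor-specific bias or drift,
inter-assessor variance structure, dilution-hardware artifacts, or any
departure of real mixtures from the generating model beyond the optional
uniform perturbation. Passing recovery tests therefore demonstrates that
the calibration pipeline is correct and well-conditioned at the study's
scale — not that real panels behave this ideally.

## Numerical and design notes

* **Natural logarithm throughout.** The psychophysical law and all mixture
  formulas use ln, never log10; mixing bases silently rescales `k`.
* **Units.** Thresholds and concentrations are mg/m³ only. `ppm_to_mg_m3()`
  converts ppm data (ideal gas, `mg/m³ = ppm·MW·P/(0.082057·T)`, i.e.
  MW/24.465 at 25 °C and 1 atm); the registry itself never stores ppm, so a
  unit mismatch cannot hide inside a threshold table. Thresholds are stored
  as opaque constants — the package takes no position on the panel
  methodology that produced them.
* **`beta` validity.** `derive_cos_alpha()` accepts `beta` in [0, 1];
  `beta > 1` would imply `cos_alpha > 1`, which no angle satisfies, and
  raises an error rather than clamping. Fitted `beta` marginally above 1
  (possible under noise with near-additive data) is truncated to 1 by
  `calibrate()` before derivation.
* **Dual-encoded inputs.** A sample row may carry both a concentration and
  an lnOAV; when a registry is available the two are cross-checked to
  1e−6 (looser than machine precision, because hand-entered lnOAV values
  are typically printed at two decimals) and a disagreement is an error,
  not a silent preference.
* **Known quaternary discrepancy.** On the shipped validation table the
  quaternary modified-Vector-Model predictions evaluate to 5.63, 4.17 and
  3.36 (5.6, 4.2, 3.4 at one decimal) while the published table prints
  5.5, 4.1 and 3.3; every binary and ternary cell agrees exactly. The
  printed quaternary cells appear to carry intermediate rounding that
  cannot be reconstructed from the formula, so this package evaluates the
  quaternary formula literally and documents the ~0.1 offset. The same
  offset propagates to the table-mode mean predictive coefficient: 0.97
  here versus 0.96 from the printed cells (SCM: 0.78, identical).
* **Problem sizes.** The packaged tests run the recovery study at its
  native scale (28 individual + 32 binary points per replicate; 200
  replicates for the coverage check, 30 per noise level for the
  convergence check), which keeps the whole suite under a minute on one
  CPU while leaving the Monte-Carlo assertions comfortably powered.

## Limitations

The constants ship from a single aromatic-compound study: they transfer
only within chemical families of similar functional groups and molecular
structure, and new families need both `k` and `cos_alpha` recalibrated.
The shared-coefficient simplification was validated on mixtures of two to
four components; beyond that it is an extrapolation. The model takes no
account of qualitative odor character, hedonics, or sub-threshold synergy,
and the U and Additivity models sometimes cited alongside these baselines
are out of scope.
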