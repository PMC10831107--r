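---
title: "Methods: Metabolic-Index habitat predictability in aerohab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Metabolic-Index habitat predictability in aerohab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerohab)
```

## The model

Aerobic habitat suitability is quantified by the Metabolic Index, the ratio
of environmental O₂ supply to a species' temperature-dependent resting
metabolic demand:

$$\Phi = A_o\,\frac{p_{O_2}}{\exp\left\{-\frac{E_o}{k_B}\left[\frac{1}{T}-\frac{1}{T_{ref}}\right]\right\}}$$

`aerohab` works throughout with the normalized index $\phi = \Phi/\Phi_{crit}$
(the hypoxic-tolerance trait `A_c` is $A_o$ normalized by $\Phi_{crit}$), so
that $\phi > 1$ marks viable habitat uniformly. Temperatures enter the
Arrhenius factor in kelvin; the temperature sensitivity is corrected
linearly, $E_o \to E_o + \frac{dE_o}{dT}(T - T_{ref})$, *inside* the
exponent. Partial pressure is fractional saturation scaled by the
atmospheric O₂ mole fraction,
$p_{O_2} = 0.209\,\mathrm{atm}\cdot O_2 / O_2^{sol}(T,S)$, with the
saturation concentration $O_2^{sol}$ from the Garcia & Gordon (1992)
combined fit to the Benson–Krause data. The fit is evaluated in µmol kg⁻¹
and converted to mmol m⁻³ with a fixed reference density of 1025 kg m⁻³;
the density is a deliberate constant (not a full equation of state) so the
concentration–pressure map stays exactly invertible and testable. Neither
the $p_{O_2}$ convention nor the density affects anomaly *correlations*,
only absolute $\phi$ levels; both are kept explicit for sensitivity work.

Two conventions are pinned by regression tests because they change numbers:

* $\phi$ is computed **cellwise at native (monthly) resolution first**;
  annual means, depth-layer means (thickness-weighted) and region means
  (area-weighted, in that fixed order) are taken on $\phi$, never on the
  drivers. The nonlinearity makes the orders genuinely different.
* Habitability is the **strict** inequality $\phi > 1$; the boundary has
  measure zero but a convention must be fixed. Where O₂ is exactly zero,
  $\phi = 0$: anoxic water is uninhabitable, not missing.

### Key parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `A_c` | atm⁻¹ | 10 | hypoxic tolerance; linear scale on $\phi$ |
| `E_o` | eV | sweep −0.2…1.0 | temperature sensitivity of hypoxia vulnerability |
| `dEo_dT` | eV K⁻¹ | 0.022 | linear correction of `E_o` |
| `T_ref` | K | 288.15 | reference temperature |
| threshold | – | 1 | habitability cut on $\phi$ |
| `n_sigma` | – | 3 | interannual envelope half-width |

`A_c` cancels exactly in anomaly correlations (a positive scale factor on
both series); the package exploits this in tests — ecotypes differing only
in `A_c` verify bit-identically.

## Habitat geometry

From yearly $\phi$ the package derives the time-mean field, the pointwise
interannual standard deviation $\sigma_\phi$ (unbiased, $n-1$; pointwise
rather than regionally pooled, the only choice consistent with per-cell
maps), and three nested masks: habitable at the mean, at the lower envelope
$\bar\phi - 3\sigma_\phi$ and at the upper envelope
$\bar\phi + 3\sigma_\phi$. Their difference — the shift zone — flags where
interannual variability can contract or expand habitat. Vertical habitable
ranges are reported at grid-cell edges as half-open `[top, bottom)`
intervals in meters; interpolating the $\phi = 1$ crossing is a plotting
nicety deliberately left out, so intervals are grid-native and reproducible.

## Forecast verification

Skill of the ensemble-mean initialized forecasts is measured against the
reconstruction on yearly anomalies, as a function of lead year $\tau$:

$$\mathrm{ACC}(\tau) = \frac{\sum_i F'_i(\tau)R'_{i+\tau}}{\sqrt{\sum_i F'_i(\tau)^2 \sum_i R'^2_{i+\tau}}},
\qquad
\mathrm{NMAE}(\tau) = \frac{1}{N}\sum_i \frac{|F'_i(\tau)-R'_{i+\tau}|}{\sigma_{R'}(\tau)}$$

The ACC is implemented exactly as the **uncentered** anomaly product — not a
re-centered Pearson correlation — because the anomaly definitions (below)
make the series mean-zero only in-sample; a regression test pins the
difference on a non-mean-zero pair. Forecast anomalies come from drift
adjustment: at every cell and lead, the mean over all members and all
initialization dates is removed, which kills any lead-dependent model drift
exactly. Reconstruction anomalies are deviations from the full-period
climatology of yearly means (no baseline window is singled out; the full
period maximizes the verification sample). (Init, lead) pairs whose
verification year leaves the record are dropped and counted.

The persistence baseline predicts $R'_{i+\tau}$ by $R'_i$ and runs through
the same machinery. Significance of a nonzero ACC uses a two-sided
Student's t-test with effective degrees of freedom
$N_{\mathrm{eff}} = N\,\frac{1-r_1 r_2}{1+r_1 r_2}$ (lag-1 red-noise form;
floored at 3, capped at $N$). The ACC improvement over persistence is
tested one-sided with the Meng–Rosenthal–Rubin z-test for two correlations
sharing a common variable, with $N$ replaced by the smaller of the two
pairwise $N_{\mathrm{eff}}$ values (conservative) and the inter-predictor
correlation estimated from the aligned predictor series. The
predictability timescale is the length of the *initial* run of significant
leads: significance at leads 1–5 and 8–9 gives 5, not 9.

Both a region-series mode (verify the layer/region-averaged series; the
default and what the pipeline tabulates) and a per-cell mode
(`skill_maps()`) are provided.

## Taylor attribution and the variance budget

With traits fixed, $\phi$ is a function of the drivers $(O_2, T, S)$. Its
first-order decomposition about the full-record time means,
$\phi_i(t) = \partial\phi/\partial x_i|_{\bar x}\,(x_i(t)-\bar x_i)$, uses
**analytic** partial derivatives (including the solubility's $T$ and $S$
dependence inside $p_{O_2}$ and the $E_o(T)$ correction inside the
exponent); centered finite differences serve only as a test oracle, at
relative error below $10^{-6}$. Exactness of the identities below requires
a single consistent $\partial\phi/\partial O_2$, which is why the analytic
route is primary. $\bar\phi$ is $\phi$ evaluated at the time-mean drivers
by default — the alternative (time mean of $\phi(t)$, differing by the
nonlinearity) sits behind the `phi_bar` switch for sensitivity. The
residual is stored, never dropped, and shrinks quadratically with anomaly
amplitude (slope 2 on a log-log fit, a tested property).

Because $\phi$ is linear in O₂ at fixed $(T,S)$ and $O_2 = O_2^{sol} - AOU$,
the oxygen component splits exactly:
$\phi_{O_2} = \phi_{O_2^{sol}} + \phi_{AOU}$ with
$\partial\phi/\partial O_2 = \partial\phi/\partial O_2^{sol} =
-\partial\phi/\partial AOU$. The variance budget
$\sigma^2_\phi \approx \sum_i \sigma^2_{\phi_i} + 2\sum_{j\neq i}\mathrm{Cov}(\phi_j,\phi_i)$
is approximate (its gap is reported as a residual term), but the oxygen
sub-budget and the $O_2$–$T$ covariance split are algebraic identities and
are tested to $10^{-12}$ relative error. All moments use the unbiased
$(n-1)$ estimator, matching $\sigma_\phi$ in the habitat envelopes.

For component-wise *skill*, the driver components are built from the
drift-adjusted forecast drivers with partials and means taken from the
forecast-side lead-dependent climatology, and verified against the
unchanged reconstruction $\phi$ anomalies — the component is the forecast,
$\phi$ itself is always the predictand.

## The synthetic world

The generator supplies ground truth, emulating the statistical skeleton of
a forced ocean reconstruction and an initialized prediction ensemble:

* **Reconstruction**: monthly fields = mean vertical climatology profile
  + a yearly AR(1) anomaly shared within the year + monthly white noise,
  at every ocean cell. Cross-variable coupling is applied to the AR(1)
  innovations, rescaled by $(1-a_ja_k)/\sqrt{(1-a_j^2)(1-a_k^2)}$ so the
  *stationary* anomaly correlation matches the prescribed target exactly in
  population. The process starts from its stationary distribution. O₂ is
  clipped at zero and clips are counted.
* **Forecasts** (yearly resolution, where all verification happens): for
  init $i$, member $m$, lead $\tau$, the anomaly is
  $\alpha(\tau)\,\mathrm{truth}(i+\tau) + \sqrt{1-\alpha(\tau)^2}\,\sigma\,\varepsilon_m
  + \mathrm{drift}(\tau) + \mathrm{bias}$. Averaging $M$ members shrinks
  the noise variance by $1/M$, so the population ensemble-mean correlation
  with truth is $\alpha/\sqrt{\alpha^2 + (1-\alpha^2)/M}$
  (`ensemble_mean_acc()`), the closed form the recovery tests check
  against Fisher-z sampling bands.

Default study conditions (fixed, not tuning knobs): 6 × 6 horizontal
cells with two labeled coastal regions and a land cell, 10 depth levels
over 0–600 m split into 0–200 m and 200–600 m habitats, 64 initialization
years from 1954, 10 lead years, 10 members; AR(1) coefficients
(0.5, 0.6, 0.7) and anomaly standard deviations (0.5 °C, 0.1 psu,
10 mmol m⁻³) for (T, S, O₂); warm–low-O₂ coupling −0.6; member skill
$\alpha(\tau) = 0.9^\tau$; linear-in-lead drift. Climatology profiles are
a warm surface layer decaying to a cold interior, near-saturated surface
oxygen declining to an oxygen-poor interior, and a weak halocline —
"realistic mean vertical structure" at the level the analysis needs.
Attribution-recovery experiments use uncorrelated drivers and a
variable-specific $\alpha$ schedule (only O₂, or only T, predictable):
the controlled single-driver worlds in which recovering the known
attribution is well-posed.

What the generator does **not** emulate: spatial correlation of anomalies
between cells, seasonality, trends and externally forced signals,
non-Gaussian tails, and real bathymetry/coastlines. Passing tests
therefore demonstrate correctness of the estimators and attribution logic
under known red-noise conditions — not skill of any real forecast system.

## Numerical and design choices

* Solubility fit range: warnings outside −3…40 °C and 0…42 psu; `NA`
  propagates, land never becomes silent zeros.
* Annual means require all 12 months by default (`min_months` relaxes);
  partial trailing years are dropped with a warning.
* Zero-variance series make ACC/NMAE `NA` with a warning rather than 0/0.
* $|r| = 1$ is assigned $p = 0$; $N_{\mathrm{eff}}$ is floored at 3 so the
  t-test stays defined for pathologically persistent series.
* An "ensemble" of one member is refused by the generator (the ensemble
  mean would be meaningless); the perfect-forecast limit is exercised with
  $\alpha = 1$ and two members, where each member equals truth.
* Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state; pipeline artifacts and the manifest are bit-identical
  across reruns of one configuration.

## Problem sizes used in the test-suite experiments

Moment-recovery and calibration checks use 500-year single-column worlds;
the t-test size experiment uses 1000 replicates of length-60 white-noise
pairs (nominal 5% ± 2%); attribution recovery uses 30 replicated
single-driver worlds (40 inits × 8 members × 5 leads) plus one
well-sampled world (64 × 20 × 5); the end-to-end determinism check runs
the full default configuration twice. These sizes were chosen so every
stochastic tolerance has comfortable Monte-Carlo margin while the whole
suite stays desk-scale.

## Known limitations

* The region-series and per-cell skill modes answer slightly different
  questions; the pipeline reports the former and records the choice in its
  outputs.
* The variance budget's cross terms can be large and negative where
  drivers are strongly anticorrelated; the budget is then still exact in
  its identities but the single-component "shares" lose their intuitive
  reading.
* No hydrostatic-pressure correction of $p_{O_2}$ is applied, and no
  second-order Taylor terms are computed; both are out of scope by design.
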