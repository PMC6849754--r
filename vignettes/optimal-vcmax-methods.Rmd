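---
title: "Predicting optimal photosynthetic capacity from climate: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting optimal photosynthetic capacity from climate: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcmaxopt)
```

## The problem

Earth-system and ecosystem models need the maximum rate of Rubisco
carboxylation, $V_{cmax}$ (µmol CO$_2$ m$^{-2}$ s$^{-1}$), to simulate C$_3$
photosynthesis. Most prescribe it from leaf nitrogen and soil fertility.
`vcmaxopt` implements the alternative, optimality-based view: plants
acclimate and adapt so that photosynthetic capacity is co-optimized to the
growth environment, which makes $V_{cmax}$ predictable from four climate
variables plus CO$_2$ — growing-season mean irradiance $I_g$, air temperature
$T_g$, vapour pressure deficit $D_g$, and elevation $z$ (a proxy for
atmospheric pressure) — with no nutrient input at all.

Two optimality principles are combined.

**Least-cost theory** sets the optimal CO$_2$ drawdown. Plants are assumed to
minimize the summed unit costs of transpiration and carboxylation,
$1.6\eta^* D_g/(C_a - C_i) + \beta (C_i + K)/(C_i - \Gamma^*)$, giving an
optimal ratio $\chi = C_i'/C_a$:

$$\chi = \frac{\Gamma^*}{C_a} + \left(1 - \frac{\Gamma^*}{C_a}\right)
  \frac{\xi}{\xi + \sqrt{D_g}}, \qquad
  \xi = \sqrt{\frac{\beta\,(K + \Gamma^*)}{1.6\,\eta^*}}$$

where $\Gamma^*$ is the photorespiratory compensation point, $K$ the
effective Michaelis–Menten coefficient of Rubisco
($K = K_c(1 + O_i/K_o)$), $\eta^*$ the viscosity of water relative to
25 °C, and $\beta = 146$ the cost ratio of carboxylation to water
transport capacity. The test suite verifies the analytic $\chi$ against a
dense grid-search minimization of the cost function itself.

**Coordination theory** sets the capacity. Under average growth conditions
the Rubisco-limited and electron-transport-limited rates are equal,
$A_c = A_j$. Electron transport follows a non-rectangular hyperbola in
irradiance with curvature $\theta$ and quantum yield $\varphi$; optimal
$J_{max}$ is where its marginal benefit equals a cost $c$:
$\partial A_j/\partial J_{max} = c$, solved in closed form as
$J_{max} = \varphi I \omega$ with

$$\omega = -(1 - 2\theta) + k\sqrt{\frac{1-\theta}{d(1-\theta d)}},
  \qquad d = \frac{4c}{m},\quad k = 1 - 2\theta d.$$

Squaring the marginal condition creates two roots; the sign of $k$ selects
the branch that satisfies the original (unsquared) condition, and the test
suite pins the closed form against finite-difference/bisection solutions of
the marginal condition directly (`omega_mode = "numeric"` falls back to that
root-finding at run time). Feasibility requires $m > 4c$: the initial slope
of $A_j$ in $J_{max}$ is $m/4$, so below that threshold capacity can never
pay its marginal cost and the site fails loudly with a domain error rather
than returning NaN.

With $\omega^* = 1 + \omega - \sqrt{(1+\omega)^2 - 4\theta\omega}$,
coordination gives the capacity operating at its optimum temperature:

$$V_{cmax}^{*} = \varphi I \frac{m}{m_c} \frac{\omega^*}{8\theta},
 \qquad m = \frac{C_i' - \Gamma^*}{C_i' + 2\Gamma^*},\quad
 m_c = \frac{C_i' - \Gamma^*}{C_i' + K}.$$

**Temperature acclimation.** $V_{cmax}^*$ is interpreted as the rate at the
optimum temperature $T_o = 177.884 + 0.44\,T_g$ (Kelvin); a peaked (modified)
Arrhenius function with activation energy $H_a = 71513$ J mol$^{-1}$,
deactivation energy $H_d = 200000$ J mol$^{-1}$ and an entropy term
acclimating linearly to growth temperature
($\Delta S = 668.39 - 1.07\,T_g$[°C] J mol$^{-1}$ K$^{-1}$) scales it from
$T_o$ to $T_g$, yielding the reported $V'_{cmax}$. The same function — one
source of truth, cross-called by the tests — standardizes field
measurements from leaf temperature to $T_g$ on the observation side, always
with $\Delta S$ computed from $T_g$, not from the measurement temperature:
the entropy state is a property of the acclimated leaf, and using the
measurement temperature is the most common silent error in implementations
of this standardization.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `phi`     | 0.257 | mol mol$^{-1}$ | realized quantum yield of electron transport |
| `theta`   | 0.85  | — | curvature of the light response |
| `c_cost`  | 0.053 | — | marginal cost of $J_{max}$ capacity |
| `beta`    | 146   | — | carboxylation:transpiration cost ratio |
| `Ha`, `Hd` | 71513, 200000 | J mol$^{-1}$ | activation/deactivation energies ($V_{cmax}$) |
| `Ha_jmax` | 49884 | J mol$^{-1}$ | activation energy ($J_{max}$ variant) |

`phi` and `theta` are the model's only free parameters; `beta` and `c_cost`
were calibrated once at standard conditions ($T_g$ 25 °C, $D_g$ 1 kPa,
$z$ 0) in the source literature and are treated as universal constants.
All are overridable via `model_params()` or a `key = value` file on the
command line.

## Design choices where the design was open

* **Pressure from elevation.** The source theory indexes pressure by
  elevation without printing a conversion; we adopt the standard-atmosphere
  barometric formula (101325 Pa at sea level, 6.5 K km$^{-1}$ lapse), the
  convention of the least-cost literature. O$_2$ and CO$_2$ partial
  pressures both scale with pressure, which produces the model's elevation
  response (higher $V'_{cmax}$ aloft via reduced oxygenation and drawdown).
* **Viscosity.** Full Huber et al. (2009) correlation (with Tumlirz-equation
  water density) as default, validated against published reference points;
  a temperature-only approximation is available behind
  `viscosity_mode = "simple"` and agrees to ~3% at surface conditions.
* **Rubisco kinetics.** Bernacchi-type in-vivo Arrhenius constants pinned in
  `model_params()` as 25 °C mole fractions with activation energies;
  converted to Pa at site pressure. Kinetics are evaluated at $T_g$ — leaf
  temperature is assumed equal to growing-season air temperature.
* **$J_{max}$ temperature scaling.** The source theory does not state how
  the predicted $J'_{max}:V'_{cmax}$ ratio was temperature-scaled. Default:
  both capacities scaled to $T_g$ with their own constants
  (`Ha_jmax` 49884, $\Delta S_J = 659.70 - 0.75\,T_g$), sharing $T_o$;
  `jv_ratio_mode = "at_to"` reports the unscaled ratio instead. The ratio
  declines with growth temperature in either mode.
* **Temperature unit conventions.** $T_o$'s regression takes Kelvin and the
  entropy regressions take Celsius — both as published by their source.
  These are pinned in code with explicit Kelvin guards (any temperature
  below 150 passed to a Kelvin argument raises a unit error).
* **Grid cells.** Observations aggregate to half-degree half-open cells with
  edges at multiples of 0.5° (centers at 0.25° offsets — the CRU layout);
  `anchor = "offset"` shifts edges by a quarter degree for sensitivity
  checks. The per-cell standard error is undefined ($NA$) for single-record
  cells.
* **Model II regression.** The standardized-major-axis estimator
  (slope $= \mathrm{sign}(r)\,s_y/s_x$) with seeded pairs-bootstrap
  percentile confidence intervals rather than analytic SMA intervals:
  assumption-light, and convergent with the analytic intervals at large
  $n$.
* **AIC.** Full Gaussian likelihood including constants, error variance
  counted as a parameter — numerically identical to `stats::AIC` on `lm`
  objects (pinned by a test). Only $\Delta$AIC between models on identical
  case sets is interpreted; comparisons on unequal case sets are refused.
* **No multiple-testing correction** on the bias regressions, and trends are
  reported at $p < 0.05$, matching standard practice for this analysis.

## The synthetic-data generator: what it emulates, what it does not

`simulate_sites()` states a world resembling the global compilation this
pipeline was designed to evaluate against: ~200 sites with ~18 observations
each (≈3700 values), climates drawn uniformly over vegetated ranges
($T_g$ 0–35 °C, $D_g$ 100–3000 Pa, $I_g$ 200–1500 µmol m$^{-2}$ s$^{-1}$,
$z$ 0–4000 m), and pseudo-observations built as
*truth × lognormal noise*, measured at a leaf temperature jittered ±8 °C
around $T_g$ and then **un**-standardized with the inverse of the
peaked-Arrhenius scaling — so the pipeline's standardization step recovers
the noisy truth exactly, and with zero noise the whole pipeline closes on
the model (RMA slope 1, intercept 0, $r^2$ 1). Observation noise is
multiplicative (CV 0.25, median 1) because capacity is positive and field
scatter grows with magnitude. Leaf nitrogen follows demand
($N_a = 0.8 + 0.02\,V'_{cmax} + \varepsilon$, giving realistic
1–3 gN m$^{-2}$); the six soil variables are noise, optionally correlated
with $T_g$ through `soil_rho`; 44% of records are labelled one-point-method.
An optional `bias_ig` injects a known irradiance-dependent bias for
parameter-recovery tests. One subtlety the recovery tests account for:
because the noise is *median*-one (lognormal, meanlog 0), the percent-bias
statistic — which divides by the cell-mean observation — has expectation
$\kappa = E[1/\bar{x}_m] = e^{-\sigma^2/2}(1 + (e^{\sigma^2}-1)/m) +
O(m^{-2})$ times the injected factor, so the regression estimand is
$\kappa \cdot$`bias_ig` ($\approx 0.974\,$`bias_ig` at $m = 18$
observations per site), and that implied coefficient is the recovery
target.

What it does **not** emulate: real geographic covariance (sites are
scattered uniformly, so nearly every site is its own grid cell), canopy
light gradients, species identity, shared-measurement-campaign error
structure, or any genuine soil effect on capacity. A green pipeline test
therefore establishes the statistical machinery is correct and unbiased
under the stated world — it does not re-establish the published model–data
agreement, which requires the original compilation.

## Numerical notes

* $\chi$ is clamped to $(\Gamma^*/C_a + 10^{-9}, 1]$ with a warning — it
  cannot leave that interval for valid inputs; the guard protects $m$, $m_c$
  from rounding at extreme $D_g$.
* $C_a \le \Gamma^*$, $m \le 4c$, non-positive observations, leaf
  temperatures outside 0–50 °C, and rank-deficient regression designs all
  raise typed errors (`vcx_domain_error`, `vcx_parse_error`,
  `vcx_config_error`) that the CLI maps to distinct exit codes; nothing is
  silently NaN'd.
* Written CSVs round to 6 significant digits (diffable, reparse-stable);
  closure tests through files use correspondingly relaxed tolerances while
  in-memory closure is asserted at 10$^{-8}$.
* All stochastic components (bootstrap, simulation) run under local seeds
  that do not disturb the caller's RNG stream.

## Known limitations

Soil moisture enters only through vapour pressure deficit — there is no
explicit soil-water cost term. Predictions are growing-season means; no
sub-daily or interannual acclimation dynamics. The one-point-method flag is
metadata for subset analyses only; this package does not estimate
$V_{cmax}$ from gas-exchange curves.
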