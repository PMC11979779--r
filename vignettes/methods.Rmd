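---
title: "Model description and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model description and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyoptim)
```

# The model

`canopyoptim` computes daily stand-level GPP and canopy transpiration for a
boreal conifer stand from an eco-evolutionary optimality principle: the two
plastic plant variables — stomatal conductance of a top-canopy needle and
leaf nitrogen mass concentration — take the values that maximize a
net-carbon-gain fitness proxy, subject to a hydraulic-risk discount and
nitrogen maintenance costs. This vignette records the model equations in
the package's notation, the numerical choices, the design decisions that
were genuinely open, and what the synthetic test-bed does and does not
establish.

## Leaf photosynthesis

Assimilation is co-limited (coordination hypothesis): the carboxylation- and
electron-transport-limited rates are assumed equal, so a single expression

$$A = \frac{J}{4}\,\frac{c_i - \Gamma^*}{c_i + 2\Gamma^*}$$

is balanced against Fick's-law supply $A = g\,(c_a - c_i)/P$ with the lumped
stomatal-plus-mesophyll conductance $g = 0.42\,g_s$. Mesophyll conductance
is never represented separately; only the ratio enters. Equating demand and
supply yields a quadratic in $c_i$ whose **greater** root is physical;
substituting back gives $A(g_s, I, J_{\max})$. The electron transport rate
$J$ is the **smaller** root of the non-rectangular hyperbola
$\theta_J J^2 - (\alpha I + J_{\max})J + \alpha I J_{\max} = 0$, which keeps
$J \le \min(\alpha I, J_{\max})$.

Temperature enters twice: the compensation point $\Gamma^*$ follows an
Arrhenius response around $T_{\mathrm{ref}} = 298$ K (kept at 298 exactly,
not 298.15, matching the source of the constants), and $J_{\max}$ follows a
peaked response normalized to 1 at $T_{\mathrm{opt}} = 305$ K. All public
interfaces take °C; Kelvin conversion happens inside these two functions.

Seasonality enters through a delayed temperature
$S_t = (1 - 1/\tau)S_{t-1} + T_t/\tau$ (initialized at the first observed
mean temperature) and an activation factor $X_t$ that ramps linearly from 0
at $S_{\min}$ to 1 at $S_{\min} + \Delta S$, with closed intervals at both
ends. Both the quantum yield and $J_{\max}$ are scaled by $X_t$. $S_{\min}$
is not part of the published constant set; the package exposes it with
default 0 °C, which places the activation ramp symmetrically around typical
boreal spring temperatures and can be changed in `photo_params()`.

Capacity is tied to nitrogen linearly:
$J_{\max} = X_t\, a_{J\max} N_{mf}\, f_{J\max}(T)$. Note that $a_{J\max}$
and $N_{mf}$ enter the model *only through their product*, so in
calibration only the leaf-N observations separate the two — an inherent
identifiability property, not an implementation artifact.

## Hydraulics

Soil water potential follows Brooks–Corey,
$\psi_s = \psi_a S_e^{-1/\lambda}$ with
$S_e = (\theta - \theta_r)/(\theta_s - \theta_r)$; the retention curve is
undefined at or below $\theta_r$ and the package refuses such input rather
than extrapolating. The xylem vulnerability curve is
$P(\psi) = (1/2)^{(\psi/\psi_{50})^{b}}$ — the fraction of maximal
soil-canopy conductance remaining — and the effective conductance over a
transpiring path is the integral mean of $P$ between the canopy potential
$\psi_c$ and the pre-dawn potential
$\psi_{c,pd} = \psi_s - H\rho g \cdot 10^{-6}$ (with $\rho = 997$ and
$g = 9.82$ exactly as in the source constant set). Combined with Darcy's
law $\psi_c = \psi_{c,pd} - E/k_{sc}$ this is a one-dimensional fixed-point
problem.

**Solver.** We iterate
$k^{(n+1)} = k_{\max}\cdot\text{mean}_{\text{Simpson}}(P;\ \psi_c^{(n)},
\psi_{c,pd})$ with $\psi_c^{(n)} = \psi_{c,pd} - E/k^{(n)}$, initial guess
$k^{(0)} = k_{\max}P(\psi_{c,pd})$ (exact in the zero-flux limit), a 0.5
damping factor if the update oscillates, relative tolerance $10^{-9}$ and a
200-iteration cap. The Simpson rule uses a fixed even subdivision (50
panels by default, configurable); at these settings the solution agrees
with an adaptive-quadrature + bisection oracle to well under $10^{-5}$ MPa
across the tested driver space (observed worst case $\sim 6\times10^{-8}$).
The iteration map has slope $1 - P(\psi_c)/\bar P \in [0, 1)$ near the
solution, so convergence is guaranteed but slows as the state approaches
the runaway threshold; the supply integral is monotone in $\psi_c$, so the
solution is unique whenever it exists. If transpiration exceeds the
maximal supply the solver reports runaway embolism (`converged = FALSE`)
rather than fabricating a state; the optimizer never requests such states
because of the critical-conductance cap below.

**Critical conductance.** The stomatal bound $g_{s,\mathrm{crit}}$ at which
$P(\psi_c) = f_{\mathrm{crit}} = 0.12$ is computed in closed form: the
critical potential is
$\psi_{\mathrm{crit}} = \psi_{50}(\log f_{\mathrm{crit}}/\log 0.5)^{1/b}$,
the corresponding flux is the supply integral from $\psi_{\mathrm{crit}}$
to $\psi_{c,pd}$ evaluated with the *same* Simpson discretization as the
fixed-point solver, and the conductance follows from inverting the
transpiration equation. Using the same discretization in both places makes
the cap and the solver mutually consistent to the fixed-point tolerance.
As VPD tends to zero the bound diverges and is capped at a configurable
search limit (1 mol m⁻² s⁻¹ by default).

## The fitness proxy and the diurnal scheme

$$G = A\,k_{\mathrm{cost}} - (N_r + N_u)\,J_{\max},\qquad
k_{\mathrm{cost}} = \frac{k_{sc} - 0.12\,k_{\max}}{0.88\,k_{\max}}$$

The hydraulic discount reaches zero at 88% loss of conductivity (the
commonly observed lethal threshold). The cost term uses the same
instantaneous, $X_t$- and temperature-scaled $J_{\max}$ that enters $A$; no
alternative is stated in the model formulation, and this keeps benefit and
cost on the same seasonal footing.

Daily integrals use a two-segment scheme: daylight is split at solar noon
into morning and afternoon halves, each represented by its midpoint.
Radiation follows a half-sine whose integral over daylight equals the daily
total; temperature follows a sinusoid with amplitude
$(T_{\max}-T_{\min})/2$ peaking at 0.75 of the daylight period (standard
diurnal asymmetry — it makes the two conductance values meaningfully
distinct), clipped to $[T_{\min}, T_{\max}]$; VPD is reconstructed from the
saturation curve at the instantaneous temperature with the daily actual
vapor pressure held constant (recovered from daily mean VPD and mean
temperature, floored at zero); CO₂ and soil moisture are constant within a
day. The exact representative points of segmented daily schemes vary
between implementations; this symmetric-split variant is isolated behind
`diurnal_drivers()` so it can be swapped without touching anything else.

Night-time maintenance cost of $J_{\max}$ is excluded by default (the proxy
is defined with assimilation present); `optim_opts(night_cost = TRUE)`
includes it for sensitivity analyses.

## Two-step trait optimization

Step 1 maximizes the block integral of $G$ over
$(N_{mf}, g_{s,am}, g_{s,pm})$ on the week-average day (arithmetic mean of
each driver over the block), with each day's own $X_t$. Step 2 fixes
$N_{mf}$ and re-maximizes each day's conductance pair starting from the
step-1 values. Blocks are 7 days; a trailing partial week is optimized as
its own block, because growing seasons are not multiples of seven.

Bounds are $N_{mf} \in [0.007, 0.05]$ and
$g_s \in [0.001, g_{s,\mathrm{crit}}]$ per segment, so every accepted state
satisfies $P(\psi_c) \ge 0.12$. Days where even closed stomata violate the
threshold are clamped to the lower bound and flagged; a simulation never
aborts on such days.

**Optimizer choice.** The objective is smooth inside the box but its upper
conductance bound is the active cavitation cap, so a derivative-free method
is more robust than quasi-Newton here. The package seeds a deterministic
coarse grid over the box (computed with a factorized evaluator that shares
canopy-state and assimilation sub-computations across the grid — identical
values, much cheaper), polishes the top cells with a projected Nelder–Mead
simplex, and keeps the best. Everything is deterministic and seedless. The
defining conformance property is behavioral: on synthetic weeks the
returned fitness must be within 0.5% of a dense 40³ grid-search oracle, and
at interior optima the central-difference gradient must vanish relative to
the fitness scale; both are asserted in the test suite.

## Upscaling

Capacity and conductance are assumed to acclimate proportionally to the
exponential irradiance profile, so canopy totals are top-leaf rates times
$\Lambda = (1 - e^{-k\,\mathrm{LAI}})/k$. Top-leaf incident irradiance is
taken as $I_{\mathrm{inc}} = k\,I(t)/(1-m)$ per projected leaf area
(interception per leaf area at the canopy top, corrected for leaf
transmittance $m$); the proportionality constant of this choice is absorbed
by $a_{J\max}$ in calibration, which is why it is isolated in a single
function. Ecosystem GPP adds understory production through
$\zeta = \mathrm{GPP}_e/\mathrm{GPP}_c$ (1.2 fertilized, 1.13 control —
understory shares of 17% and 12%). Carbon converts at 12.011 g mol⁻¹,
water at 18.015 g mol⁻¹ (1 kg m⁻² = 1 mm). WUE is reported as
$\mathrm{GPP}_c/E_c$.

## Calibration and validation

Errors are Laplace with prediction-linear scale,
$y - M \sim \mathrm{Laplace}(0, a + bM)$, with data-type weights
($w_{\mathrm{GPP}} = 1.5$, $w_{E_c} = w_{N_{mf}} = 1$). The log-likelihood
(not the raw product) is the objective — numerically mandatory, identical
argmax. Leaf-N observations enter as per-treatment seasonal means compared
with the mean modeled leaf N, matching how such data are reported (single
values per treatment). In the default scheme all parameters are shared
between treatments except $N_u$ and $k_{sc,\max}$.

The global search is a compact seeded differential evolution
(rand/1/bin, dithered weight, bound reflection) followed by a box-projected
Nelder–Mead polish of the best point; any seeded population-based method
passing the recovery property below would be conformant. Free-parameter
bounds are package choices (documented in `param_scheme()`), since the
source prints none: $\tau \in [2, 40]$ d, $\Delta S \in [1, 30]$ °C,
$a_{J\max} \in [0.005, 0.1]$, $\alpha_{season} \in [0.05, 0.5]$,
$k_{sc,\max} \in [10^{-4}, 5\times10^{-3}]$, $N_u \in [0, 0.05]$,
$a_{\mathrm{GPP}} \in [0.01, 5]$, $b_{\mathrm{GPP}} \in [0, 1]$.

Holdout validation draws `round(fraction * n)` points uniformly without
replacement per repeat (a `size` switch mirrors protocols that fix the
absolute count — e.g. 119 of 588, which differs by one from the rounded
fraction). Metrics are RMSE, MAPE in percent (zero-valued observations
excluded, with a count) and $R^2$.

Ablations: `static_nmf` freezes leaf N at its baseline season median;
`shared_nmf` applies one leaf-N value to both treatments; `shared_nu` one
uptake cost; `static_theta` replaces soil moisture by its per-treatment
season mean. Reports contain the mean predicted leaf N and the $R^2$
change per treatment.

## Synthetic weather

The generator emulates the observed boreal driver ranges with seasonal
structure and cross-correlations: temperature is a seasonal sinusoid
(mean 2 °C, amplitude 14 °C, peak mid-July) plus AR(1) anomalies
($\phi = 0.75$, innovation SD 2.2 °C); cloudiness is an autocorrelated
clearness fraction that drives PAR (clear-sky envelope ∝ day length),
widens the diurnal temperature range and lowers relative humidity, so
sunny days carry higher VPD; soil moisture is a slow AR(1)
($\phi = 0.95$) around a regime mean with an optional scheduled drought
spell; CO₂ ramps slowly within the observed band; day length comes from
solar geometry (CBM form with the sun-center coefficient, which reproduces
the observed upper bound at the site latitude). All series are clamped to
the observed ranges (−5.1…30.8 °C, 1.8…63.5 mol m⁻² d⁻¹, 45.5…1420 Pa,
6.7…29.8% soil water, 38.5…40.9 Pa CO₂). Saturation vapor pressure uses
the Tetens/Magnus dialect $610.78\,e^{17.27T/(T+237.3)}$ Pa — the dialect
is pinned here because downstream VPD reconstruction must be
self-consistent.

What the generator does **not** emulate: observed spell statistics of
frontal weather, precipitation-driven soil-moisture recharge dynamics,
radiation–temperature lags, or multi-year trends. Tests passing on this
test-bed therefore establish internal consistency and qualitative response
directions of the model, not site-level predictive skill — that requires
the real flux, sap-flow and weather series, which are not packaged.

## Problem sizes and the recovery experiment

The package's own reproduction machinery (in the test suite) uses sizes
chosen to exercise every mechanism while keeping full runs comfortable on
a laptop core:

* solver-versus-oracle equivalence on 500 random parameter/driver draws;
* optimizer-versus-grid on five synthetic weeks with a 40³ grid;
* parameter recovery on 2 treatments × 2 synthetic seasons of 49 days
  starting in cold spring (so the acclimation ramp is in the data and
  $\tau$, $\Delta S$ are identifiable), with a reduced
  differential-evolution budget (population 14, 30 generations, 250-step
  polish; $a_{J\max}$ and $k_{sc,\max}$ searched on log scale, as is usual
  for strictly positive scale parameters). The experiment has two parts.
  *Point recovery* uses small Laplace noise (one fifth of the published
  error scales) and requires $\tau$, $\Delta S$, $a_{J\max}$ and
  per-treatment $k_{sc,\max}$ within 15% of truth from a single refit.
  *Treatment contrast* uses the full published error scales and requires
  the $N_u$ ordering (fertilized below control) to survive in at least 9
  of 10 seeded noise-plus-refit repetitions. The two noise levels are
  deliberate: with only one seasonal-mean leaf-N observation per treatment,
  the $a_{J\max}$ likelihood ridge at full noise is flat enough that
  maximum-likelihood estimates legitimately scatter beyond 15% (we verified
  that such fits can sit within a few log-likelihood units of the truth),
  so a point check there would test the noise draw, not the machinery; the
  ordering, by contrast, is robust at full noise.

Calibration model runs use a slightly coarsened solver configuration
(8 Simpson panels, fixed-point tolerance $10^{-6}$, single polish start);
on the tested driver space this changes optimized traits by $\sim10^{-6}$
relative — far below the Laplace noise floor — while cutting run time
several-fold. All reported checks recompute at run time; nothing is stored.

## Known limitations

* No accumulation of hydraulic damage across drought events: severe-drought
  behavior is conservative (stomata close, but xylem recovers instantly).
* No within-canopy N profile, multi-layer radiative transfer, energy
  balance or boundary-layer conductance (explicitly neglected in the model
  formulation).
* Mesophyll conductance only as a fixed ratio; no C4 pathway.
* Soil moisture is exogenous — there is no water balance, so ablations that
  modify transpiration do not feed back on soil water.
* The $a_{J\max}$–$N_{mf}$ product identifiability noted above: without
  leaf-N observations the two are not separable.
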