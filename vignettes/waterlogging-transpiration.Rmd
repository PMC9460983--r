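---
title: "Modelling transpiration under waterlogging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transpiration under waterlogging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatflow)
```

## The problem

On drained peatland the water table can sit anywhere from the surface to
well over a metre down, and tree water use responds non-monotonically:
deep water tables dry the rooting zone (classical drought limitation),
while shallow ones displace soil air, starve roots of oxygen and shut
down water uptake (hypoxia). `peatflow` implements a hierarchical model
that carries a daily water table depth (WTD, $\delta$, cm) through soil
water content and a segmented soil-to-root conductance into an
optimal-stomata canopy model, and calibrates it against per-tree sap
flow converted to leaf-area transpiration.

## Process model

**Canopy.** Stomata are assumed to maximize carbon gain minus the water
cost $\lambda E$, which at steady state gives
$E = 1.6\,D\,g_\sigma$ with
$g_\sigma = (\sqrt{(C_a - R/f(I)) / (1.6\lambda D)} - 1) f(I)$.
Respiration follows a Q10 law in leaf temperature,
$T_l = T + 1.5\times10^3 I$, and the irradiance response
$f(I) = \iota\gamma I/(\iota I + \gamma)$ has its initial slope
$\iota = \max\{c\,(S - S_0), 0\}$ gated by a delayed temperature
acclimation state $S$ with daily dynamics $dS/dt = (T_l - S)/\tau$.

**Belowground.** Soil water content comes from a van Genuchten
retention curve in WTD. The soil-to-root conductance has a rising
(water-limited) power-law branch in relative saturation, a falling
(hypoxia) branch whose base is the available air-filled porosity proxy
$2\theta^* - \theta$, and a plateau spanning $\pm 10$ cm of WTD around
the optimal depth $\delta^*$, defined as the mean of the two branches
evaluated at the plateau edges; the realized conductance is the
pointwise minimum of the three. Root-to-leaf conductance is constant
per tree under an isohydric assumption,
$k_{rl} = \max J/(\rho\,|\Psi_{lmin}|)$, and composes in series with the
soil-to-root part. The marginal water-use efficiency is tied to the
soil-to-leaf conductance by $\log_{10}\lambda = z_0 + z_1\log_{10}
(k_{sl}/k_0)$ with $z_1 < 0$, so a throttled supply path raises the
price of water and closes stomata. The resulting $\lambda(\delta)$ is
U-shaped with its minimum on the plateau.

**Reference variants.** RM1 drops the belowground chain entirely and
estimates a constant per-tree $\lambda$; RM2 keeps the chain but uses
the rising branch alone (monotonic in soil water, i.e. no waterlogging
effect). RM2's uncapped form is the minimal structural change from the
full model; `pf_config(rm2_cap = "ksr_star")` caps it at the branch's
saturated value instead, which we expose because the choice is genuinely
open — the comparison results in the test suite hold under the default.

## Estimated parameters and priors

Nineteen process parameters are estimated for the six-tree application:
tree-specific rising-branch multipliers $\xi_{m,i}$ (box 0.07–0.15) and
acclimation slopes $c_i$ (0.01–0.07 m³ (mol °C)⁻¹), shared
$\xi_p$ (7–10), $\eta_m$ (0.05–0.17), $\eta_p$ (1.5–10), $\delta^*$
(20–50 cm), $z_0$ (−5.2 to −3.8), $z_1$ (−1.0 to −0.5) and $\gamma$
(1.6–3.0 × 10⁻³ m s⁻¹). All priors are independent and uniform on
closed boxes. Three error parameters complete the vector: the error SD
is $\exp(\alpha + \beta_{W1} E^{(M)})$ for the `W1` trees (ids 4 and 6)
and $\beta_{W2} E^{(M)}$ for the `W2` trees. The error-parameter boxes
($\alpha \in [-15, 0]$, $\beta_{W1} \in [0, 50]$,
$\beta_{W2} \in [0, 1]$) are package choices: wide enough to be
non-informative on the scales the data model can express, and exposed
through `pf_priors()`.

## Fixed constants

Constants not estimated are held in `pf_config()` and documented there.
The canopy block ($R_0 = 10^{-6}$ mol CO₂ m⁻² s⁻¹, $Q_{10} = 2$,
$S_0 = 0$ °C, $\tau = 8$ d, $C_a = 0.0167$ mol m⁻³ ≈ 400 ppm) uses
standard boreal-conifer values from the acclimation-model literature.
The tree block fixes $\rho = 2500$ m² leaf per m² sapwood and
$\Psi_{lmin} = -2$ MPa, typical for Scots pine.

The soil block needs more comment. The retention shape constants
($a = 0.072$ cm⁻¹, $n = 1.371$) describe the peat profile. The
remaining four — $\theta_{sat} = 0.88$, $\theta_{res} = 0.108$,
$k_0 = 2.218\times10^{-8}$, and the single factor
$9.283\times10^{-7}$ that converts the ground-area multipliers
$\xi_m,\eta_m$ to per-leaf-area conductance — were fixed once, jointly,
so that the belowground curves evaluated at the reference parameter
estimates of the six-tree Scots pine application reproduce that
application's conductance-plateau and water-cost ranges. Because the
conductance branches depend on water content only through
$\theta/\theta_{sat}$, the model is sensitive only to the ratio
$\theta_{res}/\theta_{sat}$, the conversion factor and $k_0$; the three
are identifiable from the curve ranges and the implied solution also
predicts the per-tree decline-onset depths to within a fraction of a
percent, which we treat as an independent consistency check. They are
ordinary config entries and should be re-derived for any other site.

## Numerical choices

* **Daily statistic.** Sub-daily records reduce to the median of the
  $\lceil 0.1 n\rceil$ largest values per day — the ceiling guarantees a
  non-empty set for any $n \ge 1$; ranking is stable under ties.
* **WTD anchoring.** Sparse manual tube readings are merged with the
  continuous logger by additive-offset anchoring: the manual-minus-
  logger offset is linearly interpolated in time and added to the
  logger series, which preserves the logger's temporal pattern and
  reproduces every manual reading exactly. Negative depths (standing
  water) clamp to 0 with a warning. Days missing any driver are
  dropped, never imputed.
* **Clamps.** The stomatal conductance and the square-root argument
  clamp at 0 (closure); the falling-branch base clamps at 0 for
  $\theta \ge 2\theta^*$ to avoid complex powers with non-integer
  exponents; the error SD is floored at $10^{-8}$ mol m⁻² s⁻¹ so the
  likelihood stays proper when modelled transpiration reaches 0.
* **Acclimation.** Forward Euler at $\Delta t = 1$ d, initialized at
  the first modelled day's leaf temperature (no pre-season data exist);
  an optional spin-up repeats day 1. $\theta^*$ is recomputed from
  $\delta^*$ at every likelihood evaluation.
* **Zero-intercept $R^2$.** Both conventions are implemented; the
  default compares residuals against the centered total sum of squares,
  the uncentered alternative sits behind the `r2` argument of
  `zero_intercept_fit()`.

## Sampler

The posterior is sampled by differential-evolution MCMC with snooker
updates and a growing archive of past states: three chains propose
jumps along difference vectors of archive states (step
$2.38/\sqrt{2d}$, occasionally 1 for mode switching; snooker moves with
probability 0.1), the archive is appended every 10 generations, and
proposals outside the box are rejected by the flat prior. Only the
second halves of the chains are retained for every summary; convergence
requires Gelman–Rubin $\hat R < 1.1$ on the retained halves, and a fit
failing the criterion is flagged, never silently accepted. The MAP
estimate is the retained draw with the highest log-posterior.

Because the posterior is far tighter than the prior box (thousands of
daily observations), `pf_fit()` by default seeds the archive from a
Laplace approximation around a posterior mode located by multi-start
box-constrained quasi-Newton search. This only accelerates the
sampler's adaptation — the chains still target the exact posterior —
and `init = "prior"` disables it. An all-chain stagnation guard aborts
with a diagnostic if acceptance stays under 1% for 2000 generations.

## Synthetic data

The generator reproduces the statistical structure the calibration
assumes, not meteorological realism: temperature is a seasonal sinusoid
plus AR(1) noise; humidity an AR(1) fluctuation clamped to [0.3, 1];
irradiance a clear-sky envelope thinned by beta-distributed cloudiness;
the water table follows a scheduled regime path (defaults 10, 47,
100 cm — hypoxic, plateau, water-limited) with AR(1) jitter, held 70%
of each segment so all three conductance regimes are well occupied.
Observations are forward-model transpiration plus heteroscedastic noise
with the `W1`/`W2` group structure; the generating truth is an interior
point of the prior box built from the reference six-tree estimates,
with error values ($\alpha = -8.6$, $\beta_{W1} = 30$,
$\beta_{W2} = 0.28$) that put per-tree NRMSE in the realistic 20–35%
band. Negative observation draws clamp at 0 (about 3% of tree-days in
the recovery scenario; the rate is attached to the generated table).
This clamp slightly biases the error model near zero flux — a known,
accepted feature that the recovery tolerances absorb.

What passing tests on these data do **not** show: robustness to driver
measurement error, to spatial WTD heterogeneity between tubes, to
seasonality in root physiology (e.g. water temperature effects, which
the model deliberately omits), or to misspecified group membership in
the error model. They do show that the estimation machinery recovers
known parameters under the model's own assumptions and that the
waterlogging branch is identifiable when the water table visits the
hypoxic regime.

## Problem sizes

The shipped experiments are desk-scale by design: the recovery scenario
uses 6 trees over 4 seasons of 150 days (600 days, ~3600 tree-days)
with 3 chains of 25 000 generations; the reference-model comparison
uses 2 seasons and 10 000 generations; predictive bands use 6000
posterior draws. These sizes give stable diagnostics ($\hat R < 1.1$)
while keeping a full test run in minutes on one core.

## Known limitations

The hypoxia branch is heuristic: $\eta_m,\eta_p$ lump aquaporin
dynamics, respiration enzymes and soil gas transport, and no
oxygen-diffusion mechanism is modelled. Water temperature is carried
through the pipeline (and its residual correlation is reported by
`residual_wtt_correlation()`) but does not enter the process model.
$\rho$ and $\Psi_{lmin}$ are constants although both vary with tree
size; $k_{rl}$ inherits any bias in the observed maximum sap flow. The
plateau half-width (10 cm) is structural, not estimated. Sub-daily
simulation and carbon-budget outputs are out of scope.
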