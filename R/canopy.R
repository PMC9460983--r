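# Optimal-stomata canopy model: temperature-dependent respiration, a
# saturating irradiance response gated by delayed temperature acclimation,
# and the optimal stomatal conductance / transpiration solution.

#' Canopy parameters
#'
#' Bundles the fixed canopy constants with the two estimated canopy
#' parameters: `c` (acclimation slope, per tree) and `gamma` (saturation
#' of the irradiance response).
#'
#' @param c Acclimation slope (m^3 (mol C)^-1); may be a vector per tree.
#' @param gamma Irradiance-response saturation (m s^-1).
#' @param fixed Fixed canopy block, e.g. `pf_config()$canopy`
#'   (`R0, Q10, S0, tau, Ca`).
#' @return list of class `canopy_params`.
#' @export
canopy_params <- function(c, gamma, fixed = pf_config()$canopy) {
  stopifnot(all(c > 0), gamma > 0, fixed$Q10 > 1, fixed$tau >= 1)
  structure(c(list(c = c, gamma = gamma), fixed), class = "canopy_params")
}

#' Foliage respiration
#'
#' Q10 temperature response \eqn{R = \max\{R_0 Q_{10}^{T_l/10}, 0\}}.
#'
#' @param T_l Leaf temperature (degrees C).
#' @param R0 Respiration at 0 C (mol CO2 m^-2 s^-1).
#' @param Q10 Relative increase per 10 C.
#' @export
respiration <- function(T_l, R0, Q10) {
  pmax(R0 * Q10^(T_l / 10), 0)
}

#' One daily step of the temperature-acclimation state
#'
#' Forward-Euler discretization (daily step) of
#' \eqn{dS/dt = (T_l - S)/\tau}: the acclimated temperature relaxes toward
#' the current leaf temperature at rate `1/tau`.
#'
#' @param S_prev Previous acclimation state (degrees C).
#' @param T_l Leaf temperature of the day (degrees C).
#' @param tau Time constant (days, >= 1).
#' @export
update_acclimation <- function(S_prev, T_l, tau) {
  stopifnot(tau >= 1)
  S_prev + (T_l - S_prev) / tau
}

#' Acclimation state over a daily series
#'
#' Runs the daily recursion over a leaf-temperature series. The state is
#' initialized at the first day's leaf temperature (no spin-up data exist
#' before the season starts); `spin_up` repeats day 1 that many times
#' first, which only matters for short series with `S_init` far from
#' equilibrium.
#'
#' @param T_l Daily leaf-temperature series.
#' @param tau Time constant (days).
#' @param S_init Initial state; defaults to `T_l[1]`.
#' @param spin_up Number of day-1 repetitions before the series.
#' @return Numeric vector of S, aligned with `T_l`.
#' @export
acclimation_series <- function(T_l, tau, S_init = T_l[1], spin_up = 0) {
  stopifnot(tau >= 1, length(T_l) >= 1)
  s <- S_init
  if (spin_up > 0) {
    for (k in seq_len(spin_up)) s <- update_acclimation(s, T_l[1], tau)
  }
  S <- numeric(length(T_l))
  S[1] <- s
  for (t in seq_along(T_l)[-1]) S[t] <- update_acclimation(S[t - 1], T_l[t], tau)
  S
}

#' Irradiance response of stomatal conductance
#'
#' Saturating hyperbola \eqn{f(I) = \iota \gamma I / (\iota I + \gamma)}
#' whose initial slope \eqn{\iota = \max\{c (S - S_0), 0\}} is gated by the
#' acclimation state: below the threshold `S0` the canopy is dormant and
#' `f(I) = 0` regardless of light.
#'
#' @param I PPFD (mol m^-2 s^-1, >= 0).
#' @param S Acclimation state (degrees C).
#' @param c Acclimation slope.
#' @param gamma Saturation (m s^-1).
#' @param S0 Threshold temperature (degrees C).
#' @return f(I) in m s^-1, in `[0, gamma)`.
#' @export
light_response <- function(I, S, c, gamma, S0 = pf_config()$canopy$S0) {
  if (any(I < 0, na.rm = TRUE)) stop("`I` must be non-negative")
  iota <- pmax(c * (S - S0), 0)
  ifelse(iota * I > 0, iota * gamma * I / (iota * I + gamma), 0)
}

#' Optimal stomatal conductance and transpiration
#'
#' The interior optimum of the stomatal control problem (maximize carbon
#' gain minus lambda times water loss) gives
#' \deqn{E = 1.6 D g_\sigma = 1.6 D \left(\sqrt{\frac{C_a - R/f(I)}
#'   {1.6 \lambda D}} - 1\right) f(I)}
#' `g_sigma` is clamped at 0 (stomata fully closed) when the square root
#' falls below 1, i.e. when \eqn{1.6 \lambda D \ge C_a - R/f(I)}; the
#' square-root argument is likewise clamped at 0. When `f(I)` is (near)
#' zero the canopy is dark or dormant and E = 0.
#'
#' @param D Vapour concentration deficit (mol H2O m^-3, >= 0).
#' @param fI Irradiance response (m s^-1), see [light_response()].
#' @param R Respiration (mol CO2 m^-2 s^-1), see [respiration()].
#' @param lambda Marginal water-use efficiency (mol CO2 mol^-1 H2O, > 0).
#' @param Ca Atmospheric CO2 (mol m^-3).
#' @return list with `g_sigma` (m s^-1) and `E` (mol H2O m^-2 leaf s^-1),
#'   vectorized over the inputs.
#' @export
transpiration <- function(D, fI, R, lambda, Ca = pf_config()$canopy$Ca) {
  if (any(lambda <= 0, na.rm = TRUE)) stop("`lambda` must be positive")
  if (any(D < 0, na.rm = TRUE)) stop("`D` must be non-negative")
  n <- max(length(D), length(fI), length(R), length(lambda))
  D <- rep_len(D, n); fI <- rep_len(fI, n)
  R <- rep_len(R, n); lambda <- rep_len(lambda, n)
  inner <- pmax(Ca - R / pmax(fI, 1e-300), 0)
  g <- pmax(sqrt(inner / (1.6 * lambda * pmax(D, 1e-300))) - 1, 0) * fI
  dead <- fI < 1e-12 | D <= 0
  g[dead] <- 0
  list(g_sigma = g, E = 1.6 * D * g)
}
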