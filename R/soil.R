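# Soil hydraulics: water retention, the segmented soil-to-root conductance,
# the series soil-to-leaf composition, and the marginal water-use
# efficiency bridge.
#
# The soil-to-root conductance is deliberately non-monotonic in water table
# depth: deep water tables dry the rooting zone (water limitation, rising
# branch in soil water content), shallow water tables displace soil air
# (hypoxia, falling branch), and in between the conductance holds a
# plateau spanning 20 cm of WTD around the optimal depth delta_star.

#' Soil water content from water table depth
#'
#' van Genuchten retention evaluated at a depth-equivalent suction:
#' \deqn{\theta(\delta) = \theta_{res} + (\theta_{sat} - \theta_{res}) /
#'   [1 + (a \delta)^n]^{1 - 1/n}}
#' Strictly decreasing in `delta`, equal to `theta_sat` at the surface and
#' approaching `theta_res` at depth.
#'
#' @param delta Water table depth (cm, positive downward, >= 0).
#' @param soil Soil constant block, e.g. `pf_config()$soil`.
#' @return Volumetric soil water content (m^3 m^-3).
#' @export
theta_of_wtd <- function(delta, soil = pf_config()$soil) {
  if (any(delta < 0, na.rm = TRUE)) stop("`delta` must be >= 0")
  f <- (1 + (soil$a_vg * delta)^soil$n_vg)^(1 - 1 / soil$n_vg)
  soil$theta_res + (soil$theta_sat - soil$theta_res) / f
}

#' Soil-root conductance parameters
#'
#' Container for the segmented soil-to-root conductance. `xi_m` may be a
#' vector (one multiplier per tree); the remaining entries are shared.
#'
#' @param xi_m Rising-branch multiplier(s) (mol m^-2 s^-1 Pa^-1, ground
#'   area scale; converted to leaf area by `soil$leaf_conv`).
#' @param xi_p Rising-branch exponent.
#' @param eta_m,eta_p Falling-branch (hypoxia) multiplier and exponent.
#' @param delta_star Optimal water table depth (cm, >= 10).
#' @return list of class `soil_root_params`.
#' @export
soil_root_params <- function(xi_m, xi_p, eta_m, eta_p, delta_star) {
  stopifnot(all(xi_m > 0), xi_p > 0, eta_m > 0, eta_p > 0, delta_star >= 10)
  structure(list(xi_m = xi_m, xi_p = xi_p, eta_m = eta_m, eta_p = eta_p,
                 delta_star = delta_star), class = "soil_root_params")
}

#' Segmented soil-to-root conductance
#'
#' `ksr_plus()` is the water-limited rising branch
#' \eqn{\xi_m (\theta/\theta_{sat})^{\xi_p}}; `ksr_minus()` is the
#' hypoxia-limited falling branch
#' \eqn{\eta_m ((2\theta^* - \theta)/\theta_{sat})^{\eta_p}} with the base
#' clamped at 0 (so the branch vanishes, rather than turning complex, for
#' \eqn{\theta \ge 2\theta^*}); `ksr_star()` is the plateau constant, the
#' mean of the two branches evaluated 10 cm on either side of the optimal
#' depth; `ksr()` is their pointwise minimum. The optimal soil water
#' content \eqn{\theta^*} is recomputed from `delta_star` at every call.
#' All values are per unit leaf area (the `leaf_conv` factor of the soil
#' block is applied here and nowhere else).
#'
#' @param theta Soil water content (m^3 m^-3), `0 < theta <= theta_sat`.
#' @param p [soil_root_params()] (with scalar `xi_m` for the per-tree use).
#' @param soil Soil constant block, e.g. `pf_config()$soil`.
#' @return Conductance (mol H2O m^-2 leaf s^-1 Pa^-1).
#' @export
ksr_plus <- function(theta, p, soil = pf_config()$soil) {
  if (any(theta <= 0 | theta > soil$theta_sat, na.rm = TRUE)) {
    stop("`theta` must lie in (0, theta_sat]")
  }
  soil$leaf_conv * p$xi_m * (theta / soil$theta_sat)^p$xi_p
}

#' @rdname ksr_plus
#' @export
ksr_minus <- function(theta, p, soil = pf_config()$soil) {
  theta_star <- theta_of_wtd(p$delta_star, soil)
  base <- (2 * theta_star - theta) / soil$theta_sat
  if (any(base <= 0, na.rm = TRUE)) {
    warning("theta >= 2 theta_star: falling-branch base clamped at 0")
  }
  soil$leaf_conv * p$eta_m * pmax(base, 0)^p$eta_p
}

#' @rdname ksr_plus
#' @export
ksr_star <- function(p, soil = pf_config()$soil) {
  stopifnot(p$delta_star >= 10)
  (ksr_plus(theta_of_wtd(p$delta_star + 10, soil), p, soil) +
     ksr_minus(theta_of_wtd(p$delta_star - 10, soil), p, soil)) / 2
}

#' @rdname ksr_plus
#' @param delta Water table depth (cm, >= 0); `ksr()` is parameterized by
#'   depth and converts to water content internally.
#' @export
ksr <- function(delta, p, soil = pf_config()$soil) {
  theta <- theta_of_wtd(delta, soil)
  pmin(ksr_plus(theta, p, soil),
       suppressWarnings(ksr_minus(theta, p, soil)),
       ksr_star(p, soil))
}

#' Root-to-leaf conductance of a tree
#'
#' Assumes isohydric regulation: the observed maximum sap flow density is
#' sustained at the minimum leaf water potential, so
#' \eqn{k_{rl} = \max J / (\rho |\Psi_{lmin}|)}.
#'
#' @param J_max Maximum observed sap flow density (mol H2O m^-2 sapwood
#'   s^-1); may be a vector over trees.
#' @param tree Tree constant block, e.g. `pf_config()$tree`.
#' @return Conductance (mol H2O m^-2 leaf s^-1 Pa^-1).
#' @export
k_rl <- function(J_max, tree = pf_config()$tree) {
  stopifnot(all(J_max > 0), tree$rho > 0, tree$psi_lmin < 0)
  J_max / (tree$rho * abs(tree$psi_lmin))
}

#' Series soil-to-leaf conductance
#'
#' Harmonic composition \eqn{k_{sl}^{-1} = k_{sr}^{-1} + k_{rl}^{-1}}; a
#' blocked soil-root segment (`ksr = 0`) blocks the whole path.
#'
#' @param ksr,krl Component conductances (same units).
#' @export
ksl <- function(ksr, krl) {
  1 / (1 / ksr + 1 / krl)
}

#' Marginal water-use efficiency from soil-to-leaf conductance
#'
#' Log-log-linear bridge \eqn{\log_{10}\lambda = z_0 + z_1 \log_{10}(k_{sl}
#' / k_0)} with \eqn{z_1 < 0}: the scarcer the supply path, the higher the
#' marginal cost of water and the more conservative the stomata.
#'
#' @param k_sl Soil-to-leaf conductance (> 0).
#' @param z0,z1 Intercept and (negative) slope of the bridge.
#' @param k0 Base-case xylem conductance (same units as `k_sl`).
#' @return lambda (mol CO2 mol^-1 H2O).
#' @export
mwue <- function(k_sl, z0, z1, k0 = pf_config()$soil$k0) {
  if (any(k_sl <= 0, na.rm = TRUE)) stop("`k_sl` must be positive")
  10^(z0 + z1 * log10(k_sl / k0))
}

#' Conductance and water-cost curves over a depth grid
#'
#' Evaluates the whole belowground chain on a WTD grid for each tree:
#' soil water content, segmented soil-to-root conductance, series
#' soil-to-leaf conductance and marginal water-use efficiency. This is the
#' deterministic "curve" view of a parameter vector, useful for plotting
#' the plateau, the hypoxic decline and the U-shaped water cost.
#'
#' @param params Named list with `xi_m` (one per tree), `xi_p`, `eta_m`,
#'   `eta_p`, `delta_star`, `z0`, `z1` (see [decode_params()]).
#' @param trees data.frame with `tree_id` and `J_max` (see [pf_trees()]).
#' @param delta Depth grid (cm).
#' @param config [pf_config()].
#' @return data.frame `delta, tree_id, theta, ksr, ksl, lambda` (long).
#' @export
pf_curves <- function(params, trees = pf_trees(),
                      delta = seq(0, 200, by = 0.5), config = pf_config()) {
  soil <- config$soil
  theta <- theta_of_wtd(delta, soil)
  krl <- k_rl(trees$J_max, config$tree)
  out <- lapply(seq_len(nrow(trees)), function(i) {
    p <- soil_root_params(params$xi_m[i], params$xi_p, params$eta_m,
                          params$eta_p, params$delta_star)
    ks <- ksr(delta, p, soil)
    kl <- ksl(ks, krl[i])
    data.frame(delta = delta, tree_id = trees$tree_id[i], theta = theta,
               ksr = ks, ksl = kl,
               lambda = mwue(kl, params$z0, params$z1, soil$k0))
  })
  do.call(rbind, out)
}

#' Onset depth of the hypoxic conductance decline
#'
#' The water table depth below which (moving shallower) a tree's
#' soil-to-root conductance leaves its plateau and starts to fall on the
#' hypoxia branch: the root of \eqn{k_{sr}^-(\theta(\delta)) = k_{sr}^*}.
#'
#' @inheritParams pf_curves
#' @return Named numeric vector, one onset depth (cm) per tree.
#' @export
decline_onset <- function(params, trees = pf_trees(), config = pf_config()) {
  soil <- config$soil
  vapply(seq_len(nrow(trees)), function(i) {
    p <- soil_root_params(params$xi_m[i], params$xi_p, params$eta_m,
                          params$eta_p, params$delta_star)
    target <- ksr_star(p, soil)
    f <- function(d) ksr_minus(theta_of_wtd(d, soil), p, soil) - target
    stats::uniroot(f, c(1e-6, p$delta_star + 10), tol = 1e-10)$root
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(trees$tree_id)
}
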