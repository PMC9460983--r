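# Forward model: compose drivers -> soil hydraulics -> canopy into daily
# per-tree transpiration for the full model (FM) and the two reference
# models (RM1: constant per-tree water cost, no belowground chain;
# RM2: belowground chain with a monotonic, water-limited-only soil-to-root
# conductance).
#
# The likelihood evaluates this model tens of thousands of times, so the
# data-dependent quantities that do not involve estimated parameters
# (retention curve, respiration, acclimation state, root-to-leaf
# conductances) are precomputed once per data set and the per-evaluation
# core works on (day x tree) matrices.

# Precompute everything that depends on data and fixed constants only.
.pf_prepare <- function(drivers, trees, config) {
  soil <- config$soil; can <- config$canopy
  n <- nrow(drivers); m <- nrow(trees)
  x <- theta_of_wtd(drivers$delta, soil) / soil$theta_sat
  krl <- k_rl(trees$J_max, config$tree)
  list(
    n = n, m = m, soil = soil, can = can, config = config,
    date = drivers$date, delta = drivers$delta,
    D = drivers$D, I = drivers$I,
    x = x, lx = log(x),
    R = respiration(drivers$T_l, can$R0, can$Q10),
    S = acclimation_series(drivers$T_l, can$tau),
    krl = krl,
    inv_krl = matrix(1 / krl, n, m, byrow = TRUE),
    tree_id = trees$tree_id
  )
}

# theta(delta)/theta_sat for a scalar depth (plateau bookkeeping).
.xfrac <- function(delta, soil) theta_of_wtd(delta, soil) / soil$theta_sat

# Core simulator on a prepared data set. Returns list of (n x m) matrices.
.pf_sim_core <- function(pre, p) {
  n <- pre$n; m <- pre$m; soil <- pre$soil; can <- pre$can
  if (p$variant == "RM1") {
    k_sr <- k_sl <- NULL
    lambda <- matrix(p$lambda, n, m, byrow = TRUE)
  } else {
    kplus <- soil$leaf_conv * outer(exp(p$xi_p * pre$lx), p$xi_m)
    if (p$variant == "FM") {
      xstar <- .xfrac(p$delta_star, soil)
      bm <- pmax(2 * xstar - pre$x, 0)
      kminus <- soil$leaf_conv * p$eta_m * bm^p$eta_p
      kstar <- soil$leaf_conv *
        (p$xi_m * .xfrac(p$delta_star + 10, soil)^p$xi_p +
           p$eta_m * (2 * xstar - .xfrac(p$delta_star - 10, soil))^p$eta_p) / 2
      k_sr <- pmin(pmin(kplus, kminus), matrix(kstar, n, m, byrow = TRUE))
    } else { # RM2: monotonic rising branch, optionally capped
      k_sr <- kplus
      if (identical(pre$config$rm2_cap, "ksr_star")) {
        # cap at the rising branch's own saturated value (theta = theta_sat)
        k_sr <- pmin(k_sr, matrix(soil$leaf_conv * p$xi_m, n, m, byrow = TRUE))
      }
    }
    k_sl <- 1 / (1 / k_sr + pre$inv_krl)
    lambda <- 10^p$z0 * (k_sl / soil$k0)^p$z1
  }
  iota <- pmax(outer(pmax(pre$S - can$S0, 0), p$c), 0)
  fI <- iota * p$gamma * pre$I / (iota * pre$I + p$gamma)
  fI[iota * pre$I == 0] <- 0
  inner <- pmax(can$Ca - pre$R / pmax(fI, 1e-300), 0)
  g <- pmax(sqrt(inner / (1.6 * lambda * pmax(pre$D, 1e-300))) - 1, 0) * fI
  g[fI < 1e-12 | pre$D <= 0] <- 0
  list(E = 1.6 * pre$D * g, g_sigma = g, k_sr = k_sr, k_sl = k_sl,
       lambda = lambda)
}

#' Simulate daily per-tree transpiration
#'
#' Runs the composed process model over a daily driver table for one of
#' the three model variants:
#' \describe{
#'   \item{FM}{full model -- segmented (non-monotonic) soil-to-root
#'     conductance, series soil-to-leaf composition, water cost from the
#'     conductance bridge.}
#'   \item{RM1}{no belowground chain; the water cost is a constant
#'     per-tree parameter `lambda`.}
#'   \item{RM2}{belowground chain with the water-limited rising branch
#'     only (no hypoxia cut; `config$rm2_cap` optionally caps it).}
#' }
#' The acclimation state is driven by the same leaf-temperature series in
#' every variant. Deterministic: identical inputs give identical output.
#'
#' @param drivers data.frame `date, D, I, T, T_l, delta` (see
#'   [reduce_daily()] or [generate_drivers()]).
#' @param params Decoded parameter list (see [decode_params()]) or a flat
#'   vector together with `priors`.
#' @param trees data.frame `tree_id, J_max` (see [pf_trees()]).
#' @param priors Required when `params` is a flat vector.
#' @param config [pf_config()].
#' @return data.frame `date, tree_id, E_model, k_sr, k_sl, lambda, S`
#'   (belowground diagnostics are `NA` for RM1), ordered by tree then date.
#' @export
pf_simulate <- function(drivers, params, trees, priors = NULL,
                        config = pf_config()) {
  if (is.numeric(params)) {
    stopifnot(!is.null(priors))
    params <- decode_params(params, priors)
  }
  stopifnot(all(is.finite(drivers$D)), all(is.finite(drivers$delta)))
  pre <- .pf_prepare(drivers, trees, config)
  sim <- .pf_sim_core(pre, params)
  grab <- function(M, j) if (is.null(M)) NA_real_ else M[, j]
  out <- lapply(seq_len(pre$m), function(j) {
    data.frame(date = pre$date, tree_id = pre$tree_id[j],
               E_model = sim$E[, j], k_sr = grab(sim$k_sr, j),
               k_sl = grab(sim$k_sl, j), lambda = sim$lambda[, j],
               S = pre$S)
  })
  do.call(rbind, out)
}
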