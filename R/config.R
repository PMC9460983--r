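# Fixed constants of the model. Everything here is held constant during
# calibration; only the entries of the parameter vector (see pf_priors)
# are estimated.

#' Model configuration: fixed constants
#'
#' Returns the fixed-constant configuration consumed by the forward model
#' and the calibration, with any element overridable by name. The soil
#' block holds the van Genuchten retention constants of the peat profile
#' and the two scale constants of the conductance chain; the canopy block
#' holds the respiration, acclimation and CO2 constants of the
#' optimal-stomata model; the tree block holds the hydraulic conversion
#' constants.
#'
#' Defaults (units in brackets):
#' \describe{
#'   \item{soil}{`theta_sat` 0.88, `theta_res` 0.1080 (m^3 m^-3),
#'     `a_vg` 0.072 (cm^-1), `n_vg` 1.371, `k0` 2.218e-8 (mol H2O m^-2
#'     leaf s^-1 Pa^-1, base-case xylem conductance of the water-cost
#'     bridge), `leaf_conv` 9.283e-7 (dimensionless factor taking the
#'     ground-area conductance multipliers `xi_m`/`eta_m` to per-leaf-area
#'     conductance; applied once, inside the soil-to-root functions).}
#'   \item{canopy}{`R0` 1e-6 (mol CO2 m^-2 s^-1, respiration at 0 C),
#'     `Q10` 2 (relative increase per 10 C), `S0` 0 (C, acclimation
#'     threshold), `tau` 8 (days, acclimation time constant), `Ca` 0.0167
#'     (mol m^-3, atmospheric CO2).}
#'   \item{tree}{`rho` 2500 (m^2 leaf m^-2 sapwood), `psi_lmin` -2e6 (Pa,
#'     minimum leaf water potential, isohydric).}
#'   \item{error}{`sd_floor` 1e-8 (mol m^-2 s^-1), keeping the likelihood
#'     proper when modelled transpiration approaches 0.}
#'   \item{rm2_cap}{`"none"` or `"ksr_star"`: whether the monotonic
#'     reference model caps its conductance at the plateau value.}
#' }
#'
#' @param ... Named overrides, e.g. `pf_config(soil = list(theta_sat = 0.9))`
#'   merges into the default soil block.
#' @return A list of class `pf_config`.
#' @export
pf_config <- function(...) {
  cfg <- list(
    soil = list(theta_sat = 0.88, theta_res = 0.1080,
                a_vg = 0.072, n_vg = 1.371,
                k0 = 2.218e-8, leaf_conv = 9.283e-7),
    canopy = list(R0 = 1e-6, Q10 = 2, S0 = 0, tau = 8, Ca = 0.0167),
    tree = list(rho = 2500, psi_lmin = -2e6),
    error = list(sd_floor = 1e-8),
    rm2_cap = "none"
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pf_config")
}

#' Reference tree table
#'
#' The six monitored Scots pine trees: diameter at breast height, the
#' sapwood thickness implied by [sapwood_thickness()], the maximum sap flow
#' density observed over the study period (used for the root-to-leaf
#' conductance, see [k_rl()]), and the heteroscedasticity group of the
#' error model (`W1`: log-linear SD; `W2`: proportional SD).
#'
#' @param n Number of trees (1 to 6); the first `n` rows are returned.
#' @return data.frame `tree_id, dbh_cm, sw_cm, J_max, group`.
#' @export
pf_trees <- function(n = 6) {
  stopifnot(n >= 1, n <= 6)
  tab <- data.frame(
    tree_id = as.character(1:6),
    dbh_cm = c(12.9, 16.2, 15.0, 15.7, 13.3, 17.5),
    J_max = c(2.116, 1.415, 1.230, 1.948, 1.877, 2.072),
    group = c("W2", "W2", "W2", "W1", "W2", "W1"),
    stringsAsFactors = FALSE
  )
  tab$sw_cm <- round(sapwood_thickness(tab$dbh_cm * 10) / 10, 2)
  tab[seq_len(n), c("tree_id", "dbh_cm", "sw_cm", "J_max", "group")]
}
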