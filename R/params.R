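# The estimated parameter vector and its uniform prior boxes.
#
# Full model (FM), n trees: xi_m per tree, xi_p, eta_m, eta_p, delta_star,
# z0, z1, c per tree, gamma (process), plus alpha, beta_w1, beta_w2
# (error) -- 22 parameters for the six-tree case (19 process + 3 error).
# RM1 replaces the whole belowground chain by a constant per-tree lambda;
# RM2 keeps the chain but drops the hypoxia branch (no eta_m, eta_p,
# delta_star).

#' Prior boxes for the estimated parameters
#'
#' Independent uniform priors for every estimated parameter of a model
#' variant. Process-parameter boxes: `xi_m` (0.07, 0.15), `xi_p` (7, 10),
#' `eta_m` (0.05, 0.17), `eta_p` (1.5, 10), `delta_star` (20, 50) cm,
#' `z0` (-5.2, -3.8), `z1` (-1.0, -0.5), `c` (0.01, 0.07), `gamma`
#' (1.6e-3, 3.0e-3) m s^-1. Error-model boxes: `alpha` (-15, 0),
#' `beta_w1` (0, 50), `beta_w2` (0, 1). The per-tree constant
#' water-use-efficiency of RM1 has the box `lambda` (1e-3, 1e-2)
#' mol CO2 mol^-1 H2O.
#'
#' @param variant `"FM"`, `"RM1"` or `"RM2"`.
#' @param n_trees Number of trees (tree-specific parameters repeat).
#' @return data.frame `name, lower, upper` of class `pf_priors`; one row
#'   per scalar parameter, in the canonical vector order.
#' @export
pf_priors <- function(variant = c("FM", "RM1", "RM2"), n_trees = 6) {
  variant <- match.arg(variant)
  row <- function(name, lo, hi) data.frame(name = name, lower = lo,
                                           upper = hi,
                                           stringsAsFactors = FALSE)
  per_tree <- function(stem, lo, hi)
    row(paste0(stem, seq_len(n_trees)), lo, hi)
  process <- switch(variant,
    FM = rbind(per_tree("xi_m", 0.07, 0.15),
               row("xi_p", 7, 10), row("eta_m", 0.05, 0.17),
               row("eta_p", 1.5, 10), row("delta_star", 20, 50),
               row("z0", -5.2, -3.8), row("z1", -1.0, -0.5),
               per_tree("c", 0.01, 0.07),
               row("gamma", 1.6e-3, 3.0e-3)),
    RM1 = rbind(per_tree("lambda", 1e-3, 1e-2),
                per_tree("c", 0.01, 0.07),
                row("gamma", 1.6e-3, 3.0e-3)),
    RM2 = rbind(per_tree("xi_m", 0.07, 0.15),
                row("xi_p", 7, 10),
                row("z0", -5.2, -3.8), row("z1", -1.0, -0.5),
                per_tree("c", 0.01, 0.07),
                row("gamma", 1.6e-3, 3.0e-3)))
  pri <- rbind(process,
               row("alpha", -15, 0), row("beta_w1", 0, 50),
               row("beta_w2", 0, 1))
  attr(pri, "variant") <- variant
  attr(pri, "n_trees") <- n_trees
  class(pri) <- c("pf_priors", "data.frame")
  pri
}

#' Decode / encode a flat parameter vector
#'
#' `decode_params()` turns a flat named-order vector into the structured
#' list the forward model consumes (`xi_m` and `c` as length-`n_trees`
#' vectors); `encode_params()` is its exact inverse. Round-tripping is
#' bit-identical.
#'
#' @param v Numeric vector in the order of `priors$name`.
#' @param priors A [pf_priors()] table.
#' @return `decode_params()`: a named list with entries depending on the
#'   variant; `encode_params()`: a numeric vector.
#' @export
decode_params <- function(v, priors) {
  stopifnot(length(v) == nrow(priors))
  n <- attr(priors, "n_trees")
  variant <- attr(priors, "variant")
  names(v) <- priors$name
  g <- function(stem) unname(v[paste0(stem, seq_len(n))])
  out <- switch(variant,
    FM = list(xi_m = g("xi_m"), xi_p = v[["xi_p"]], eta_m = v[["eta_m"]],
              eta_p = v[["eta_p"]], delta_star = v[["delta_star"]],
              z0 = v[["z0"]], z1 = v[["z1"]], c = g("c"),
              gamma = v[["gamma"]]),
    RM1 = list(lambda = g("lambda"), c = g("c"), gamma = v[["gamma"]]),
    RM2 = list(xi_m = g("xi_m"), xi_p = v[["xi_p"]],
               z0 = v[["z0"]], z1 = v[["z1"]], c = g("c"),
               gamma = v[["gamma"]]))
  out$alpha <- v[["alpha"]]
  out$beta_w1 <- v[["beta_w1"]]
  out$beta_w2 <- v[["beta_w2"]]
  out$variant <- variant
  out
}

#' @rdname decode_params
#' @param p A decoded parameter list.
#' @export
encode_params <- function(p, priors) {
  n <- attr(priors, "n_trees")
  variant <- attr(priors, "variant")
  stopifnot(identical(p$variant, variant))
  v <- switch(variant,
    FM = c(p$xi_m, p$xi_p, p$eta_m, p$eta_p, p$delta_star, p$z0, p$z1,
           p$c, p$gamma),
    RM1 = c(p$lambda, p$c, p$gamma),
    RM2 = c(p$xi_m, p$xi_p, p$z0, p$z1, p$c, p$gamma))
  v <- c(v, p$alpha, p$beta_w1, p$beta_w2)
  stats::setNames(as.numeric(v), priors$name)
}

#' Is a parameter vector inside its prior box?
#'
#' @inheritParams decode_params
#' @return Logical scalar; boundary points count as inside (closed boxes).
#' @export
in_prior_box <- function(v, priors) {
  length(v) == nrow(priors) && all(is.finite(v)) &&
    all(v >= priors$lower & v <= priors$upper)
}
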