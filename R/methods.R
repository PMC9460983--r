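# S3 methods for fitted calibration objects.

#' @export
print.pf_fit <- function(x, ...) {
  cat("Water-table-driven transpiration model (variant ", x$variant,
      ")\n", sep = "")
  cat(sprintf("  %d trees, %d days, %d parameters\n",
              nrow(x$trees), nrow(x$drivers), nrow(x$priors)))
  cat(sprintf("  chains: %d x %d, acceptance %.1f%%, max R-hat %.3f%s\n",
              x$chain$settings$n_chains, x$chain$settings$n_iter,
              100 * x$accept_rate, max(x$rhat),
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  MAP log-posterior: %.2f\n",
              attr(x$map, "log_posterior")))
  invisible(x)
}

#' Summarize a fitted calibration
#'
#' Per-parameter table of the MAP estimate, the central 95% credible
#' interval and the Gelman-Rubin R-hat, computed from the retained
#' (second) halves of the chains, plus the per-tree error statistics of
#' the MAP simulation.
#'
#' @param object A [pf_fit()] object.
#' @param ... Unused.
#' @return list of class `summary.pf_fit` with elements `parameters`
#'   (data.frame `map, q2.5, q97.5, rhat`), `tree_errors` (see
#'   [pf_tree_errors()]), `regression` (zero-intercept fit of observed on
#'   modelled, see [zero_intercept_fit()]) and the convergence flag.
#' @export
summary.pf_fit <- function(object, ...) {
  pars <- data.frame(map = as.numeric(object$map),
                     q2.5 = object$ci[, "q2.5"],
                     q97.5 = object$ci[, "q97.5"],
                     rhat = object$rhat,
                     row.names = object$priors$name)
  al <- .aligned_obs_mod(object)
  out <- list(variant = object$variant, parameters = pars,
              regression = zero_intercept_fit(al$obs, al$mod),
              tree_errors = pf_tree_errors(al$obs_mat, al$mod_mat,
                                           object$trees$tree_id),
              converged = object$converged,
              accept_rate = object$accept_rate)
  class(out) <- "summary.pf_fit"
  out
}

#' @export
print.summary.pf_fit <- function(x, ...) {
  cat("Calibration summary (variant ", x$variant, ")\n\n", sep = "")
  print(format(x$parameters, digits = 4))
  cat(sprintf("\nObserved ~ 0 + modelled: slope %.3f, R^2 %.3f (n = %d)\n",
              x$regression$slope, x$regression$r_squared, x$regression$n))
  cat("Per-tree NRMSE (%):",
      paste(sprintf("%s: %.1f", x$tree_errors$tree_id,
                    x$tree_errors$nrmse), collapse = ", "), "\n")
  if (!x$converged) cat("NOTE: R-hat convergence criterion not met.\n")
  invisible(x)
}

#' @export
coef.pf_fit <- function(object, type = c("map", "median"), ...) {
  type <- match.arg(type)
  if (type == "map") {
    v <- as.numeric(object$map)
  } else {
    v <- apply(object$retained, 2, stats::median)
  }
  stats::setNames(v, object$priors$name)
}

# Aligned observed/modelled values at the MAP estimate.
.aligned_obs_mod <- function(object, drivers = NULL) {
  if (is.null(drivers)) drivers <- object$drivers
  pre <- .pf_prepare(drivers, object$trees, object$config)
  mod <- .pf_sim_core(pre, decode_params(object$map, object$priors))$E
  obs <- .obs_matrix(object$obs, drivers$date, object$trees$tree_id)
  ok <- is.finite(obs)
  list(obs = obs[ok], mod = mod[ok], obs_mat = obs, mod_mat = mod,
       delta = pre$delta, ok = ok, pre = pre)
}

#' Predict transpiration from a fitted model
#'
#' Simulates the process model at the MAP estimate over a driver table
#' (the fitted one by default).
#'
#' @param object A [pf_fit()] object.
#' @param newdata Optional driver table `date, D, I, T, T_l, delta`.
#' @param ... Unused.
#' @return data.frame as returned by [pf_simulate()].
#' @export
predict.pf_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$drivers
  pf_simulate(newdata, object$map, object$trees, priors = object$priors,
              config = object$config)
}

#' @export
fitted.pf_fit <- function(object, ...) {
  al <- .aligned_obs_mod(object)
  al$mod_mat
}

#' @export
residuals.pf_fit <- function(object, ...) {
  al <- .aligned_obs_mod(object)
  pf_residuals(al$obs_mat, al$mod_mat)
}

#' Posterior predictive simulation of observations
#'
#' Draws `nsim` parameter vectors from the retained posterior and, for
#' each, simulates the model over the fitted drivers and adds
#' heteroscedastic observation noise.
#'
#' @param object A [pf_fit()] object.
#' @param nsim Number of replicate observation sets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` data.frames `date, tree_id, E_obs`.
#' @export
simulate.pf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pre <- .pf_prepare(object$drivers, object$trees, object$config)
  idx <- sample.int(nrow(object$retained), nsim, replace = TRUE)
  lapply(idx, function(s) {
    p <- decode_params(object$retained[s, ], object$priors)
    E <- .pf_sim_core(pre, p)$E
    sd <- .pf_sd(E, p$alpha, p$beta_w1, p$beta_w2, object$trees$group,
                 object$config$error$sd_floor)
    data.frame(date = rep(pre$date, pre$m),
               tree_id = rep(pre$tree_id, each = pre$n),
               E_obs = as.vector(E + stats::rnorm(length(E), 0, sd)))
  })
}

#' Observed-versus-modelled diagnostic plot
#'
#' Scatter of observed against MAP-modelled transpiration with the 1:1
#' line and the zero-intercept regression line; shallow-water-table days
#' (depth above the fitted hypoxic decline region) are highlighted when
#' the variant carries a belowground model.
#'
#' @param x A [pf_fit()] object.
#' @param ... Passed to [plot()].
#' @export
plot.pf_fit <- function(x, ...) {
  al <- .aligned_obs_mod(x)
  mod <- al$mod_mat[al$ok]; obs <- al$obs_mat[al$ok]
  plot(mod, obs, pch = 16, cex = 0.5, col = "grey50",
       xlab = expression(E^(M) ~ (mol ~ m^-2 ~ s^-1)),
       ylab = expression(E^(O) ~ (mol ~ m^-2 ~ s^-1)), ...)
  if (x$variant != "RM1") {
    dstar <- if (x$variant == "FM") {
      decode_params(x$map, x$priors)$delta_star
    } else {
      NA_real_
    }
    if (is.finite(dstar)) {
      shallow <- matrix(al$delta < dstar - 10, length(al$delta),
                        nrow(x$trees))[al$ok]
      graphics::points(mod[shallow], obs[shallow], pch = 16, cex = 0.5,
                       col = "dodgerblue3")
    }
  }
  graphics::abline(0, 1, col = "red", lty = 2)
  graphics::abline(0, zero_intercept_fit(obs, mod)$slope, col = "grey20")
  invisible(x)
}
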