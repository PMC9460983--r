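# Synthetic data with the statistical structure the calibration assumes:
# seasonal sinusoid + AR(1) weather, a water-table trajectory visiting the
# waterlogged, optimal and dry conductance regimes, and observations
# generated from the forward model plus the heteroscedastic error model.
# Driver realism is not the goal -- only ranges, autocorrelation and
# regime coverage matter to the model.

# Stationary AR(1) noise with marginal standard deviation `sd`.
.ar1 <- function(n, phi, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - phi^2)),
                           phi, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

#' Reference "true" parameter vector for synthetic scenarios
#'
#' An interior point of the full-model prior box used as the generating
#' truth: tree-specific multipliers and acclimation slopes spread over
#' their boxes, a conductance bridge in the middle of the plausible range,
#' and error-model values that put per-tree noise around 20--30% of the
#' mean signal.
#'
#' @param n_trees Number of trees (1 to 6).
#' @return Named flat vector in [pf_priors()] order for `"FM"`.
#' @export
pf_true_params <- function(n_trees = 6) {
  stopifnot(n_trees >= 1, n_trees <= 6)
  n <- n_trees
  xi_m <- c(0.084, 0.100, 0.097, 0.146, 0.103, 0.106)[seq_len(n)]
  cc <- c(0.05477, 0.05295, 0.04562, 0.06994, 0.05234, 0.05329)[seq_len(n)]
  v <- c(xi_m, 7.518, 0.056, 5.751, 46.9, -3.9, -0.783, cc, 1.601e-3,
         -8.6, 30, 0.28)
  stats::setNames(v, pf_priors("FM", n)$name)
}

#' Synthetic scenario specification
#'
#' Bundles everything a synthetic experiment needs: sizes, the generating
#' truth, the driver-process settings and the seed. Registry:
#' \describe{
#'   \item{tiny}{3 trees x 40 days, one season -- smoke tests.}
#'   \item{recovery}{6 trees x 4 seasons x 150 days -- parameter-recovery
#'     experiments; the water table visits all three conductance regimes
#'     every season.}
#'   \item{waterlogged}{6 trees x 2 seasons with the water table mostly
#'     shallow -- reference-model comparison under hypoxia.}
#'   \item{regime_sweep}{6 trees, one season sweeping the water table
#'     linearly from the surface to 150 cm -- curve diagnostics.}
#' }
#'
#' @param name Registry name.
#' @param seed Integer seed (mandatory; drives all randomness).
#' @param ... Overrides of any spec field.
#' @return list of class `pf_scenario`.
#' @export
pf_scenario <- function(name = c("tiny", "recovery", "waterlogged",
                                 "regime_sweep"),
                        seed = 42, ...) {
  if (!is.character(name) || !(name[1] %in% c("tiny", "recovery",
                                              "waterlogged",
                                              "regime_sweep"))) {
    stop("unknown scenario '", name[1],
         "'; registry: tiny, recovery, waterlogged, regime_sweep")
  }
  name <- match.arg(name)
  base <- list(
    name = name, seed = seed,
    temp_mean = 8, temp_amp = 9,
    hr_base = 0.75,
    I_base = 0.6e-3, I_amp = 1.0e-3, cloud_shape = c(5, 1.5),
    ar_phi = list(T = 0.6, hr = 0.5, wtd = 0.8),
    noise_sd = list(T = 1.5, hr = 0.08, wtd = 3),
    wtd_levels = c(10, 47, 100), wtd_path = "regimes",
    first_year = 2008
  )
  spec <- switch(name,
    tiny = c(base, list(n_trees = 3, n_seasons = 1, days_per_season = 40)),
    recovery = c(base, list(n_trees = 6, n_seasons = 4,
                            days_per_season = 150)),
    waterlogged = {
      b <- base; b$wtd_levels <- c(8, 25, 47, 110)
      c(b, list(n_trees = 6, n_seasons = 2, days_per_season = 150))
    },
    regime_sweep = {
      b <- base; b$wtd_path <- "sweep"
      c(b, list(n_trees = 6, n_seasons = 1, days_per_season = 150))
    })
  spec$truth <- pf_true_params(spec$n_trees)
  dots <- list(...)
  spec[names(dots)] <- dots
  structure(spec, class = "pf_scenario")
}

# Deterministic water-table target path for one season: hold each
# scheduled level over 70% of its segment, ramp linearly to the next.
.wtd_target <- function(levels, n) {
  k <- length(levels)
  xs <- ys <- numeric(0)
  for (j in seq_len(k)) {
    xs <- c(xs, (j - 1) / k, (j - 1) / k + 0.7 / k)
    ys <- c(ys, levels[j], levels[j])
  }
  stats::approx(xs, ys, xout = seq(0, 1, length.out = n), rule = 2)$y
}

#' Generate daily driver series for a scenario
#'
#' Temperature is a seasonal sinusoid plus AR(1) noise; relative humidity
#' an AR(1) fluctuation around its base, clamped to \[0.3, 1\]; irradiance
#' a clear-sky seasonal envelope thinned by beta-distributed cloudiness;
#' the water table follows the scheduled regime path (or a linear sweep)
#' with AR(1) jitter, clamped at the surface. Vapour deficit and leaf
#' temperature are derived with the driver operations, so generated
#' tables satisfy the same invariants as reduced field data.
#'
#' @param spec A [pf_scenario()].
#' @return data.frame `date, D, I, T, T_l, delta`, one row per day,
#'   seasons in successive years starting May 1.
#' @export
generate_drivers <- function(spec) {
  set.seed(spec$seed)
  L <- spec$days_per_season
  out <- lapply(seq_len(spec$n_seasons), function(season) {
    s <- seq_len(L)
    env <- sin(pi * (s - 0.5) / L)
    T <- spec$temp_mean + spec$temp_amp * env +
      .ar1(L, spec$ar_phi$T, spec$noise_sd$T)
    h_r <- pmin(pmax(spec$hr_base + .ar1(L, spec$ar_phi$hr,
                                         spec$noise_sd$hr), 0.3), 1)
    I <- (spec$I_base + spec$I_amp * env) *
      stats::rbeta(L, spec$cloud_shape[1], spec$cloud_shape[2])
    delta <- if (spec$wtd_path == "sweep") {
      seq(0, 150, length.out = L)
    } else {
      pmax(.wtd_target(spec$wtd_levels, L) +
             .ar1(L, spec$ar_phi$wtd, spec$noise_sd$wtd), 0)
    }
    data.frame(
      date = seq(as.Date(sprintf("%d-05-01", spec$first_year + season - 1)),
                 by = "day", length.out = L),
      D = vpd_molar(vpd(T, h_r), T), I = I, T = T,
      T_l = leaf_temperature(T, I), delta = delta
    )
  })
  do.call(rbind, out)
}

#' Generate per-tree observations from the forward model plus noise
#'
#' Simulates the full model at the true parameter vector over the drivers
#' and adds Gaussian noise with the heteroscedastic group structure
#' (log-linear SD for `W1` trees, proportional SD for `W2`). Negative
#' draws are clamped at 0; the clamp rate is attached as an attribute.
#'
#' @param drivers Driver table (see [generate_drivers()]).
#' @param truth Flat true parameter vector ([pf_true_params()] layout).
#' @param trees Tree table (default [pf_trees()] rows for the truth size).
#' @param seed Integer seed for the noise.
#' @param config [pf_config()].
#' @return data.frame `date, tree_id, E_obs, J` with attributes
#'   `clamp_rate` and `truth`.
#' @export
generate_observations <- function(drivers, truth, trees = NULL, seed = 43,
                                  config = pf_config()) {
  n_trees <- sum(grepl("^xi_m", names(truth)))
  if (is.null(trees)) trees <- pf_trees(n_trees)
  priors <- pf_priors("FM", n_trees)
  stopifnot(in_prior_box(truth, priors))
  set.seed(seed)
  p <- decode_params(truth, priors)
  pre <- .pf_prepare(drivers, trees, config)
  E <- .pf_sim_core(pre, p)$E
  sd <- .pf_sd(E, p$alpha, p$beta_w1, p$beta_w2, trees$group,
               config$error$sd_floor)
  E_obs <- E + stats::rnorm(length(E), 0, sd)
  clamp_rate <- mean(E_obs < 0)
  E_obs <- pmax(E_obs, 0)
  out <- data.frame(date = rep(pre$date, pre$m),
                    tree_id = rep(pre$tree_id, each = pre$n),
                    E_obs = as.vector(E_obs),
                    J = as.vector(E_obs) * config$tree$rho)
  attr(out, "clamp_rate") <- clamp_rate
  attr(out, "truth") <- truth
  out
}

# Water temperature in the WTD tubes: a lagged seasonal curve with noise,
# independent of the model residuals.
.generate_wtt <- function(dates, seed) {
  set.seed(seed)
  doy <- as.integer(format(dates, "%j"))
  pmax(6 + 7 * sin(pi * (doy - 140) / 170) + stats::rnorm(length(doy), 0, 1.2),
       0)
}

#' Write a bundled synthetic scenario to disk
#'
#' Materializes a registry scenario as the standard CSV set:
#' `daily_drivers.csv`, `daily_E_obs.csv`, `wtt.csv`, `trees.csv` and the
#' generating truth `truth.yaml` (flat key: value).
#'
#' @param name Registry name, see [pf_scenario()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the list of written paths.
#' @export
make_fixture <- function(name, dir, seed = 42) {
  spec <- pf_scenario(name, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drv <- generate_drivers(spec)
  trees <- pf_trees(spec$n_trees)
  obs <- generate_observations(drv, spec$truth, trees, seed = seed + 1)
  wtt <- data.frame(date = drv$date, wtt = .generate_wtt(drv$date, seed + 2))
  paths <- file.path(dir, c("daily_drivers.csv", "daily_E_obs.csv",
                            "wtt.csv", "trees.csv", "truth.yaml"))
  write_drivers(drv, paths[1])
  write_observations(obs[, c("date", "tree_id", "E_obs", "J")], paths[2])
  .write_num_csv(wtt, paths[3])
  .write_num_csv(trees, paths[4])
  writeLines(c(sprintf("scenario: %s", name),
               sprintf("seed: %d", as.integer(seed)),
               sprintf("clamp_rate: %.6g", attr(obs, "clamp_rate")),
               sprintf("%s: %.17g", names(spec$truth), spec$truth)),
             paths[5])
  invisible(paths)
}
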