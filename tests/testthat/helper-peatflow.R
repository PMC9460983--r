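# Shared small fixtures, built in code.

# Memoized tiny scenario (3 trees x 40 days) used across test files.
.tiny_env <- new.env()
tiny_data <- function() {
  if (is.null(.tiny_env$dat)) {
    spec <- pf_scenario("tiny", seed = 42)
    drv <- generate_drivers(spec)
    trees <- pf_trees(spec$n_trees)
    obs <- generate_observations(drv, spec$truth, trees, seed = 43)
    .tiny_env$dat <- list(spec = spec, drivers = drv, trees = trees,
                          obs = obs)
  }
  .tiny_env$dat
}

# Drivers with a fixed water table depth for every day.
flat_delta_drivers <- function(delta, n_days = 30, seed = 1) {
  spec <- pf_scenario("tiny", seed = seed)
  spec$days_per_season <- n_days
  drv <- generate_drivers(spec)
  drv$delta <- delta
  drv
}

# A decoded full-model parameter list at the reference truth.
truth_decoded <- function(n_trees = 6) {
  decode_params(pf_true_params(n_trees), pf_priors("FM", n_trees))
}

# Observation matrix (day x tree) aligned on driver dates.
.obs_mat_for_test <- function(dat) {
  M <- matrix(NA_real_, nrow(dat$drivers), nrow(dat$trees))
  for (j in seq_len(nrow(dat$trees))) {
    o <- dat$obs[dat$obs$tree_id == dat$trees$tree_id[j], ]
    M[match(o$date, dat$drivers$date), j] <- o$E_obs
  }
  M
}
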