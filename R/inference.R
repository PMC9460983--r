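# Bayesian calibration: heteroscedastic Gaussian likelihood, flat priors
# on closed boxes, a differential-evolution MCMC sampler with snooker
# updates and a past-state archive, convergence diagnostics, MAP
# extraction and posterior predictive intervals.

#' Residuals between observed and modelled transpiration
#'
#' Elementwise `E_obs - E_model`. Observations originate as sap flow
#' density divided by the leaf-to-sapwood area ratio.
#'
#' @param E_obs,E_model Aligned numeric vectors or matrices
#'   (mol H2O m^-2 leaf s^-1).
#' @export
pf_residuals <- function(E_obs, E_model) {
  stopifnot(length(E_obs) == length(E_model))
  E_obs - E_model
}

# Per-tree-day SD of the error model. E_model is a (day x tree) matrix,
# groups a character vector over trees ("W1" exponential / "W2"
# proportional). The floor keeps the density proper as E_model -> 0.
.pf_sd <- function(E_model, alpha, beta_w1, beta_w2, groups,
                   sd_floor = 1e-8) {
  sd <- matrix(NA_real_, nrow(E_model), ncol(E_model))
  w1 <- groups == "W1"
  if (any(w1)) sd[, w1] <- exp(alpha + beta_w1 * E_model[, w1, drop = FALSE])
  if (any(!w1)) sd[, !w1] <- beta_w2 * E_model[, !w1, drop = FALSE]
  pmax(sd, sd_floor)
}

#' Heteroscedastic log-likelihood of the transpiration errors
#'
#' Independent Gaussian errors with a standard deviation tied to the
#' modelled transpiration: log-linear for the `W1` trees,
#' \eqn{SD = \exp(\alpha + \beta_{W1} E^{(M)})}, and proportional with no
#' intercept for the `W2` trees, \eqn{SD = \beta_{W2} E^{(M)}}. The second
#' argument of the normal is a standard deviation, not a variance. Missing
#' observations (`NA` residuals) are excluded.
#'
#' @param eps Residual matrix (day x tree), `NA` where unobserved.
#' @param E_model Modelled transpiration matrix, same shape.
#' @param error_params list with `alpha`, `beta_w1`, `beta_w2`.
#' @param groups Character vector over trees, `"W1"` or `"W2"`.
#' @param sd_floor Lower bound on the SD (mol m^-2 s^-1).
#' @return Scalar log-likelihood.
#' @export
pf_loglik <- function(eps, E_model, error_params, groups, sd_floor = 1e-8) {
  eps <- as.matrix(eps); E_model <- as.matrix(E_model)
  stopifnot(all(dim(eps) == dim(E_model)), ncol(eps) == length(groups))
  sd <- .pf_sd(E_model, error_params$alpha, error_params$beta_w1,
               error_params$beta_w2, groups, sd_floor)
  ok <- is.finite(eps)
  sum(stats::dnorm(eps[ok], 0, sd[ok], log = TRUE))
}

#' Build the log-posterior function of a calibration problem
#'
#' Returns `function(v)` over the flat parameter vector: `-Inf` outside
#' the (closed) prior box, and the data log-likelihood plus a constant
#' inside, since the priors are flat. Days with missing observations for
#' a tree are excluded from that tree's likelihood.
#'
#' @param drivers Daily driver table.
#' @param obs Observation table `date, tree_id, E_obs` (long).
#' @param trees Tree table `tree_id, J_max, group`.
#' @param priors [pf_priors()] table (fixes the variant).
#' @param config [pf_config()].
#' @return A function `v -> log posterior` with the prepared data in its
#'   environment.
#' @export
pf_log_posterior <- function(drivers, obs, trees, priors,
                             config = pf_config()) {
  pre <- .pf_prepare(drivers, trees, config)
  E_obs <- .obs_matrix(obs, drivers$date, trees$tree_id)
  groups <- trees$group
  lo <- priors$lower; hi <- priors$upper
  sd_floor <- config$error$sd_floor
  function(v) {
    if (length(v) != length(lo) || any(!is.finite(v)) ||
        any(v < lo | v > hi)) {
      return(-Inf)
    }
    p <- decode_params(v, priors)
    E <- .pf_sim_core(pre, p)$E
    pf_loglik(E_obs - E, E, p, groups, sd_floor)
  }
}

# Long observation table -> (day x tree) matrix aligned on the driver dates.
.obs_matrix <- function(obs, dates, tree_ids) {
  M <- matrix(NA_real_, length(dates), length(tree_ids),
              dimnames = list(NULL, tree_ids))
  i <- match(as.Date(obs$date), as.Date(dates))
  j <- match(as.character(obs$tree_id), as.character(tree_ids))
  keep <- !is.na(i) & !is.na(j)
  M[cbind(i[keep], j[keep])] <- obs$E_obs[keep]
  M
}

#' Differential-evolution MCMC with snooker updates and a state archive
#'
#' A DREAM(ZS)-style sampler: a small number of parallel chains propose
#' jumps along difference vectors of states drawn from an archive of past
#' states (updated every `archive_every` generations), with occasional
#' snooker updates along the chain-to-anchor direction and occasional
#' full-length (`gamma = 1`) jumps for mode switching. Proposals outside
#' the prior box are rejected by the posterior itself. Fully reproducible
#' given `seed`.
#'
#' @param log_post Function `v -> log posterior` (may return `-Inf`).
#' @param priors [pf_priors()] table; initial states and the archive are
#'   drawn uniformly from the box.
#' @param n_iter Generations per chain.
#' @param n_chains Number of parallel chains (>= 3).
#' @param seed Integer seed.
#' @param archive_size Initial archive rows (default `10 * d`).
#' @param archive_every Generations between archive appends.
#' @param p_snooker,p_gamma1 Probabilities of a snooker update and of a
#'   unit-gamma jump.
#' @param jitter SD of the small Gaussian proposal jitter.
#' @param init Optional matrix (`n_chains` x d) of starting states.
#' @param init_archive Optional matrix (rows x d) seeding the archive,
#'   e.g. draws from a Laplace approximation around a posterior mode;
#'   rows are clipped into the prior box. Defaults to uniform box draws.
#' @return list of class `pf_chain`: `draws` (iter x chain x parameter
#'   array), `lp` (iter x chain), `accept_rate`, `settings`.
#' @export
demc_zs <- function(log_post, priors, n_iter = 5000, n_chains = 3,
                    seed = 1, archive_size = NULL, archive_every = 10,
                    p_snooker = 0.1, p_gamma1 = 0.1, jitter = 1e-12,
                    init = NULL, init_archive = NULL) {
  stopifnot(n_chains >= 3, n_iter >= 2)
  set.seed(seed)
  d <- nrow(priors)
  lo <- priors$lower; hi <- priors$upper; span <- hi - lo
  if (is.null(archive_size)) archive_size <- max(10 * d, 5 * n_chains)
  rbox <- function(k) {
    matrix(stats::runif(k * d), k, d) * rep(span, each = k) +
      rep(lo, each = k)
  }
  clip <- function(M) {
    pmin(pmax(M, rep(lo, each = nrow(M))), rep(hi, each = nrow(M)))
  }
  Z <- if (is.null(init_archive)) rbox(archive_size) else clip(init_archive)
  X <- if (is.null(init)) {
    if (is.null(init_archive)) rbox(n_chains) else
      Z[sample.int(nrow(Z), n_chains), , drop = FALSE]
  } else {
    init
  }
  lpX <- apply(X, 1, log_post)
  # replace any -Inf start by fresh draws (flat prior: finite inside box)
  for (i in which(!is.finite(lpX))) {
    for (k in 1:100) {
      X[i, ] <- rbox(1)
      lpX[i] <- log_post(X[i, ])
      if (is.finite(lpX[i])) break
    }
  }
  gamma_d <- 2.38 / sqrt(2 * d)
  draws <- array(NA_real_, c(n_iter, n_chains, d),
                 dimnames = list(NULL, NULL, priors$name))
  lp <- matrix(NA_real_, n_iter, n_chains)
  n_acc <- 0L; n_prop <- 0L; acc_window <- 0L
  for (t in seq_len(n_iter)) {
    nz <- nrow(Z)
    for (i in seq_len(n_chains)) {
      x <- X[i, ]
      corr <- 0
      if (stats::runif(1) < p_snooker) {
        idx <- sample.int(nz, 3L)
        z <- Z[idx[1L], ]
        dx <- x - z
        nrm2 <- sum(dx * dx)
        if (nrm2 == 0) {
          xp <- x + stats::rnorm(d, 0, jitter)
        } else {
          proj <- sum((Z[idx[2L], ] - Z[idx[3L], ]) * dx) / nrm2
          xp <- x + stats::runif(1, 1.2, 2.2) * proj * dx
          corr <- (d - 1) * (log(sqrt(sum((xp - z)^2))) - log(sqrt(nrm2)))
        }
      } else {
        g <- if (stats::runif(1) < p_gamma1) 1 else gamma_d
        idx <- sample.int(nz, 2L)
        xp <- x + g * (Z[idx[1L], ] - Z[idx[2L], ]) +
          stats::rnorm(d, 0, jitter)
      }
      lp_p <- log_post(xp)
      n_prop <- n_prop + 1L
      if (is.finite(lp_p) &&
          log(stats::runif(1)) < lp_p - lpX[i] + corr) {
        X[i, ] <- xp
        lpX[i] <- lp_p
        n_acc <- n_acc + 1L
        acc_window <- acc_window + 1L
      }
    }
    draws[t, , ] <- X
    lp[t, ] <- lpX
    if (t %% archive_every == 0L) Z <- rbind(Z, X)
    if (t %% 2000L == 0L) {
      if (acc_window < 0.01 * 2000L * n_chains) {
        stop("sampler stagnated: acceptance < 1% over the last 2000 ",
             "generations (log-posterior around ",
             signif(max(lpX), 6), ")")
      }
      acc_window <- 0L
    }
  }
  structure(list(draws = draws, lp = lp,
                 accept_rate = n_acc / n_prop,
                 settings = list(n_iter = n_iter, n_chains = n_chains,
                                 seed = seed,
                                 archive_every = archive_every,
                                 p_snooker = p_snooker,
                                 p_gamma1 = p_gamma1)),
            class = "pf_chain")
}

# Posterior mode by multi-start box-constrained quasi-Newton, and a
# Laplace (normal) approximation around it, used to seed the sampler's
# archive at the right location and scale. The chains still sample the
# exact posterior; the approximation only accelerates adaptation.
.pf_laplace_archive <- function(log_post, priors, size, seed,
                                n_prior = 200, n_opt = 2) {
  set.seed(seed)
  d <- nrow(priors)
  lo <- priors$lower; hi <- priors$upper; span <- hi - lo
  fn <- function(v) log_post(pmin(pmax(v, lo), hi))
  cand <- matrix(stats::runif(n_prior * d), n_prior, d) *
    rep(span, each = n_prior) + rep(lo, each = n_prior)
  lps <- apply(cand, 1, fn)
  starts <- cand[order(lps, decreasing = TRUE)[seq_len(n_opt)], ,
                 drop = FALSE]
  best <- NULL; best_lp <- -Inf
  for (i in seq_len(nrow(starts))) {
    op <- try(stats::optim(starts[i, ], fn, method = "L-BFGS-B",
                           lower = lo, upper = hi,
                           control = list(fnscale = -1, maxit = 300,
                                          parscale = span / 10)),
              silent = TRUE)
    if (!inherits(op, "try-error") && op$value > best_lp) {
      best <- op$par; best_lp <- op$value
    }
  }
  if (is.null(best)) return(NULL)
  H <- try(stats::optimHess(best, fn,
                            control = list(fnscale = -1,
                                           parscale = span / 10)),
           silent = TRUE)
  L <- NULL
  if (!inherits(H, "try-error")) {
    Sigma <- try(solve(-(H + t(H)) / 2), silent = TRUE)
    if (!inherits(Sigma, "try-error")) {
      L <- try(chol(Sigma), silent = TRUE)
      if (inherits(L, "try-error")) L <- NULL
    }
  }
  draws <- if (is.null(L)) {
    rep(best, each = size) +
      matrix(stats::rnorm(size * d, 0, 1), size, d) *
        rep(span * 1e-3, each = size)
  } else {
    rep(best, each = size) + matrix(stats::rnorm(size * d), size, d) %*% L
  }
  list(archive = draws, mode = best, lp_mode = best_lp)
}

# Second halves of the chains ("without burn-in"): all diagnostics and
# summaries are computed on these.
.retained <- function(chain) {
  n <- dim(chain$draws)[1L]
  keep <- seq.int(floor(n / 2) + 1L, n)
  list(draws = chain$draws[keep, , , drop = FALSE],
       lp = chain$lp[keep, , drop = FALSE])
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per parameter from the
#' between-/within-chain variance decomposition:
#' \eqn{\hat R = \sqrt{((n-1)/n\, W + B/n) / W}} with `W` the mean
#' within-chain variance and `B/n` the variance of the chain means.
#' Degenerate chains with zero within-variance report 1.
#'
#' @param draws Array (iteration x chain x parameter) of retained draws,
#'   with at least 2 chains of equal length.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(draws) {
  stopifnot(length(dim(draws)) == 3, dim(draws)[2L] >= 2)
  n <- dim(draws)[1L]
  vapply(seq_len(dim(draws)[3L]), function(k) {
    ch <- draws[, , k, drop = FALSE][, , 1L]
    W <- mean(apply(ch, 2, stats::var))
    if (!is.finite(W) || W <= 0) return(1)
    B_over_n <- stats::var(colMeans(ch))
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1)) |> stats::setNames(dimnames(draws)[[3L]])
}

#' Maximum a posteriori draw of a chain
#'
#' The retained draw with the highest log-posterior; ties broken by first
#' occurrence (iteration-major order).
#'
#' @param chain A `pf_chain` (see [demc_zs()]) or a list with `draws` and
#'   `lp` of matching retained shapes.
#' @param retained_only Use only the second halves (the default, matching
#'   every other summary).
#' @return Named parameter vector with attribute `log_posterior`.
#' @export
map_estimate <- function(chain, retained_only = TRUE) {
  part <- if (retained_only) .retained(chain) else chain
  stopifnot(length(part$lp) >= 1)
  best <- arrayInd(which.max(part$lp), dim(part$lp))
  v <- part$draws[best[1L], best[2L], ]
  attr(v, "log_posterior") <- part$lp[best[1L], best[2L]]
  v
}

#' Posterior predictive interval bands
#'
#' For each of `n_samples` parameter vectors drawn (with replacement) from
#' the retained posterior, simulates the model and adds observation noise
#' from the heteroscedastic error model; the band is the pointwise
#' 2.5%/97.5% quantile envelope per tree-day.
#'
#' @param fit A [pf_fit()] object, or a retained draw matrix via `draws`.
#' @param drivers Driver table to predict on (default: the fitted one).
#' @param n_samples Number of posterior draws (default 6000).
#' @param seed Seed for draw selection and noise.
#' @param level Interval probability (default 0.95).
#' @return data.frame `date, tree_id, lower, upper, E_map`.
#' @export
predictive_interval <- function(fit, drivers = NULL, n_samples = 6000,
                                seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "pf_fit"))
  if (is.null(drivers)) drivers <- fit$drivers
  set.seed(seed)
  pre <- .pf_prepare(drivers, fit$trees, fit$config)
  groups <- fit$trees$group
  R <- fit$retained
  idx <- sample.int(nrow(R), n_samples, replace = TRUE)
  nm <- pre$n * pre$m
  sims <- matrix(NA_real_, n_samples, nm)
  for (s in seq_len(n_samples)) {
    p <- decode_params(R[idx[s], ], fit$priors)
    E <- .pf_sim_core(pre, p)$E
    sd <- .pf_sd(E, p$alpha, p$beta_w1, p$beta_w2, groups,
                 fit$config$error$sd_floor)
    sims[s, ] <- E + stats::rnorm(nm, 0, sd)
  }
  a <- (1 - level) / 2
  qs <- apply(sims, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  E_map <- .pf_sim_core(pre, decode_params(fit$map, fit$priors))$E
  data.frame(date = rep(pre$date, pre$m),
             tree_id = rep(pre$tree_id, each = pre$n),
             lower = matrix(qs[1L, ], pre$n, pre$m) |> as.vector(),
             upper = matrix(qs[2L, ], pre$n, pre$m) |> as.vector(),
             E_map = as.vector(E_map))
}

#' Calibrate a transpiration model by MCMC
#'
#' The package's main fitting function: builds the heteroscedastic
#' log-posterior for the chosen model variant, samples it with
#' [demc_zs()], retains the second halves of the chains, and summarizes
#' them (MAP, central 95% credible intervals, Gelman-Rubin R-hat per
#' parameter). A fit is flagged (with a warning) rather than rejected
#' when any R-hat is at or above `rhat_threshold`.
#'
#' @param drivers Daily driver table `date, D, I, T, T_l, delta`.
#' @param obs Observations `date, tree_id, E_obs` (long); missing
#'   tree-days are simply absent rows.
#' @param trees Tree table `tree_id, J_max, group`; by default derived
#'   from `obs` (`J_max = rho * max(E_obs)` per tree, groups `W1` for
#'   tree ids 4 and 6, `W2` otherwise).
#' @param variant `"FM"`, `"RM1"` or `"RM2"`.
#' @param n_iter,n_chains,seed Sampler budget and seed (see [demc_zs()]).
#' @param config [pf_config()].
#' @param priors Prior table; defaults to [pf_priors()] for the variant.
#' @param rhat_threshold Convergence criterion (default 1.1).
#' @param init `"laplace"` (default) seeds the sampler archive from a
#'   normal approximation around a posterior mode found by multi-start
#'   box-constrained optimization, which greatly shortens the adaptation
#'   phase; `"prior"` seeds it uniformly from the prior box.
#' @param ... Passed on to [demc_zs()].
#' @return An object of class `pf_fit`; see [summary.pf_fit()],
#'   [coef.pf_fit()], [predict.pf_fit()], [simulate.pf_fit()].
#' @export
pf_fit <- function(drivers, obs, trees = NULL,
                   variant = c("FM", "RM1", "RM2"),
                   n_iter = 5000, n_chains = 3, seed = 1,
                   config = pf_config(), priors = NULL,
                   rhat_threshold = 1.1, init = c("laplace", "prior"),
                   ...) {
  variant <- match.arg(variant)
  init <- match.arg(init)
  if (is.null(trees)) {
    ids <- sort(unique(as.character(obs$tree_id)))
    trees <- data.frame(
      tree_id = ids,
      J_max = vapply(ids, function(id) {
        config$tree$rho * max(obs$E_obs[obs$tree_id == id], na.rm = TRUE)
      }, numeric(1)),
      group = ifelse(ids %in% c("4", "6"), "W1", "W2"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(priors)) priors <- pf_priors(variant, nrow(trees))
  stopifnot(attr(priors, "variant") == variant,
            attr(priors, "n_trees") == nrow(trees))
  log_post <- pf_log_posterior(drivers, obs, trees, priors, config)
  init_archive <- NULL
  if (init == "laplace") {
    lap <- .pf_laplace_archive(log_post, priors,
                               size = max(10 * nrow(priors), 5 * n_chains),
                               seed = seed)
    if (!is.null(lap)) init_archive <- lap$archive
  }
  chain <- demc_zs(log_post, priors, n_iter = n_iter,
                   n_chains = n_chains, seed = seed,
                   init_archive = init_archive, ...)
  ret <- .retained(chain)
  d <- nrow(priors)
  retained <- matrix(aperm(ret$draws, c(1, 2, 3)), ncol = d,
                     dimnames = list(NULL, priors$name))
  rhat <- gelman_rubin(ret$draws)
  map <- map_estimate(chain)
  ci <- t(apply(retained, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  colnames(ci) <- c("q2.5", "q97.5")
  converged <- all(rhat < rhat_threshold)
  if (!converged) {
    warning("convergence flag: max R-hat = ", round(max(rhat), 3),
            " >= ", rhat_threshold, call. = FALSE)
  }
  structure(list(call = match.call(), variant = variant,
                 drivers = drivers, obs = obs, trees = trees,
                 priors = priors, config = config,
                 chain = chain, retained = retained,
                 lp_retained = as.vector(ret$lp),
                 map = map, rhat = rhat, ci = ci,
                 accept_rate = chain$accept_rate,
                 converged = converged, seed = seed),
            class = "pf_fit")
}
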