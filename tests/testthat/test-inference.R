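test_that("residuals are elementwise observation minus model", {
  expect_equal(pf_residuals(c(1, 2, 3), c(1, 1, 1)), c(0, 1, 2))
  # sap flow converts to leaf-area flux before differencing
  expect_equal(2.116 / 2500, 8.464e-4)
  M <- matrix(1:6, 2); expect_equal(pf_residuals(M + 0.5, M),
                                    matrix(0.5, 2, 3))
})

test_that("heteroscedastic log-likelihood matches a brute-force summation", {
  set.seed(5)
  E <- matrix(abs(rnorm(12, 3e-4, 1e-4)), 4, 3)
  eps <- matrix(rnorm(12, 0, 1e-4), 4, 3)
  eps[2, 3] <- NA                                   # one masked day
  groups <- c("W1", "W2", "W2")
  ep <- list(alpha = -8.5, beta_w1 = 25, beta_w2 = 0.3)

  # independent oracle: explicit double loop over trees and days
  oracle <- 0
  for (j in 1:3) {
    for (i in 1:4) {
      if (!is.finite(eps[i, j])) next
      s <- if (groups[j] == "W1") exp(ep$alpha + ep$beta_w1 * E[i, j])
           else ep$beta_w2 * E[i, j]
      s <- max(s, 1e-8)
      oracle <- oracle + dnorm(eps[i, j], 0, s, log = TRUE)
    }
  }
  ll <- pf_loglik(eps, E, ep, groups)
  expect_equal(ll, oracle, tolerance = 1e-12)

  # a single proportional-error point at the mode
  s <- 0.3 * 2e-4
  expect_equal(pf_loglik(matrix(0), matrix(2e-4), ep, "W2"),
               -log(s * sqrt(2 * pi)), tolerance = 1e-12)
  # independence: duplicating a point doubles the log-likelihood
  expect_equal(pf_loglik(matrix(c(0, 0)), matrix(c(2e-4, 2e-4)), ep, "W2"),
               2 * pf_loglik(matrix(0), matrix(2e-4), ep, "W2"))
})

test_that("flat priors: posterior is likelihood inside the box, -Inf outside", {
  dat <- tiny_data()
  pri <- pf_priors("FM", 3)
  lp <- pf_log_posterior(dat$drivers, dat$obs, dat$trees, pri)
  mid <- (pri$lower + pri$upper) / 2
  expect_true(is.finite(lp(mid)))
  expect_true(is.finite(lp(pri$lower)))        # closed boxes
  expect_true(is.finite(lp(pri$upper)))
  out <- mid; out[4] <- pri$upper[4] * 1.01
  expect_identical(lp(out), -Inf)
  expect_identical(lp(mid[-1]), -Inf)          # wrong length

  # posterior differences equal likelihood differences (flat prior)
  v2 <- mid; v2[pri$name == "z0"] <- mid[pri$name == "z0"] + 0.1
  ll <- function(v) {
    p <- decode_params(v, pri)
    E <- matrix(pf_simulate(dat$drivers, p, dat$trees)$E_model,
                ncol = 3)
    obs <- matrix(NA_real_, nrow(dat$drivers), 3)
    for (j in 1:3) {
      o <- dat$obs[dat$obs$tree_id == dat$trees$tree_id[j], ]
      obs[match(o$date, dat$drivers$date), j] <- o$E_obs
    }
    pf_loglik(obs - E, E, p, dat$trees$group)
  }
  expect_equal(lp(mid) - lp(v2), ll(mid) - ll(v2), tolerance = 1e-9)
})

test_that("the DE sampler recovers a known bivariate Gaussian", {
  mu <- c(0.3, -0.2); sds <- c(0.1, 0.2); rho <- 0.5
  Sig <- diag(sds) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sds)
  Pinv <- solve(Sig)
  lp <- function(v) {
    if (any(v < -2 | v > 2)) return(-Inf)
    -0.5 * drop(t(v - mu) %*% Pinv %*% (v - mu))
  }
  pri <- pf_priors("FM", 6)[1:2, ]  # borrow structure, override the box
  pri$lower <- c(-2, -2); pri$upper <- c(2, 2); pri$name <- c("a", "b")
  ch <- demc_zs(lp, pri, n_iter = 4000, n_chains = 3, seed = 31)
  keep <- 2001:4000
  draws <- matrix(ch$draws[keep, , ], ncol = 2)
  expect_equal(colMeans(draws), mu, tolerance = 0.04)
  expect_equal(apply(draws, 2, sd), sds, tolerance = 0.2)
  expect_equal(cor(draws)[1, 2], rho, tolerance = 0.15)
})

test_that("fixed seed gives identical chains; stagnation guard trips", {
  pri <- pf_priors("FM", 6)[1:2, ]
  pri$lower <- c(-2, -2); pri$upper <- c(2, 2); pri$name <- c("a", "b")
  lp <- function(v) if (any(abs(v) > 2)) -Inf else -sum(v^2)
  c1 <- demc_zs(lp, pri, n_iter = 300, seed = 8)
  c2 <- demc_zs(lp, pri, n_iter = 300, seed = 8)
  expect_identical(c1$draws, c2$draws)
  expect_identical(c1$lp, c2$lp)

  # a needle target no proposal can hit stalls every chain
  # (archive updates disabled so proposals stay prior-scale)
  lp_needle <- function(v) if (sum((v - 0.5)^2) < 1e-20) 0 else -1e10
  init <- matrix(0.5, 3, 2)
  expect_error(demc_zs(lp_needle, pri, n_iter = 2500, seed = 8,
                       init = init, archive_every = 1e6),
               "stagnated")
})

test_that("R-hat separates mixed chains from disjoint chains", {
  set.seed(12)
  n <- 500
  same <- array(rnorm(n * 3 * 2), c(n, 3, 2))
  rh <- gelman_rubin(same)
  expect_true(all(abs(rh - 1) < 0.05))

  split <- array(rnorm(n * 3 * 1, mean = rep(c(0, 0, 8), each = n)),
                 c(n, 3, 1))
  expect_gt(gelman_rubin(split)[1], 1.5)

  flat <- array(5, c(10, 3, 1))           # zero within-variance guard
  expect_equal(unname(gelman_rubin(flat)[1]), 1)
})

test_that("MAP extraction respects the retained-half bookkeeping", {
  d <- 2; n <- 100
  draws <- array(rnorm(n * 2 * d), c(n, 2, d))
  lp <- matrix(rnorm(n * 2, -10), n, 2)
  # plant the global best in the first (discarded) half and a second-best
  # in the retained half
  lp[10, 1] <- 5; draws[10, 1, ] <- c(111, 111)
  lp[80, 2] <- 2; draws[80, 2, ] <- c(7, 8)
  chain <- list(draws = draws, lp = lp)
  m <- map_estimate(chain)
  expect_equal(as.numeric(m), c(7, 8))
  expect_equal(attr(m, "log_posterior"), 2)
  # single retained draw is returned as-is
  one <- list(draws = array(c(1, 2), c(1, 1, 2)), lp = matrix(0))
  expect_equal(as.numeric(map_estimate(one, retained_only = FALSE)),
               c(1, 2))
})

# Minimal fitted object for predictive-interval unit tests.
.fake_fit <- function(truth, dat, alpha = -15, beta_w1 = 0, beta_w2 = 0) {
  pri <- pf_priors("FM", 3)
  v <- truth
  v[pri$name == "alpha"] <- alpha
  v[pri$name == "beta_w1"] <- beta_w1
  v[pri$name == "beta_w2"] <- beta_w2
  structure(list(variant = "FM", drivers = dat$drivers, obs = dat$obs,
                 trees = dat$trees, priors = pri, config = pf_config(),
                 retained = matrix(v, 1, length(v), byrow = TRUE,
                                   dimnames = list(NULL, pri$name)),
                 map = setNames(v, pri$name)),
            class = "pf_fit")
}

test_that("predictive bands collapse without noise and widen with it", {
  dat <- tiny_data()
  truth <- pf_true_params(3)
  f0 <- .fake_fit(truth, dat)              # SD at the floor
  pi0 <- predictive_interval(f0, n_samples = 200, seed = 2)
  expect_lt(max(pi0$upper - pi0$lower), 1e-6)
  expect_equal((pi0$upper + pi0$lower) / 2, pi0$E_map, tolerance = 1e-5)

  f1 <- .fake_fit(truth, dat, beta_w2 = 0.1)
  f2 <- .fake_fit(truth, dat, beta_w2 = 0.3)
  pi1 <- predictive_interval(f1, n_samples = 400, seed = 2)
  pi2 <- predictive_interval(f2, n_samples = 400, seed = 2)
  active <- pi1$E_map > 1e-5
  expect_true(all((pi2$upper - pi2$lower)[active] >
                    (pi1$upper - pi1$lower)[active]))
})
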