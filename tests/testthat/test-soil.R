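soil <- pf_config()$soil

test_that("retention curve endpoints, limits and a frozen midpoint", {
  expect_equal(theta_of_wtd(0, soil), soil$theta_sat)
  # slow power-law tail: approaches the residual content from above
  expect_lt(theta_of_wtd(1e9, soil) - soil$theta_res, 1e-3)
  expect_gt(theta_of_wtd(1e9, soil), soil$theta_res)
  expect_error(theta_of_wtd(-1, soil), ">= 0")
  # strictly decreasing in depth
  grid <- seq(0, 300, by = 0.5)
  expect_true(all(diff(theta_of_wtd(grid, soil)) < 0))
  # independent hand evaluation at the optimal depth
  expect_equal(theta_of_wtd(46.9, soil), 0.5770746970135154,
               tolerance = 1e-12)
})

test_that("rising branch is a power law in relative saturation", {
  p <- soil_root_params(0.1, 8, 0.06, 6, 46.9)
  expect_equal(ksr_plus(soil$theta_sat, p, soil), soil$leaf_conv * 0.1)
  expect_equal(ksr_plus(soil$theta_sat / 2, p, soil),
               soil$leaf_conv * 0.1 * 2^-8)
  th <- seq(0.1, soil$theta_sat, length.out = 200)
  expect_true(all(diff(ksr_plus(th, p, soil)) > 0))
  expect_error(ksr_plus(0, p, soil), "theta")
})

test_that("falling branch: reference point, clamp boundary, monotonicity", {
  p <- soil_root_params(0.1, 8, 0.06, 6, 46.9)
  th_star <- theta_of_wtd(46.9, soil)
  expect_equal(ksr_minus(th_star, p, soil),
               soil$leaf_conv * 0.06 * (th_star / soil$theta_sat)^6)
  expect_warning(v <- ksr_minus(2 * th_star, p, soil), "clamped")
  expect_equal(v, 0)
  for (x in c(0.01, 0.05, 0.1)) {
    expect_lt(ksr_minus(th_star + x, p, soil),
              ksr_minus(th_star - x, p, soil))
  }
  th <- seq(0.3, 0.8, length.out = 100)
  expect_true(all(diff(ksr_minus(th, p, soil)) < 0))
})

test_that("plateau constant is the mean of the two offset branches", {
  p <- soil_root_params(0.11, 7.7, 0.07, 5.3, 40)
  by_hand <- (ksr_plus(theta_of_wtd(50, soil), p, soil) +
                ksr_minus(theta_of_wtd(30, soil), p, soil)) / 2
  expect_equal(ksr_star(p, soil), by_hand, tolerance = 1e-14)
})

test_that("segmented conductance equals the brute-force branch minimum", {
  p <- soil_root_params(0.084, 7.518, 0.056, 5.751, 46.9)
  grid <- seq(0, 200, by = 0.1) # 1-mm steps
  th <- theta_of_wtd(grid, soil)
  oracle <- pmin(ksr_plus(th, p, soil),
                 suppressWarnings(ksr_minus(th, p, soil)),
                 ksr_star(p, soil))
  expect_equal(ksr(grid, p, soil), oracle, tolerance = 1e-12)

  # regime structure: falling branch at the surface, plateau at the
  # optimum, rising branch at depth
  expect_equal(ksr(0, p, soil),
               suppressWarnings(ksr_minus(theta_of_wtd(0, soil), p, soil)))
  expect_equal(ksr(46.9, p, soil), ksr_star(p, soil))
  expect_equal(ksr(180, p, soil),
               ksr_plus(theta_of_wtd(180, soil), p, soil))
})

test_that("conductance is unimodal in depth and constant on the plateau", {
  p <- soil_root_params(0.1, 7.5, 0.056, 5.751, 46.9)
  grid <- seq(0, 200, by = 0.1)
  k <- ksr(grid, p, soil)
  plateau <- which(k == ksr_star(p, soil))
  expect_gt(length(plateau), 10)            # a real plateau, not a point
  expect_true(all(diff(plateau) == 1))      # contiguous
  expect_true(all(diff(k[1:min(plateau)]) >= 0))   # rising toward it
  expect_true(all(diff(k[max(plateau):length(k)]) <= 0)) # falling past it
})

test_that("series composition: harmonic mean below both components", {
  expect_equal(ksl(2e-9, 2e-9), 1e-9)
  expect_equal(ksl(1e6, 4.232e-10), 4.232e-10, tolerance = 1e-6)
  # reference tree: frozen independent harmonic sum
  expect_equal(ksl(3e-9, k_rl(2.116)), 3.7088104697359196e-10,
               tolerance = 1e-12)
  set.seed(3)
  a <- 10^runif(50, -10, -8); b <- 10^runif(50, -10, -8)
  expect_true(all(ksl(a, b) < pmin(a, b)))
  # blocked soil-root path blocks the series
  expect_equal(ksl(0, 4e-10), 0)
})

test_that("water-cost bridge is log-log linear and decreasing", {
  k0 <- soil$k0
  expect_equal(mwue(k0, -3.8, -0.783, k0), 10^-3.8)
  expect_equal(mwue(10 * k0, -3.8, -0.783, k0), 10^(-3.8 - 0.783))
  ks <- 10^seq(-11, -8, length.out = 100)
  expect_true(all(diff(mwue(ks, -3.8, -0.783, k0)) < 0))
  expect_error(mwue(0, -3.8, -0.783, k0), "positive")
})

test_that("water cost is U-shaped in depth with its minimum on the plateau", {
  params <- truth_decoded()
  cv <- pf_curves(params, pf_trees(1), delta = seq(1, 200, by = 0.5))
  i_min <- which.min(cv$lambda)
  # minimum sits where the conductance plateau sits
  expect_equal(cv$ksr[i_min], max(cv$ksr))
  # rises toward the surface and toward depth
  expect_true(all(diff(cv$lambda[1:i_min]) <= 0))
  expect_gt(cv$lambda[nrow(cv)], cv$lambda[i_min])
  expect_gt(cv$lambda[1], cv$lambda[i_min])
})

test_that("decline onset lies between the surface and the optimum", {
  params <- truth_decoded()
  on <- decline_onset(params, pf_trees(6))
  expect_length(on, 6)
  expect_true(all(on > 0 & on < params$delta_star))
  # onset is where the falling branch crosses the plateau value
  p1 <- soil_root_params(params$xi_m[1], params$xi_p, params$eta_m,
                         params$eta_p, params$delta_star)
  expect_equal(ksr_minus(theta_of_wtd(on[[1]], soil), p1, soil),
               ksr_star(p1, soil), tolerance = 1e-7)
})
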