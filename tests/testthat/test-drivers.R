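test_that("sapwood allometry reproduces the reference tree table", {
  # mm-scale values for the smallest and largest monitored trees
  expect_equal(round(sapwood_thickness(129), 2), 32.94)
  expect_equal(round(sapwood_thickness(175), 2), 42.01)
  # cm-scale, as tabulated for all six trees
  dbh_mm <- c(12.9, 16.2, 15.0, 15.7, 13.3, 17.5) * 10
  expect_equal(round(sapwood_thickness(dbh_mm) / 10, 2),
               c(3.29, 3.94, 3.70, 3.84, 3.37, 4.20))
  # intercept limit and domain guard
  expect_equal(sapwood_thickness(1e-9), 9.755, tolerance = 1e-6)
  expect_error(sapwood_thickness(0), "positive")
  expect_error(sapwood_thickness(-5), "positive")
})

test_that("vapour pressure deficit formula and conversions", {
  expect_equal(vpd(15, 1), 0)
  expect_equal(vpd(0, 0), 611)
  # frozen independent evaluation of the Magnus expression
  expect_equal(vpd(20, 0.5), 1168.2397137744122, tolerance = 1e-12)
  expect_error(vpd(20, 1.2), "\\[0, 1\\]")

  expect_equal(vpd_molar(0, 25), 0)
  expect_equal(vpd_molar(8.3145 * 273.15, 0), 1)
  expect_equal(vpd_molar(1168, 20), 0.47919999693935617, tolerance = 1e-12)
})

test_that("vpd is monotone: decreasing in humidity, increasing in T", {
  T <- 15
  hr <- seq(0, 1, by = 0.05)
  expect_true(all(diff(vpd(T, hr)) < 0))
  Ts <- seq(-5, 35, by = 1)
  expect_true(all(diff(vpd(Ts, 0.6)) > 0))
})

test_that("leaf temperature is a linear irradiance offset", {
  expect_equal(leaf_temperature(12, 0), 12)
  expect_equal(leaf_temperature(10, 1.5e-3), 12.25)
  expect_equal(leaf_temperature(20, 1e-3), 21.5)
  expect_error(leaf_temperature(20, -1e-3), "non-negative")
})

test_that("top-decile median matches a brute-force ranking oracle", {
  expect_equal(daily_top_decile_median(1:10), 10)
  expect_equal(daily_top_decile_median(rep(7.5, 13)), 7.5)
  expect_equal(daily_top_decile_median(1:20), 19.5)
  expect_true(is.na(daily_top_decile_median(numeric(0))))

  oracle <- function(x) {
    x <- x[is.finite(x)]
    k <- ceiling(0.1 * length(x))
    median(rev(sort(x))[1:k])
  }
  set.seed(101)
  for (n in c(1, 3, 9, 10, 11, 47, 144)) {
    x <- rnorm(n)
    expect_equal(daily_top_decile_median(x), oracle(x))
    # never below the plain median
    expect_gte(daily_top_decile_median(x), median(x))
  }
})

test_that("WTD anchoring reproduces manual readings and logger shape", {
  tl <- 0:100
  logger <- data.frame(timestamp = tl, delta = 40 + 10 * sin(tl / 8))

  # manual points lying on the logger series leave it unchanged
  manual <- logger[c(11, 51, 91), ]
  out <- interpolate_wtd(manual, logger)
  expect_equal(out$delta, logger$delta)

  # constant logger: anchoring degenerates to linear interpolation a -> b
  flat <- data.frame(timestamp = tl, delta = rep(30, 101))
  man2 <- data.frame(timestamp = c(0, 100), delta = c(20, 60))
  out2 <- interpolate_wtd(man2, flat)
  expect_equal(out2$delta, seq(20, 60, length.out = 101))

  # single manual point: constant offset shift
  man3 <- data.frame(timestamp = 50, delta = logger$delta[51] + 5)
  out3 <- interpolate_wtd(man3, logger)
  expect_equal(out3$delta, logger$delta + 5)

  # exact interpolation property at manual timestamps
  man4 <- data.frame(timestamp = c(10, 60), delta = c(35, 55))
  out4 <- interpolate_wtd(man4, logger)
  expect_equal(out4$delta[out4$timestamp %in% man4$timestamp], man4$delta)

  # standing water clamps at the surface with a warning
  man5 <- data.frame(timestamp = 50, delta = 0)
  expect_warning(out5 <- interpolate_wtd(man5, logger), "clamped")
  expect_true(all(out5$delta >= 0))
})

test_that("sub-daily records reduce to daily drivers, day-complete only", {
  set.seed(7)
  ts <- function(day, hour) sprintf("2008-06-%02dT%02d:00:00", day, hour)
  hours <- 6:18
  met <- do.call(rbind, lapply(1:3, function(d) {
    data.frame(timestamp = ts(d, hours), T = 10 + hours / 2,
               h_r = 0.9 - hours / 40, I = pmax(sin((hours - 6) / 12 * pi), 0) * 1.5e-3)
  }))
  wtd <- data.frame(timestamp = ts(rep(1:3, each = 13), rep(hours, 3)),
                    delta = rep(c(30, 40, 50), each = 13) + runif(39))
  sap <- data.frame(timestamp = rep(met$timestamp, 2),
                    tree_id = rep(c("1", "2"), each = nrow(met)),
                    J = rep(c(1.2, 0.8), each = nrow(met)) *
                      rep(pmax(sin((hours - 6) / 12 * pi), 0.05), 6))
  out <- reduce_daily(met, wtd, sap, rho = 2500)
  expect_equal(nrow(out$drivers), 3)
  expect_named(out$drivers, c("date", "D", "I", "T", "T_l", "delta"))
  # reduction applies per variable: daily T is the top-decile median of T
  expect_equal(out$drivers$T,
               rep(daily_top_decile_median(10 + hours / 2), 3))
  expect_true(all(out$drivers$T_l >= out$drivers$T))
  expect_equal(sort(unique(out$obs$tree_id)), c("1", "2"))
  # sap flow converts to leaf-area flux by rho
  expect_equal(out$obs$E_obs[out$obs$tree_id == "1"],
               daily_top_decile_median(1.2 * pmax(sin((hours - 6) / 12 * pi), 0.05)) / 2500 * c(1, 1, 1))
})

test_that("driver tables round-trip through CSV bit-identically", {
  dat <- tiny_data()
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_drivers(dat$drivers, p1)
  back <- read_drivers(p1)
  expect_identical(back$D, dat$drivers$D)
  expect_identical(back$delta, dat$drivers$delta)
  expect_equal(back$date, dat$drivers$date)

  write_observations(dat$obs[, c("date", "tree_id", "E_obs")], p2)
  back2 <- read_observations(p2)
  expect_identical(back2$E_obs, dat$obs$E_obs)
  unlink(c(p1, p2))
})

test_that("multiple WTD tubes reduce per tube, then average", {
  ts <- sprintf("2008-06-01T%02d:00:00", 8:17)
  wtd <- rbind(
    data.frame(timestamp = ts, delta = 30 + 1:10, tube_id = "a"),
    data.frame(timestamp = ts, delta = 50 + 1:10, tube_id = "b")
  )
  met <- data.frame(timestamp = ts, T = 15, h_r = 0.7, I = 1e-3)
  out <- reduce_daily(met, wtd)
  expect_equal(out$drivers$delta,
               mean(c(daily_top_decile_median(30 + 1:10),
                      daily_top_decile_median(50 + 1:10))))
})
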