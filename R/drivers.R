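# Driver pre-processing: meteorology, water table depth, sap flow.
#
# All model input is daily: sub-daily records are reduced to the median of
# the largest 10% of values within each calendar day, variable by variable.

#' Sapwood thickness from stem diameter
#'
#' Quadratic allometry relating diameter at breast height to sapwood
#' thickness for Scots pine on drained peatland, used to convert sap flow
#' density measurements to whole-tree water flux cross-sections.
#'
#' @param d Diameter at breast height (mm); must be positive.
#' @return Sapwood thickness (mm).
#' @examples
#' sapwood_thickness(129) # 32.94 mm for a 12.9 cm DBH tree
#' @export
sapwood_thickness <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("`d` must be positive and finite (DBH in mm)")
  }
  0.0001 * d^2 + 0.1668 * d + 9.755
}

#' Vapour pressure deficit
#'
#' Saturation vapour pressure by the Magnus-type formula
#' \eqn{611 \exp(17.502 T / (T + 240.97))} Pa, scaled by the relative
#' humidity deficit.
#'
#' @param T Air temperature (degrees C).
#' @param h_r Relative humidity as a fraction in \[0, 1\].
#' @return VPD in Pa.
#' @export
vpd <- function(T, h_r) {
  if (any(h_r < 0 | h_r > 1, na.rm = TRUE)) {
    stop("`h_r` must lie in [0, 1]")
  }
  611 * exp(17.502 * T / (T + 240.97)) * (1 - h_r)
}

#' Convert VPD from Pa to molar concentration
#'
#' Ideal-gas conversion \eqn{D = VPD / (8.3145 (T + 273.15))}.
#'
#' @param VPD Vapour pressure deficit (Pa).
#' @param T Air temperature (degrees C).
#' @return D, water vapour concentration deficit (mol H2O m^-3).
#' @export
vpd_molar <- function(VPD, T) {
  VPD / (8.3145 * (T + 273.15))
}

#' Leaf temperature from air temperature and irradiance
#'
#' Linear radiative heating proxy \eqn{T_l = T + 1.5 \times 10^3 I}.
#'
#' @param T Air temperature (degrees C).
#' @param I Photosynthetic photon flux density (mol m^-2 s^-1).
#' @return Leaf temperature (degrees C); never below `T` since `I >= 0`.
#' @export
leaf_temperature <- function(T, I) {
  if (any(I < 0, na.rm = TRUE)) stop("`I` must be non-negative")
  T + 1.5e3 * I
}

#' Median of the top decile of a day's values
#'
#' The daily statistic used for every driver and for sap flow: rank the
#' within-day values and take the median of the largest 10%. The top-decile
#' set has `ceiling(0.1 * n)` members so that it is never empty.
#'
#' @param x Numeric vector of within-day values; `NA`s are dropped.
#' @return A scalar, or `NA` if the day holds no finite values.
#' @export
daily_top_decile_median <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  k <- ceiling(0.1 * n)
  stats::median(sort(x, decreasing = TRUE)[seq_len(k)])
}

#' Anchor a logger water-table series to manual readings
#'
#' The continuous logger records the temporal pattern of water table depth
#' at one point of the site; sparse manual tube readings carry the local
#' level. The two are merged by additive-offset anchoring: the offset
#' (manual minus logger) is computed at each manual timestamp, linearly
#' interpolated in time, and added to the logger series. At every manual
#' timestamp the output equals the manual reading exactly; in between it
#' follows the logger's shape. With a single manual point the whole logger
#' series is shifted by a constant. Outside the manual span the nearest
#' offset is carried (with a warning when logger coverage does not reach a
#' manual point, where the anchoring degenerates to linear interpolation).
#'
#' @param manual data.frame with columns `timestamp` (numeric or Date) and
#'   `delta` (cm) of manual readings, sorted in time.
#' @param logger data.frame with the same columns for the logger series.
#' @return data.frame on the logger timestamps with the anchored `delta`,
#'   clamped at 0 (standing water) with a warning if negatives arise.
#' @export
interpolate_wtd <- function(manual, logger) {
  stopifnot(all(c("timestamp", "delta") %in% names(manual)),
            all(c("timestamp", "delta") %in% names(logger)))
  tm <- as.numeric(manual$timestamp)
  tl <- as.numeric(logger$timestamp)
  if (is.unsorted(tm) || is.unsorted(tl)) stop("series must be time-sorted")
  if (min(tm) < min(tl) || max(tm) > max(tl)) {
    warning("logger series does not cover the manual span; ",
            "edge offsets extrapolated as constants")
  }
  log_at_manual <- stats::approx(tl, logger$delta, xout = tm, rule = 2)$y
  offset <- manual$delta - log_at_manual
  off_series <- if (length(tm) == 1L) {
    rep(offset, length(tl))
  } else {
    stats::approx(tm, offset, xout = tl, rule = 2)$y
  }
  delta <- logger$delta + off_series
  if (any(delta < 0)) {
    warning("negative interpolated WTD clamped to 0 (standing water)")
    delta <- pmax(delta, 0)
  }
  data.frame(timestamp = logger$timestamp, delta = delta)
}

#' Reduce sub-daily records to daily model drivers
#'
#' Computes VPD per record, then reduces every variable (D, I, T, delta and
#' per-tree sap flow) to its daily top-decile median, derives leaf
#' temperature from the daily T and I, and converts sap flow density to
#' leaf-area-specific transpiration by the leaf-to-sapwood area ratio.
#' Days missing any driver are dropped.
#'
#' @param met data.frame `timestamp, T, h_r, I` (ISO timestamps or Date).
#' @param wtd data.frame `timestamp, delta` (daily interpolated WTD; see
#'   [interpolate_wtd()]). Multiple tubes may be present, in which case the
#'   daily reduction is followed by the across-tube mean.
#' @param sap Optional data.frame `timestamp, tree_id, J` with sap flow
#'   density (mol H2O m^-2 sapwood s^-1).
#' @param rho Leaf-to-sapwood area ratio used for `E_obs = J / rho`.
#' @return A list with `drivers` (data.frame `date, D, I, T, T_l, delta`)
#'   and, when `sap` is given, `obs` (data.frame `date, tree_id, E_obs`).
#' @export
reduce_daily <- function(met, wtd, sap = NULL, rho = 2500) {
  day <- function(ts) as.Date(substr(as.character(ts), 1, 10))
  dmet <- day(met$timestamp)
  D_rec <- vpd_molar(vpd(met$T, met$h_r), met$T)
  agg <- function(x, by) {
    out <- tapply(x, by, daily_top_decile_median)
    data.frame(date = as.Date(names(out)), value = as.numeric(out))
  }
  dD <- agg(D_rec, dmet); dI <- agg(met$I, dmet); dT <- agg(met$T, dmet)
  dw <- if (!is.null(wtd$tube_id)) {
    # reduce per tube first, then average the tubes' daily values
    per_tube <- lapply(split(wtd, wtd$tube_id), function(w) {
      agg(w$delta, day(w$timestamp))
    })
    all_days <- sort(unique(do.call(c, lapply(per_tube, `[[`, "date"))))
    vals <- do.call(cbind, lapply(per_tube, function(a) {
      a$value[match(all_days, a$date)]
    }))
    data.frame(date = all_days, value = rowMeans(vals, na.rm = TRUE))
  } else {
    agg(wtd$delta, day(wtd$timestamp))
  }
  drv <- Reduce(function(a, b) merge(a, b, by = "date"),
                list(stats::setNames(dD, c("date", "D")),
                     stats::setNames(dI, c("date", "I")),
                     stats::setNames(dT, c("date", "T")),
                     stats::setNames(dw, c("date", "delta"))))
  drv$T_l <- leaf_temperature(drv$T, drv$I)
  drv <- drv[stats::complete.cases(drv),
             c("date", "D", "I", "T", "T_l", "delta")]
  rownames(drv) <- NULL
  out <- list(drivers = drv)
  if (!is.null(sap)) {
    ds <- day(sap$timestamp)
    spl <- split(sap, sap$tree_id)
    obs <- do.call(rbind, lapply(names(spl), function(id) {
      a <- agg(spl[[id]]$J, day(spl[[id]]$timestamp))
      data.frame(date = a$date, tree_id = id, E_obs = a$value / rho)
    }))
    obs <- obs[obs$date %in% drv$date & is.finite(obs$E_obs), ]
    rownames(obs) <- NULL
    out$obs <- obs
  }
  out
}

# Full-precision CSV round-trip: numbers are written with 17 significant
# digits so that read-back is bit-identical.
.write_num_csv <- function(x, path) {
  fmt <- function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }
  out <- as.data.frame(lapply(x, fmt), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write and read daily driver tables
#'
#' Plain-CSV persistence for the daily driver and observation tables, with
#' full floating-point precision so that a write/read round trip preserves
#' values exactly.
#'
#' @param drivers data.frame `date, D, I, T, T_l, delta`.
#' @param path File path.
#' @export
write_drivers <- function(drivers, path) .write_num_csv(drivers, path)

#' @rdname write_drivers
#' @export
read_drivers <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  x
}

#' @rdname write_drivers
#' @param obs data.frame `date, tree_id, E_obs`.
#' @export
write_observations <- function(obs, path) .write_num_csv(obs, path)

#' @rdname write_drivers
#' @export
read_observations <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  x$tree_id <- as.character(x$tree_id)
  x
}
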