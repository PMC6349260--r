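#' Generate a set of synthetic counties with climate and soil parameters
#'
#' Places counties on a rectangular domain with a north--south temperature
#' gradient and an east--west precipitation gradient, and draws county-level
#' deviations for temperature, precipitation, soil water-holding capacity and
#' soil brightness. These county parameters drive the spatial differentiation
#' that the clustering and cross-validation stages rely on.
#'
#' @param config a configuration list (see [default_config()]).
#' @param seed integer seed.
#' @return a list with `counties` (a data.frame of ids, coordinates and soil
#'   factors) and `climate` (a list, one entry per county, each holding the
#'   monthly climatology `tmax`, `tmin`, `prcp`, `srad` plus noise scales).
#' @export
make_counties <- function(config = default_config(), seed = 1L) {
  cc <- config$counties
  wc <- config$weather
  set.seed(seed)
  n <- cc$n_counties
  lat <- runif(n, 0, cc$lat_span)
  lon <- runif(n, 0, cc$lon_span)
  d_temp <- rnorm(n, 0, cc$county_temp_sd)
  d_prcp <- rnorm(n, 0, cc$county_prcp_sd)
  whc_factor <- exp(rnorm(n, 0, cc$soil_whc_lsd))
  soil_bright <- pmax(0.6, rnorm(n, 1, cc$soil_bright_sd))

  counties <- data.frame(
    county_id = sprintf("C%03d", seq_len(n)),
    lat = lat, lon = lon,
    whc_factor = whc_factor,
    soil_bright = soil_bright,
    stringsAsFactors = FALSE
  )

  m <- 1:12
  seas_t <- (1 - cos(2 * pi * (m - 1) / 12)) / 2   # 0 in Jan, 1 in Jul
  seas_r <- (1 - cos(2 * pi * (m - 0.5) / 12)) / 2 # radiation peak near Jun/Jul
  climate <- vector("list", n)
  for (i in seq_len(n)) {
    tmax_jul <- wc$tmax_jul + cc$temp_lat_gradient * lat[i] + d_temp[i]
    tmax_jan <- wc$tmax_jan + cc$temp_lat_gradient * lat[i] + d_temp[i]
    tmax <- tmax_jan + (tmax_jul - tmax_jan) * seas_t
    prcp <- wc$prcp_jan + (wc$prcp_jul - wc$prcp_jan) * seas_t +
      cc$prcp_lon_gradient * lon[i] + d_prcp[i]
    prcp <- pmax(prcp, 5)
    climate[[i]] <- list(
      county_id = counties$county_id[i],
      tmax = tmax,
      tmin = tmax - wc$dtr,
      prcp = prcp,                    # monthly totals, mm
      srad = wc$srad_min + (wc$srad_max - wc$srad_min) * seas_r,
      wet_frac = wc$wet_frac,
      temp_year_sd = wc$temp_year_sd,
      prcp_year_lsd = wc$prcp_year_lsd,
      temp_day_sd = wc$temp_day_sd,
      temp_day_ar = wc$temp_day_ar,
      prcp_noise = wc$prcp_noise,
      srad_day_sd = wc$srad_day_sd,
      dtr = wc$dtr
    )
  }
  names(climate) <- counties$county_id
  list(counties = counties, climate = climate)
}

days_in_month <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# month index (1..12) for each day of a 365-day year
month_of_doy <- rep.int(1:12, days_in_month)

# interpolate a length-12 monthly climatology to a smooth daily series
monthly_to_daily <- function(mon) {
  centers <- cumsum(days_in_month) - days_in_month / 2
  x <- c(centers[12] - 365, centers, centers[1] + 365)
  y <- c(mon[12], mon, mon[1])
  stats::approx(x, y, xout = 1:365)$y
}

#' Generate one county-year of daily weather
#'
#' Produces a seeded, reproducible daily weather series (365 days) from a
#' county's monthly climatology: an interannual temperature anomaly and
#' precipitation factor, AR(1) daily temperature noise, a Bernoulli--gamma
#' wet-day precipitation process, and seasonal solar radiation damped on wet
#' days. Daily maximum temperature is always at least the daily minimum by
#' construction (the diurnal range is bounded below by 1 degree C). Setting
#' the climate's `prcp_noise` to 0 replaces the stochastic precipitation by
#' the uniform daily climatology of each month.
#'
#' @param climate one county's climate entry from [make_counties()].
#' @param year calendar year (only used to label the series).
#' @param seed integer seed.
#' @return a data.frame with columns `doy`, `tmax`, `tmin`, `prcp`, `srad`.
#' @export
generate_weather <- function(climate, year, seed) {
  set.seed(seed)
  t_anom <- rnorm(1, 0, climate$temp_year_sd)
  p_factor <- exp(rnorm(1, 0, climate$prcp_year_lsd))

  tmax_base <- monthly_to_daily(climate$tmax) + t_anom
  e <- numeric(365)
  z <- rnorm(365, 0, climate$temp_day_sd)
  for (d in 2:365) e[d] <- climate$temp_day_ar * e[d - 1] +
    sqrt(1 - climate$temp_day_ar^2) * z[d]
  e[1] <- z[1]
  tmax <- tmax_base + e
  dtr <- pmax(1, climate$dtr + rnorm(365, 0, 0.7 * climate$temp_day_sd))
  tmin <- tmax - dtr

  mon <- month_of_doy
  daily_clim <- (climate$prcp / days_in_month)[mon]   # mm/day climatology
  if (climate$prcp_noise == 0) {
    prcp <- daily_clim
    wet <- rep(FALSE, 365)
  } else {
    wet <- runif(365) < climate$wet_frac
    amount <- rgamma(365, shape = 0.7,
                     scale = pmax(daily_clim, 0.01) / (climate$wet_frac * 0.7))
    prcp <- ifelse(wet, amount, 0) * p_factor * climate$prcp_noise
  }

  srad <- monthly_to_daily(climate$srad) + rnorm(365, 0, climate$srad_day_sd)
  srad <- pmax(ifelse(wet, srad * 0.7, srad), 1)

  data.frame(doy = 1:365, tmax = tmax, tmin = tmin, prcp = prcp, srad = srad,
             year = year)
}

#' Resolve planting-date percentiles from a weather series
#'
#' Emulates a county-year planting-progress curve: planting activity is
#' centred on the first day of year (at or after day 95) on which the 10-day
#' running mean temperature reaches 12 degrees C, clamped to days 105--140,
#' and spreads around that centre with a normal progress curve (sd 6 days).
#' The requested percentiles of that curve become candidate planting days.
#'
#' @param weather a data.frame from [generate_weather()].
#' @param percentiles numeric percentiles in (0, 100).
#' @param spread_sd sd (days) of the planting-progress curve.
#' @return named integer vector of day-of-year planting dates.
#' @export
planting_percentiles <- function(weather, percentiles = c(25, 50, 75),
                                 spread_sd = 6) {
  tmean <- (weather$tmax + weather$tmin) / 2
  run10 <- stats::filter(tmean, rep(1 / 10, 10), sides = 1)
  idx <- which(seq_along(run10) >= 95 & run10 >= 12)
  centre <- if (length(idx) == 0L) 140 else min(idx)
  centre <- min(max(centre, 105), 140)
  out <- round(centre + stats::qnorm(percentiles / 100) * spread_sd)
  names(out) <- as.character(percentiles)
  out
}
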