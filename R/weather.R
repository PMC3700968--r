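# Synthetic daily weather generation, hourly disaggregation, and
# pseudo-observation generation for calibration tests.

#' Climate parameters for the synthetic weather generator
#'
#' Describes a mid-latitude continental climate as a sinusoidal seasonal
#' cycle in daily mean temperature plus lag-1 autoregressive anomalies,
#' Poisson-arriving winter cold outbreaks (additive negative temperature
#' pulses), Bernoulli precipitation occurrence with gamma amounts, and an
#' optional linear warming trend.
#'
#' @param annual_mean_temp annual mean of daily mean temperature, deg C.
#' @param seasonal_amplitude half peak-to-trough of the seasonal cycle, deg C.
#' @param coldest_day_of_year day-of-year index of the seasonal minimum.
#' @param anomaly_sd stationary standard deviation of daily anomalies, deg C.
#' @param anomaly_autocorr lag-1 autocorrelation of anomalies, in [0, 1).
#' @param outbreak_rate expected number of Arctic cold outbreaks per winter.
#' @param outbreak_drop mean additional cooling at outbreak peak, deg C.
#' @param outbreak_duration_days outbreak length, days (>= 1).
#' @param wet_day_prob probability any day is wet.
#' @param precip_mean mean precipitation per wet day, mm (annual average).
#' @param winter_precip_fraction fraction of annual precipitation falling in
#'   the November-March window.
#' @param trend_per_decade linear warming applied to daily temperatures,
#'   deg C per decade (0 for a stationary climate).
#' @param latitude site latitude, degrees, for solar geometry.
#' @param diurnal_range mean daily tmax - tmin spread, deg C.
#' @param site_label free-text site name.
#' @return an object of class `climate_params` (a validated list).
#' @seealso [site_climate()] for the shipped site presets.
#' @export
climate_params <- function(annual_mean_temp = 8,
                           seasonal_amplitude = 14.5,
                           coldest_day_of_year = 15,
                           anomaly_sd = 4,
                           anomaly_autocorr = 0.7,
                           outbreak_rate = 2,
                           outbreak_drop = 10,
                           outbreak_duration_days = 5,
                           wet_day_prob = 0.28,
                           precip_mean = 6,
                           winter_precip_fraction = 0.18,
                           trend_per_decade = 0,
                           latitude = 43,
                           diurnal_range = 9,
                           site_label = "custom") {
  stopifnot(seasonal_amplitude > 0,
            anomaly_autocorr >= 0, anomaly_autocorr < 1,
            outbreak_duration_days >= 1,
            precip_mean > 0,
            wet_day_prob >= 0, wet_day_prob <= 1,
            winter_precip_fraction > 0, winter_precip_fraction < 1,
            latitude >= -90, latitude <= 90,
            diurnal_range > 0)
  structure(list(annual_mean_temp = annual_mean_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 coldest_day_of_year = coldest_day_of_year,
                 anomaly_sd = anomaly_sd,
                 anomaly_autocorr = anomaly_autocorr,
                 outbreak_rate = outbreak_rate,
                 outbreak_drop = outbreak_drop,
                 outbreak_duration_days = outbreak_duration_days,
                 wet_day_prob = wet_day_prob,
                 precip_mean = precip_mean,
                 winter_precip_fraction = winter_precip_fraction,
                 trend_per_decade = trend_per_decade,
                 latitude = latitude,
                 diurnal_range = diurnal_range,
                 site_label = site_label),
            class = "climate_params")
}

#' Named site presets spanning a north-south Midwest-style climate gradient
#'
#' Eight synthetic sites from a cold, dry northern-plains climate to a mild
#' southern one, differing in mean temperature, seasonal amplitude, cold
#' outbreak statistics, and snowfall amount/persistence (through winter
#' precipitation fraction and wet-day frequency).
#'
#' @return character vector of preset names.
#' @export
site_presets <- function() {
  names(.site_table())
}

.site_table <- function() {
  list(
    "north-plains"    = list(annual_mean_temp = 4.0, seasonal_amplitude = 17.5,
                             latitude = 47.5, outbreak_rate = 3, outbreak_drop = 12,
                             wet_day_prob = 0.24, precip_mean = 4.5,
                             winter_precip_fraction = 0.14, anomaly_sd = 4.5),
    "west-plains"     = list(annual_mean_temp = 7.5, seasonal_amplitude = 16.0,
                             latitude = 44.5, outbreak_rate = 2.5, outbreak_drop = 11,
                             wet_day_prob = 0.24, precip_mean = 5.0,
                             winter_precip_fraction = 0.12, anomaly_sd = 4.5),
    "upper-lakes"     = list(annual_mean_temp = 5.0, seasonal_amplitude = 15.5,
                             latitude = 46.0, outbreak_rate = 2.5, outbreak_drop = 11,
                             wet_day_prob = 0.34, precip_mean = 5.5,
                             winter_precip_fraction = 0.24, anomaly_sd = 4.0),
    "central-cornbelt" = list(annual_mean_temp = 9.0, seasonal_amplitude = 15.0,
                             latitude = 42.0, outbreak_rate = 2, outbreak_drop = 10,
                             wet_day_prob = 0.28, precip_mean = 6.5,
                             winter_precip_fraction = 0.14, anomaly_sd = 4.0),
    "east-cornbelt"   = list(annual_mean_temp = 10.0, seasonal_amplitude = 13.5,
                             latitude = 40.5, outbreak_rate = 1.8, outbreak_drop = 9,
                             wet_day_prob = 0.31, precip_mean = 7.0,
                             winter_precip_fraction = 0.18, anomaly_sd = 3.8),
    "lakeshore"       = list(annual_mean_temp = 8.0, seasonal_amplitude = 13.0,
                             latitude = 43.0, outbreak_rate = 1.8, outbreak_drop = 9,
                             wet_day_prob = 0.38, precip_mean = 6.0,
                             winter_precip_fraction = 0.28, anomaly_sd = 3.5),
    "south-cornbelt"  = list(annual_mean_temp = 11.5, seasonal_amplitude = 13.0,
                             latitude = 39.0, outbreak_rate = 1.5, outbreak_drop = 9,
                             wet_day_prob = 0.28, precip_mean = 7.5,
                             winter_precip_fraction = 0.16, anomaly_sd = 3.8),
    "south"           = list(annual_mean_temp = 13.5, seasonal_amplitude = 12.0,
                             latitude = 37.5, outbreak_rate = 1.2, outbreak_drop = 8,
                             wet_day_prob = 0.29, precip_mean = 8.0,
                             winter_precip_fraction = 0.18, anomaly_sd = 3.5)
  )
}

#' Climate parameters for a named site preset
#'
#' @param site one of [site_presets()].
#' @param ... overrides passed to [climate_params()].
#' @return a `climate_params` object.
#' @export
site_climate <- function(site, ...) {
  tab <- .site_table()
  if (!site %in% names(tab))
    stop("unknown site preset '", site, "'; valid presets: ",
         paste(names(tab), collapse = ", "))
  args <- utils::modifyList(tab[[site]], list(...))
  args$site_label <- site
  do.call(climate_params, args)
}

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# daily extraterrestrial radiation, MJ m-2 d-1 (FAO-56)
extraterrestrial_radiation <- function(doy, latitude) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  ws <- acos(x)
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Generate a multi-year synthetic daily weather series
#'
#' Daily mean temperature is a sinusoid (minimum at
#' `coldest_day_of_year`) plus AR(1) anomalies, additive half-sine cold
#' outbreak pulses arriving as a Poisson process within each November-March
#' window, and an optional linear trend. Precipitation occurrence is
#' Bernoulli, amounts gamma with seasonally modulated mean so that the
#' November-March share equals `winter_precip_fraction`. Years are 365 days
#' (no leap days).
#'
#' @param params a [climate_params()] object.
#' @param n_years number of full years to generate (>= 1).
#' @param seed integer seed; identical seeds give byte-identical series.
#' @return data.frame with columns `date`, `year`, `doy`, `tmax_c`, `tmin_c`,
#'   `precip_mm`, `rh_pct`, `wind_ms`, `solar_mj`.
#' @export
generate_daily_series <- function(params, n_years, seed) {
  stopifnot(inherits(params, "climate_params"))
  if (!is.numeric(n_years) || n_years < 1)
    stop("n_years must be a positive integer (got ", n_years, ")")
  n_years <- as.integer(n_years)
  n <- 365L * n_years
  doy <- rep(seq_len(365L), n_years)
  year <- rep(seq_len(n_years), each = 365L)
  with_local_seed(seed, {
    tbar <- params$annual_mean_temp -
      params$seasonal_amplitude *
        cos(2 * pi * (doy - params$coldest_day_of_year) / 365) +
      params$trend_per_decade * ((seq_len(n) - 1) / 365) / 10

    # AR(1) anomalies with stationary sd = anomaly_sd
    rho <- params$anomaly_autocorr
    eps <- rnorm(n, 0, params$anomaly_sd * sqrt(1 - rho^2))
    anom <- numeric(n)
    anom[1] <- rnorm(1, 0, params$anomaly_sd)
    for (i in 2:n) anom[i] <- rho * anom[i - 1] + eps[i]

    # cold outbreaks: half-sine negative pulses in each winter window
    pulse <- numeric(n)
    dur <- max(1L, round(params$outbreak_duration_days))
    for (w in 0:n_years) {
      w0 <- w * 365L - 60L; w1 <- w * 365L + 90L
      n_ob <- rpois(1, params$outbreak_rate)
      if (n_ob == 0) next
      starts <- floor(runif(n_ob, w0, w1 - dur))
      mags <- rgamma(n_ob, shape = 2, scale = params$outbreak_drop / 2)
      for (j in seq_len(n_ob)) {
        idx <- starts[j] + seq_len(dur) - 1L
        keep <- idx >= 1L & idx <= n
        pulse[idx[keep]] <- pulse[idx[keep]] +
          mags[j] * sin(pi * (seq_len(dur)[keep] - 0.5) / dur)
      }
    }
    tmean <- tbar + anom - pulse

    rng <- pmax(2, params$diurnal_range *
                  (1 + 0.25 * cos(2 * pi * (doy - params$coldest_day_of_year -
                                              182.5) / 365)) +
                  rnorm(n, 0, 1.5))
    tmax <- tmean + rng / 2
    tmin <- tmean - rng / 2

    # precipitation: Bernoulli occurrence, gamma amounts, seasonal mean shift
    winter <- doy >= 305 | doy <= 90   # Nov-Mar, 151 days
    frac <- params$winter_precip_fraction
    mult <- ifelse(winter, frac * 365 / 151, (1 - frac) * 365 / 214)
    wet <- rbinom(n, 1, params$wet_day_prob) == 1
    precip <- numeric(n)
    precip[wet] <- rgamma(sum(wet), shape = 0.75,
                          scale = params$precip_mean * mult[wet] / 0.75)

    rh <- ifelse(wet, rnorm(n, 85, 5), rnorm(n, 62, 8))
    rh <- pmin(100, pmax(25, rh))
    wind <- pmin(15, pmax(0.5, rlnorm(n, log(3.5), 0.4)))

    ra <- extraterrestrial_radiation(doy, params$latitude)
    tau <- ifelse(wet, rnorm(n, 0.30, 0.08), rnorm(n, 0.70, 0.06))
    tau <- pmin(0.78, pmax(0.10, tau))
    solar <- pmax(0, ra * tau)

    data.frame(
      date = as.Date(paste0(2000 + year, "-01-01")) + (doy - 1),
      year = year, doy = doy,
      tmax_c = tmax, tmin_c = tmin, precip_mm = precip,
      rh_pct = rh, wind_ms = wind, solar_mj = solar)
  })
}

#' Disaggregate daily weather to hourly forcing
#'
#' Air temperature follows a piecewise cosine with the minimum at (rounded)
#' sunrise and the maximum at 14:00, clamped to the day's `[tmin, tmax]`;
#' shortwave follows the clear-sky zenith-angle shape normalised to conserve
#' the daily total exactly; precipitation falls in a contiguous 6-hour block
#' from 05:00; downwelling longwave uses a Brutsaert clear-sky emissivity
#' with a wet-day cloud correction. Precipitation phase is snow at or below
#' 1.1 deg C (see [partition_precipitation()]).
#'
#' @param daily data.frame as returned by [generate_daily_series()] (columns
#'   `tmax_c`, `tmin_c`, `precip_mm`, `rh_pct`, `wind_ms`, `solar_mj`, and
#'   `doy`; one or more consecutive days). First/last days reuse their own
#'   values as the previous/next day.
#' @param latitude degrees, in [-90, 90].
#' @return data.frame with 24 rows per day: `day`, `hour`, `air_temp`,
#'   `precip_mm`, `precip_snow`, `shortwave`, `longwave_down`,
#'   `rel_humidity`, `wind`.
#' @export
disaggregate_to_hourly <- function(daily, latitude) {
  if (latitude < -90 || latitude > 90)
    stop("latitude must be within [-90, 90]")
  nd <- nrow(daily)
  if (nd == 0) return(data.frame())
  doy <- if ("doy" %in% names(daily)) daily$doy else seq_len(nd)
  tmax <- daily$tmax_c; tmin <- daily$tmin_c
  tmax_prev <- c(tmax[1], tmax[-nd])
  tmin_next <- c(tmin[-1], tmin[nd])

  phi <- latitude * pi / 180
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  sunrise <- 12 - acos(x) * 12 / pi
  sr <- pmin(10, pmax(4, round(sunrise)))

  h <- 0:23
  hh <- matrix(rep(h, nd), nrow = nd, byrow = TRUE)
  srm <- matrix(sr, nrow = nd, ncol = 24)
  tmaxm <- matrix(tmax, nd, 24); tminm <- matrix(tmin, nd, 24)
  tpm <- matrix(tmax_prev, nd, 24); tnm <- matrix(tmin_next, nd, 24)
  srnext <- c(sr[-1], sr[nd]); srnm <- matrix(srnext, nd, 24)

  temp <- matrix(NA_real_, nd, 24)
  pre <- hh < srm
  mid <- hh >= srm & hh <= 14
  post <- hh > 14
  # descending from previous day's 14:00 peak to today's sunrise minimum
  dpre <- srm + 10
  temp[pre] <- tminm[pre] + (tpm[pre] - tminm[pre]) * 0.5 *
    (1 + cos(pi * (hh[pre] + 10) / dpre[pre]))
  # rising limb sunrise -> 14:00
  temp[mid] <- tminm[mid] + (tmaxm[mid] - tminm[mid]) * 0.5 *
    (1 - cos(pi * (hh[mid] - srm[mid]) / (14 - srm[mid])))
  # descending limb toward next day's sunrise minimum
  dpost <- srnm + 10
  temp[post] <- tnm[post] + (tmaxm[post] - tnm[post]) * 0.5 *
    (1 + cos(pi * (hh[post] - 14) / dpost[post]))
  temp <- pmin(tmaxm, pmax(tminm, temp))  # keep hourly extremes = tmax/tmin

  # shortwave: zenith-angle weights at hour centres, exact daily conservation
  coszen <- sin(phi) * sin(delta) %o% rep(1, 24) +
    (cos(phi) * cos(delta)) %o% rep(1, 24) *
      matrix(rep(cos(pi * (h + 0.5 - 12) / 12), nd), nd, byrow = TRUE)
  w <- pmax(coszen, 0)
  wsum <- rowSums(w)
  flat <- wsum <= 0
  if (any(flat)) { w[flat, 11:15] <- 1; wsum[flat] <- 5 }
  sw <- (daily$solar_mj * 1e6 / 3600) * w / wsum

  # precipitation: contiguous block, hours 5-10
  pr <- matrix(0, nd, 24)
  pr[, 6:11] <- daily$precip_mm / 6

  rhm <- matrix(daily$rh_pct, nd, 24)
  windm <- matrix(daily$wind_ms, nd, 24)

  # longwave down: Brutsaert clear-sky emissivity + cloud correction
  tk <- temp + 273.15
  ea_hpa <- rhm / 100 * 6.11 * exp(17.27 * temp / (temp + 237.3))
  eps_cs <- 1.24 * (ea_hpa / tk)^(1 / 7)
  cloud <- matrix(ifelse(daily$precip_mm > 0, 0.8, 0.25), nd, 24)
  eps_sky <- pmin(1, eps_cs * (1 + 0.22 * cloud^2))
  lwd <- eps_sky * 5.670374419e-8 * tk^4

  out <- data.frame(
    day = rep(seq_len(nd), each = 24),
    hour = rep(h, nd),
    air_temp = as.vector(t(temp)),
    precip_mm = as.vector(t(pr)),
    shortwave = as.vector(t(sw)),
    longwave_down = as.vector(t(lwd)),
    rel_humidity = as.vector(t(rhm)),
    wind = as.vector(t(windm)))
  out$precip_snow <- out$precip_mm > 0 &
    partition_precipitation(out$air_temp) == "snow"
  out
}

#' Generate pseudo-observed annual extremes from simulated ones
#'
#' Applies a quadratic transform `obs = a*sim^2 + b*sim + c` plus Gaussian
#' noise, emulating the systematic bias between a simulator and station
#' observations so bias-correction recovery can be tested without
#' proprietary station data.
#'
#' @param sim_extremes numeric vector of simulated annual extreme minima.
#' @param bias_poly numeric length-3 `(a, b, c)` = (quadratic, linear,
#'   intercept) coefficients.
#' @param noise_sd observation noise standard deviation, deg C (>= 0).
#' @param seed integer seed.
#' @return numeric vector of pseudo-observations, same length as input.
#' @export
make_pseudo_observations <- function(sim_extremes, bias_poly, noise_sd, seed) {
  stopifnot(length(bias_poly) == 3, noise_sd >= 0)
  if (length(sim_extremes) == 0) return(numeric(0))
  with_local_seed(seed, {
    bias_poly[1] * sim_extremes^2 + bias_poly[2] * sim_extremes +
      bias_poly[3] + rnorm(length(sim_extremes), 0, noise_sd)
  })
}

#' Write / read a daily weather series as CSV
#'
#' One row per day with header
#' `date,tmax_c,tmin_c,precip_mm,rh_pct,wind_ms,solar_mj` (ISO-8601 dates),
#' so externally supplied series can substitute for synthetic ones.
#'
#' @param daily data.frame from [generate_daily_series()].
#' @param path file path.
#' @return `read_weather_csv` returns the data.frame with `year`/`doy`
#'   reconstructed from the dates.
#' @export
write_weather_csv <- function(daily, path) {
  cols <- c("date", "tmax_c", "tmin_c", "precip_mm", "rh_pct", "wind_ms",
            "solar_mj")
  stopifnot(all(cols %in% names(daily)))
  write.csv(daily[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("date", "tmax_c", "tmin_c", "precip_mm", "rh_pct", "wind_ms",
            "solar_mj")
  missing <- setdiff(cols, names(d))
  if (length(missing))
    stop("weather CSV lacks columns: ", paste(missing, collapse = ", "))
  d$date <- as.Date(d$date)
  yr <- as.integer(format(d$date, "%Y"))
  d$year <- yr - min(yr) + 1L
  d$doy <- as.integer(format(d$date, "%j"))
  d$doy[d$doy > 365L] <- 365L
  if (any(d$tmax_c < d$tmin_c)) stop("weather CSV has tmax < tmin")
  if (any(d$precip_mm < 0)) stop("weather CSV has negative precipitation")
  d
}
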