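# Scenario composition: weather -> hourly forcing -> column engine ->
# daily 10 cm temperature series, plus paired sensitivity sweeps.

.SCENARIO_REGISTRY <- list(
  "MAIZE+TILL"     = list(residue = NULL),
  "MAIZE+NOTILL"   = list(residue_type = "maize", thickness = 0.05),
  "MISCAN+R_1cm"   = list(residue_type = "miscanthus", thickness = 0.01),
  "MISCAN+R_2.5cm" = list(residue_type = "miscanthus", thickness = 0.025),
  "MISCAN+R_5cm"   = list(residue_type = "miscanthus", thickness = 0.05))

#' Names of the registered management scenarios
#'
#' `MAIZE+TILL` is conventional tillage with all residue removed (bare soil
#' over winter); `MAIZE+NOTILL` leaves a 5 cm prostrate maize-stover layer;
#' the `MISCAN+R_*` scenarios leave miscanthus straw of 1, 2.5 or 5 cm.
#' All residue layers persist year-round.
#'
#' @return character vector of scenario names.
#' @export
scenario_names <- function() names(.SCENARIO_REGISTRY)

#' Configure a simulation scenario
#'
#' @param scenario_name one of [scenario_names()], or `"custom"` with an
#'   explicit `residue` argument (or `NULL` for bare soil).
#' @param climate a [climate_params()] object (e.g. from [site_climate()])
#'   or a path to a weather CSV readable by [read_weather_csv()].
#' @param texture soil texture class label (length 1 or 11), see
#'   [soil_grid()].
#' @param residue a [residue_spec()] or `NULL`; ignored for registered
#'   scenario names, which define their own residue.
#' @param albedo_override optional residue albedo replacing the preset.
#' @param porosity_override optional residue porosity; bulk density is
#'   re-derived at fixed cellulose density
#'   (`bulk = cellulose * (1 - porosity)`).
#' @param n_years number of output years (after spin-up).
#' @param spinup_years years discarded as spin-up (default 1).
#' @param seed integer seed for the weather generator.
#' @param dt_hours solver time step, hours (default 1; 0.5 halves the step).
#' @param soil_albedo bare-soil albedo.
#' @param snow_density constant snow density, kg/m^3.
#' @param snow_albedo snow albedo.
#' @param snow_d_full depth of full snow cover, m.
#' @param probe_depth_cm output probe depth, cm (10 = rhizome depth).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario_name = "custom",
                            climate = site_climate("central-cornbelt"),
                            texture = "loam",
                            residue = NULL,
                            albedo_override = NULL,
                            porosity_override = NULL,
                            n_years = 30,
                            spinup_years = 1,
                            seed = 1,
                            dt_hours = 1,
                            soil_albedo = 0.15,
                            snow_density = 250,
                            snow_albedo = 0.75,
                            snow_d_full = 0.05,
                            probe_depth_cm = 10) {
  if (scenario_name != "custom") {
    reg <- .SCENARIO_REGISTRY[[scenario_name]]
    if (is.null(reg))
      stop("unknown scenario '", scenario_name, "'; registered scenarios: ",
           paste(scenario_names(), collapse = ", "),
           " (or use scenario_name = 'custom' with an explicit residue)")
    residue <- if (is.null(reg$residue_type)) NULL
    else residue_spec(reg$residue_type, thickness = reg$thickness)
  }
  if (!is.null(residue)) {
    stopifnot(inherits(residue, "residue_spec"))
    if (!is.null(porosity_override)) {
      stopifnot(porosity_override > 0, porosity_override < 1)
      residue$porosity <- porosity_override
      residue$bulk_density <- residue$cellulose_density *
        (1 - porosity_override)
    }
    if (!is.null(albedo_override)) {
      stopifnot(albedo_override > 0, albedo_override < 1)
      residue$albedo <- albedo_override
    }
  }
  stopifnot(n_years >= 0, spinup_years >= 0, dt_hours > 0)
  structure(list(scenario_name = scenario_name, climate = climate,
                 texture = texture, residue = residue,
                 n_years = n_years, spinup_years = spinup_years,
                 seed = seed, dt_hours = dt_hours,
                 soil_albedo = soil_albedo, snow_density = snow_density,
                 snow_albedo = snow_albedo, snow_d_full = snow_d_full,
                 probe_depth_cm = probe_depth_cm),
            class = "scenario_config")
}

#' Build the hourly forcing shared by a scenario (or a sweep)
#'
#' Generates (or reads) the daily series including spin-up years,
#' disaggregates it to hourly, and packs the numeric forcing matrix the
#' engine consumes. Sweeps reuse one forcing object across all members so
#' that differences between members are purely parametric (common random
#' numbers).
#'
#' @param config a [scenario_config()].
#' @return list of class `scenario_forcing` with `daily`, `hourly`, `mat`,
#'   `latitude`, `n_total_years`.
#' @export
scenario_forcing <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  total_years <- config$n_years + config$spinup_years
  if (inherits(config$climate, "climate_params")) {
    lat <- config$climate$latitude
    daily <- if (total_years >= 1)
      generate_daily_series(config$climate, total_years, config$seed)
    else NULL
  } else {
    daily <- read_weather_csv(config$climate)
    lat <- 43
    total_years <- nrow(daily) %/% 365L
  }
  if (is.null(daily) || total_years < 1)
    return(structure(list(daily = daily, hourly = NULL, mat = NULL,
                          latitude = lat, n_total_years = total_years),
                     class = "scenario_forcing"))
  hourly <- disaggregate_to_hourly(daily, lat)
  if (config$dt_hours != 1) hourly <- .refine_hourly(hourly, config$dt_hours)
  mat <- cbind(hourly$air_temp, hourly$precip_mm,
               as.numeric(hourly$precip_snow), hourly$shortwave,
               hourly$longwave_down, hourly$rel_humidity, hourly$wind)
  structure(list(daily = daily, hourly = hourly, mat = mat, latitude = lat,
                 n_total_years = total_years),
            class = "scenario_forcing")
}

# linear-in-time refinement of the hourly forcing to sub-hourly steps
.refine_hourly <- function(hourly, dt_hours) {
  k <- round(1 / dt_hours)
  stopifnot(k >= 1, abs(k * dt_hours - 1) < 1e-9)
  if (k == 1) return(hourly)
  idx <- rep(seq_len(nrow(hourly)), each = k)
  out <- hourly[idx, ]
  out$precip_mm <- out$precip_mm / k
  out
}

# one engine run over the forcing for a given residue configuration
.run_column <- function(fc, grid, residue, config, init_temp) {
  soil <- list(thick_m = grid$layer_thicknesses_cm / 100,
               porosity = grid$porosity,
               field_capacity = grid$field_capacity,
               wilting_point = grid$wilting_point,
               k_dry = grid$dry_conductivity,
               k_solids = grid$solids_conductivity,
               c_solids = grid$solids_heat_capacity,
               init_temp = rep(init_temp, 11),
               init_liquid = grid$field_capacity,
               init_ice = rep(0, 11))
  has_res <- !is.null(residue) && residue$thickness > 0
  surf <- list(res_present = has_res,
               res_thick = if (has_res) residue$thickness else 0,
               res_k = if (has_res) residue$thermal_conductivity else 0.1,
               res_cvol = if (has_res)
                 residue$bulk_density * residue$specific_heat else 1e4,
               res_albedo = if (has_res) residue$albedo else config$soil_albedo,
               res_z0 = if (has_res) residue$roughness_length else 0.01,
               snow_rho = config$snow_density,
               snow_albedo = config$snow_albedo,
               snow_dfull = config$snow_d_full,
               # pack enters the conduction stack once 5 mm deep, so the
               # engine's minimum slab thickness never binds
               snow_min_swe = config$snow_density * 0.005,
               soil_albedo = config$soil_albedo,
               soil_z0 = 0.01)
  opts <- list(dt_s = config$dt_hours * 3600, emiss = 0.98, dTf = 0.5,
               zref = 10, probe_depth_cm = config$probe_depth_cm)
  cpp_run_column(fc$mat, soil, surf, opts)
}

#' Run a management scenario
#'
#' Composes the weather generator, soil column, surface layers, and thermal
#' solver into one simulation and returns the daily 10 cm temperature
#' series after spin-up. When the residue covers only a fraction of the
#' ground, a residue-covered column and a bare column are run on identical
#' forcing and area-weighted (parallel two-column treatment of fractional
#' cover). Identical configurations and seeds give identical output.
#'
#' @param config a [scenario_config()].
#' @param forcing optional [scenario_forcing()] to reuse across runs
#'   (common random numbers); built from `config` when omitted.
#' @return data.frame of class `frost_run`, one row per simulated day after
#'   spin-up: `date`, `year`, `doy`, `t10cm_daily_mean`, `snow_depth_m`,
#'   `swe_mm`, `surface_albedo`. Attributes: `config`, `ledgers` (energy /
#'   water / snow conservation accounting per column), `provenance`.
#' @export
run_scenario <- function(config, forcing = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(forcing)) forcing <- scenario_forcing(config)
  if (config$n_years == 0 || is.null(forcing$mat)) {
    out <- data.frame(date = as.Date(character(0)), year = integer(0),
                      doy = integer(0), t10cm_daily_mean = numeric(0),
                      snow_depth_m = numeric(0), swe_mm = numeric(0),
                      surface_albedo = numeric(0))
    class(out) <- c("frost_run", "data.frame")
    attr(out, "config") <- config
    return(out)
  }
  grid <- soil_grid(config$texture)
  init_temp <- if (inherits(config$climate, "climate_params"))
    config$climate$annual_mean_temp
  else mean((forcing$daily$tmax_c + forcing$daily$tmin_c) / 2)

  res <- config$residue
  cov <- .run_column(forcing, grid, res, config, init_temp)
  ledgers <- list(covered = list(energy = cov$energy, water = cov$water,
                                 snow = cov$snow))
  if (!is.null(res) && res$fractional_cover < 1) {
    bare <- .run_column(forcing, grid, NULL, config, init_temp)
    f <- res$fractional_cover
    t10 <- f * cov$t10_daily_mean + (1 - f) * bare$t10_daily_mean
    depth <- f * cov$snow_depth_m + (1 - f) * bare$snow_depth_m
    swe <- f * cov$swe_mm + (1 - f) * bare$swe_mm
    alb <- f * cov$albedo + (1 - f) * bare$albedo
    ledgers$bare <- list(energy = bare$energy, water = bare$water,
                         snow = bare$snow)
  } else {
    t10 <- cov$t10_daily_mean; depth <- cov$snow_depth_m
    swe <- cov$swe_mm; alb <- cov$albedo
  }

  keep <- seq.int(config$spinup_years * 365L + 1L,
                  forcing$n_total_years * 365L)
  daily <- forcing$daily[keep, ]
  out <- data.frame(date = daily$date,
                    year = daily$year - config$spinup_years,
                    doy = daily$doy,
                    t10cm_daily_mean = t10[keep],
                    snow_depth_m = depth[keep],
                    swe_mm = swe[keep],
                    surface_albedo = alb[keep])
  rownames(out) <- NULL
  class(out) <- c("frost_run", "data.frame")
  attr(out, "config") <- config
  attr(out, "ledgers") <- ledgers
  attr(out, "provenance") <- list(
    package_version = as.character(utils::packageVersion("frosthatch")),
    seed = config$seed, scenario = config$scenario_name)
  out
}

#' @export
print.frost_run <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<frost_run> scenario:", cfg$scenario_name, "\n")
  if (inherits(cfg$climate, "climate_params"))
    cat("  site:", cfg$climate$site_label, "\n")
  cat("  days:", nrow(x), " seed:", cfg$seed, "\n")
  if (nrow(x) > 0)
    cat(sprintf("  10 cm temperature: mean %.2f C, min %.2f C\n",
                mean(x$t10cm_daily_mean), min(x$t10cm_daily_mean)))
  invisible(x)
}

#' @export
summary.frost_run <- function(object, thresholds = c(-3.5, -6.0), ...) {
  rec <- annual_extreme_minima(object)
  exc <- vapply(thresholds, function(th)
    if (nrow(rec)) exceedance_frequency(rec, th) else NA_real_, numeric(1))
  names(exc) <- paste0("P(min <= ", thresholds, "C)")
  structure(list(scenario = attr(object, "config")$scenario_name,
                 n_winters = nrow(rec),
                 mean_extreme_min = mean(rec$extreme_min_t10),
                 sd_extreme_min = stats::sd(rec$extreme_min_t10),
                 exceedance = exc, records = rec),
            class = "summary.frost_run")
}

#' @export
print.summary.frost_run <- function(x, ...) {
  cat("<frost_run summary> scenario:", x$scenario, "\n")
  cat(sprintf("  winters: %d\n", x$n_winters))
  cat(sprintf("  annual extreme min of 3-day running-mean 10 cm T: %.2f C (sd %.2f)\n",
              x$mean_extreme_min, x$sd_extreme_min))
  for (i in seq_along(x$exceedance))
    cat(sprintf("  %s = %.2f\n", names(x$exceedance)[i], x$exceedance[i]))
  invisible(x)
}

#' @export
plot.frost_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1.5, 1))
  on.exit(graphics::par(op))
  plot(x$date, x$t10cm_daily_mean, type = "l",
       xlab = "", ylab = "10 cm soil temperature (C)", ...)
  graphics::abline(h = c(-3.5, -6), lty = 2, col = c("orange", "red"))
  plot(x$date, x$snow_depth_m * 100, type = "l",
       xlab = "", ylab = "snow depth (cm)")
  invisible(x)
}

#' Residue-thickness sensitivity sweep
#'
#' Runs the base scenario once per residue thickness plus the bare (0 cm)
#' reference, all on the identical weather realisation, and collects the
#' annual extreme minima of the 3-day running-mean 10 cm temperature.
#'
#' @param base a [scenario_config()] whose residue supplies the residue
#'   type/properties (defaults to the miscanthus preset when base is bare).
#' @param thicknesses residue thicknesses, cm, non-negative sorted unique.
#' @return list of class `frost_sweep` with `param = "thickness"`, `values`,
#'   `runs` (named list of `frost_run`), `extremes` (named list of
#'   annual-extreme record frames).
#' @export
thickness_sweep <- function(base, thicknesses = c(1, 2.5, 5, 10, 20)) {
  stopifnot(inherits(base, "scenario_config"))
  if (any(thicknesses < 0)) stop("thicknesses must be non-negative")
  if (is.unsorted(thicknesses, strictly = TRUE))
    stop("thicknesses must be sorted and unique")
  values <- unique(c(0, thicknesses))
  forcing <- scenario_forcing(base)
  template <- base$residue
  if (is.null(template)) template <- residue_spec("miscanthus")
  runs <- lapply(values, function(t_cm) {
    cfg <- base
    cfg$scenario_name <- if (t_cm == 0) "bare-reference"
    else sprintf("%s+R_%gcm", template$residue_type, t_cm)
    cfg$residue <- if (t_cm == 0) NULL else {
      r <- template; r$thickness <- t_cm / 100; r
    }
    run_scenario(cfg, forcing)
  })
  names(runs) <- as.character(values)
  structure(list(param = "thickness", values = values, runs = runs,
                 extremes = lapply(runs, annual_extreme_minima),
                 base = base),
            class = "frost_sweep")
}

#' Residue albedo / porosity sensitivity sweep
#'
#' One run per value on shared weather. Porosity variation adjusts bulk
#' density at fixed cellulose density, so it alters the residue heat
#' capacity but not its tabulated conductivity.
#'
#' @param base a [scenario_config()] with a residue layer.
#' @param field `"albedo"` or `"porosity"`.
#' @param values values to sweep, each in (0, 1).
#' @return a `frost_sweep` (see [thickness_sweep()]).
#' @export
property_sweep <- function(base, field = c("albedo", "porosity"), values) {
  stopifnot(inherits(base, "scenario_config"))
  field <- match.arg(field)
  if (is.null(base$residue))
    stop("property_sweep requires a base scenario with a residue layer")
  if (any(values <= 0 | values >= 1))
    stop(field, " values must lie strictly within (0, 1)")
  forcing <- scenario_forcing(base)
  runs <- lapply(values, function(v) {
    cfg <- base
    if (field == "albedo") {
      cfg$residue$albedo <- v
    } else {
      cfg$residue$porosity <- v
      cfg$residue$bulk_density <- cfg$residue$cellulose_density * (1 - v)
    }
    cfg$scenario_name <- sprintf("%s[%s=%g]", base$scenario_name, field, v)
    run_scenario(cfg, forcing)
  })
  names(runs) <- as.character(values)
  structure(list(param = field, values = values, runs = runs,
                 extremes = lapply(runs, annual_extreme_minima),
                 base = base),
            class = "frost_sweep")
}

#' @export
print.frost_sweep <- function(x, ...) {
  cat("<frost_sweep> parameter:", x$param, "\n  values:",
      paste(x$values, collapse = ", "), "\n")
  means <- vapply(x$extremes, function(r)
    if (nrow(r)) mean(r$extreme_min_t10) else NA_real_, numeric(1))
  for (i in seq_along(means))
    cat(sprintf("  %s = %-6s mean annual extreme min: %.2f C\n",
                x$param, names(means)[i], means[i]))
  invisible(x)
}

#' Read a scenario configuration from a YAML file
#'
#' Recognised keys: `scenario` (registered name or "custom"), `site` or a
#' `climate:` block of [climate_params()] fields, `texture`, `n_years`,
#' `spinup_years`, `seed`, and an optional `residue:` block
#' (`type`, `thickness_cm`, plus any [residue_spec()] field).
#'
#' @param path YAML file path.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  climate <- if (!is.null(y$site)) site_climate(y$site)
  else if (!is.null(y$climate)) do.call(climate_params, y$climate)
  else site_climate("central-cornbelt")
  residue <- NULL
  if (!is.null(y$residue)) {
    args <- y$residue
    if (!is.null(args$thickness_cm)) {
      args$thickness <- args$thickness_cm / 100
      args$thickness_cm <- NULL
    }
    names(args)[names(args) == "type"] <- "residue_type"
    residue <- do.call(residue_spec, args)
  }
  scenario_config(
    scenario_name = y$scenario %||% "custom",
    climate = climate,
    texture = y$texture %||% "loam",
    residue = residue,
    n_years = y$n_years %||% 30,
    spinup_years = y$spinup_years %||% 1,
    seed = y$seed %||% 1)
}
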