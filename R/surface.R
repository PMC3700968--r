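# Surface covers above the mineral soil: bulk snowpack and prostrate crop
# residue, plus surface albedo composition and thatch-mass arithmetic.

#' Biophysical description of a prostrate crop-residue layer
#'
#' Shipped presets describe post-harvest maize stover and miscanthus straw
#' lying flat on the soil surface. Any field can be overridden. The
#' tabulated porosity is used wherever porosity is required; the diagnostic
#' `1 - bulk_density/cellulose_density` is available via
#' [residue_porosity_check()] since field-measured bulk density and porosity
#' need not be mutually consistent.
#'
#' @param residue_type `"maize"` or `"miscanthus"`.
#' @param thickness layer thickness, m (>= 0; 0 means the layer is absent).
#' @param roughness_length aerodynamic roughness, m.
#' @param bulk_density layer bulk density, kg/m^3.
#' @param cellulose_density particle (cellulose) density, kg/m^3.
#' @param thermal_conductivity W/m/K.
#' @param specific_heat J/kg/K.
#' @param porosity unitless in (0, 1).
#' @param albedo unitless in (0, 1).
#' @param fractional_cover fraction of ground covered, in [0, 1].
#' @return object of class `residue_spec`.
#' @export
residue_spec <- function(residue_type = c("miscanthus", "maize"),
                         thickness = NULL,
                         roughness_length = NULL,
                         bulk_density = NULL,
                         cellulose_density = NULL,
                         thermal_conductivity = NULL,
                         specific_heat = NULL,
                         porosity = NULL,
                         albedo = NULL,
                         fractional_cover = NULL) {
  residue_type <- match.arg(residue_type)
  defaults <- switch(residue_type,
    maize = list(thickness = 0.05, roughness_length = 0.012,
                 bulk_density = 36.4, cellulose_density = 1450,
                 thermal_conductivity = 0.126, specific_heat = 1900,
                 porosity = 0.975, albedo = 0.25, fractional_cover = 0.95),
    miscanthus = list(thickness = 0.05, roughness_length = 0.0065,
                      bulk_density = 22.0, cellulose_density = 1350,
                      thermal_conductivity = 0.08, specific_heat = 1335,
                      porosity = 0.96, albedo = 0.32, fractional_cover = 0.90))
  supplied <- list(thickness = thickness, roughness_length = roughness_length,
                   bulk_density = bulk_density,
                   cellulose_density = cellulose_density,
                   thermal_conductivity = thermal_conductivity,
                   specific_heat = specific_heat, porosity = porosity,
                   albedo = albedo, fractional_cover = fractional_cover)
  spec <- utils::modifyList(defaults, supplied[!vapply(supplied, is.null,
                                                       logical(1))])
  spec$residue_type <- residue_type
  stopifnot(spec$thickness >= 0,
            spec$albedo > 0, spec$albedo < 1,
            spec$bulk_density < spec$cellulose_density,
            spec$porosity > 0, spec$porosity < 1,
            spec$fractional_cover >= 0, spec$fractional_cover <= 1)
  structure(spec, class = "residue_spec")
}

#' Diagnostic: porosity implied by bulk and cellulose density
#'
#' @param spec a [residue_spec()].
#' @return list with the tabulated porosity, the implied
#'   `1 - bulk_density/cellulose_density`, and their difference.
#' @export
residue_porosity_check <- function(spec) {
  stopifnot(inherits(spec, "residue_spec"))
  implied <- 1 - spec$bulk_density / spec$cellulose_density
  list(tabulated = spec$porosity, implied = implied,
       difference = implied - spec$porosity)
}

#' Partition precipitation into rain or snow
#'
#' Precipitation is snow when the air temperature is at or below 1.1 deg C
#' (the boundary value itself is assigned to the frozen phase).
#'
#' @param air_temp air temperature(s), deg C.
#' @return character vector, `"snow"` or `"rain"`.
#' @export
partition_precipitation <- function(air_temp) {
  ifelse(air_temp <= 1.1, "snow", "rain")
}

#' Bulk snowpack state
#'
#' Single bulk layer with constant density: depth is slaved to snow water
#' equivalent (SWE), fractional cover ramps linearly to 1 at `d_full`.
#'
#' @param swe_mm snow water equivalent, mm (= kg/m^2).
#' @param bulk_temp bulk snow temperature, deg C (<= 0 whenever swe > 0).
#' @param rho_snow constant snow density, kg/m^3.
#' @param d_full depth of full fractional cover, m.
#' @return object of class `snow_state` with derived `depth_m` and
#'   `frac_cover`.
#' @export
snow_state <- function(swe_mm = 0, bulk_temp = 0, rho_snow = 250,
                       d_full = 0.05) {
  stopifnot(swe_mm >= 0, rho_snow > 0)
  if (swe_mm > 0 && bulk_temp > 0) stop("bulk_temp must be <= 0 when swe > 0")
  depth <- swe_mm / rho_snow      # mm (kg/m^2) / (kg/m^3) = m
  structure(list(swe = swe_mm,
                 bulk_temp = if (swe_mm > 0) bulk_temp else 0,
                 rho_snow = rho_snow, d_full = d_full,
                 depth_m = depth,
                 frac_cover = min(1, depth / d_full)),
            class = "snow_state")
}

#' Update the snowpack for one time step
#'
#' Snowfall adds SWE (new snow arrives at `min(air_temp, 0)` and mixes into
#' the bulk temperature by mass). Positive surface energy first warms the
#' bulk temperature to 0 deg C, then melts at 334 kJ/kg; negative energy
#' cools the pack. Melt water is routed to infiltration (reported as an
#' attribute); SWE never goes negative. Rain passes through the pack.
#'
#' @param state a [snow_state()].
#' @param forcing list or one-row data.frame with `air_temp` (deg C),
#'   `precip_mm`, and optionally `precip_snow` (logical; defaults to the
#'   1.1 deg C partition).
#' @param surface_energy net energy into the pack, W/m^2.
#' @param dt time step, h (> 0).
#' @return updated `snow_state`; attributes `melt_mm` and `rain_through_mm`.
#' @export
update_snowpack <- function(state, forcing = list(air_temp = 0, precip_mm = 0),
                            surface_energy = 0, dt = 1) {
  stopifnot(inherits(state, "snow_state"))
  if (dt <= 0) stop("dt must be positive")
  L_F <- 334000; CP_ICE <- 2100
  swe <- state$swe; tb <- state$bulk_temp
  p <- forcing$precip_mm %||% 0
  snow_phase <- forcing$precip_snow %||%
    (partition_precipitation(forcing$air_temp) == "snow")
  rain_through <- 0
  if (p > 0) {
    if (snow_phase) {
      tnew <- min(forcing$air_temp, 0)
      tb <- if (swe + p > 0) (swe * tb + p * tnew) / (swe + p) else 0
      swe <- swe + p
    } else rain_through <- p
  }
  melt <- 0
  e <- surface_energy * dt * 3600     # J/m^2
  if (swe > 0 && e != 0) {
    if (e > 0) {
      warm <- -tb * CP_ICE * swe      # energy to reach 0 C
      if (e <= warm) {
        tb <- tb + e / (CP_ICE * swe)
      } else {
        tb <- 0
        melt <- min(swe, (e - warm) / L_F)
        swe <- swe - melt
      }
    } else {
      tb <- tb + e / (CP_ICE * swe)
    }
  }
  if (swe <= 0) { swe <- 0; tb <- 0 }
  out <- snow_state(swe, tb, state$rho_snow, state$d_full)
  attr(out, "melt_mm") <- melt
  attr(out, "rain_through_mm") <- rain_through
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thermal properties of the bulk snowpack
#'
#' Conductivity follows the Yen (1981) density power law
#' `k = 2.22362 (rho/1000)^1.885`; with constant density the conductivity is
#' constant. Volumetric heat capacity is `rho_snow` times the specific heat
#' of ice (2100 J/kg/K).
#'
#' @param state a [snow_state()] (or a list with `rho_snow` and `swe`).
#' @return list with `conductivity` (W/m/K), `heat_capacity` (J/m^3/K), and
#'   `present` (FALSE when swe = 0, meaning the slab is omitted from the
#'   conduction stack).
#' @export
snow_thermal_properties <- function(state) {
  list(conductivity = cpp_snow_conductivity(state$rho_snow),
       heat_capacity = state$rho_snow * 2100,
       present = state$swe > 0)
}

#' Thermal properties of a residue layer
#'
#' Conductivity is taken directly from the spec; volumetric heat capacity is
#' bulk density times specific heat.
#'
#' @param spec a [residue_spec()].
#' @return list with `conductivity` (W/m/K), `heat_capacity` (J/m^3/K), and
#'   `present` (FALSE when thickness = 0).
#' @export
residue_thermal_properties <- function(spec) {
  stopifnot(inherits(spec, "residue_spec"))
  list(conductivity = spec$thermal_conductivity,
       heat_capacity = spec$bulk_density * spec$specific_heat,
       present = spec$thickness > 0)
}

#' Area-weighted composite surface albedo
#'
#' The snow-covered fraction takes the snow albedo; the remaining fraction
#' takes `fractional_cover` times the residue albedo plus the bare fraction
#' times the soil albedo. The result is a convex combination of its
#' components.
#'
#' @param soil_albedo bare-soil albedo, in (0, 1).
#' @param residue a [residue_spec()] or `NULL` when absent.
#' @param snow a [snow_state()] or `NULL`; `snow_albedo` is its reflectance.
#' @param snow_albedo snow albedo, in (0, 1).
#' @return composite albedo, in (0, 1).
#' @export
composite_albedo <- function(soil_albedo, residue = NULL, snow = NULL,
                             snow_albedo = 0.75) {
  stopifnot(soil_albedo > 0, soil_albedo < 1)
  fsnow <- if (is.null(snow)) 0 else snow$frac_cover
  ground <- if (is.null(residue) || residue$thickness <= 0) soil_albedo
  else residue$fractional_cover * residue$albedo +
    (1 - residue$fractional_cover) * soil_albedo
  fsnow * snow_albedo + (1 - fsnow) * ground
}

#' Above-ground biomass required for a given thatch thickness
#'
#' A prostrate layer of bulk density `rho` (kg/m^3) and thickness `t` (cm)
#' over one hectare weighs `rho * t/100 * 10^4` kg = `rho * t / 10` Mg.
#' With the default miscanthus straw bulk density of 22 kg/m^3 this gives
#' 2.2 Mg/ha per cm of thatch depth.
#'
#' @param bulk_density residue bulk density, kg/m^3 (>= 0).
#' @param thickness thatch depth, cm (>= 0).
#' @return biomass, Mg/ha.
#' @export
thatch_mass_for_thickness <- function(bulk_density, thickness) {
  stopifnot(all(bulk_density >= 0), all(thickness >= 0))
  bulk_density * thickness / 10
}
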