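# Hourly surface energy balance and 1-D heat conduction through the
# snow-residue-soil slab stack. Thin wrappers over the compiled step
# functions that the scenario engine also uses.

#' Build a conduction stack of slabs
#'
#' A stack is an ordered set of horizontal slabs (top first): optional snow,
#' optional residue, then soil layers. Interface conductances are series
#' combinations of the half-slab resistances (harmonic means). Soil slabs
#' (`is_soil = TRUE`) carry freezable water `theta` and exchange latent heat
#' when crossing the freezing range.
#'
#' @param thickness_m slab thicknesses, m (> 0).
#' @param conductivity slab conductivities, W/m/K.
#' @param heat_capacity sensible volumetric heat capacities, J/m^3/K (for
#'   soil slabs: the solids + air contribution; water/ice heat is added from
#'   `theta` internally).
#' @param temperature slab temperatures, deg C.
#' @param is_soil logical per slab (recycled).
#' @param theta freezable volumetric water per slab (recycled; ignored for
#'   non-soil slabs).
#' @return data.frame of class `conduction_stack`.
#' @export
conduction_stack <- function(thickness_m, conductivity, heat_capacity,
                             temperature, is_soil = FALSE, theta = 0) {
  n <- length(thickness_m)
  stopifnot(all(thickness_m > 0), all(conductivity > 0),
            all(heat_capacity > 0),
            length(conductivity) == n, length(heat_capacity) == n,
            length(temperature) == n)
  structure(data.frame(thickness_m = thickness_m,
                       conductivity = conductivity,
                       heat_capacity = heat_capacity,
                       temperature = temperature,
                       is_soil = rep_len(is_soil, n),
                       theta = rep_len(theta, n)),
            class = c("conduction_stack", "data.frame"))
}

#' Surface energy balance at the top of the stack
#'
#' Solves for the skin temperature that closes
#' `net_shortwave + net_longwave - sensible - latent - ground_heat_flux = 0`
#' by bounded bisection (residual below 0.1 W/m^2 at convergence, enforced
#' to 1e-6). Sensible and latent fluxes use neutral bulk aerodynamic
#' formulas with the given roughness length; the ground heat flux couples
#' the skin to the top slab through the half-slab conductance. Latent heat
#' is suppressed over snow or a frozen surface and scaled by a soil-moisture
#' beta otherwise.
#'
#' @param forcing list or one-row data.frame with `air_temp` (deg C),
#'   `shortwave` and `longwave_down` (W/m^2), `rel_humidity` (percent),
#'   `wind` (m/s).
#' @param albedo surface albedo, in (0, 1).
#' @param roughness_length aerodynamic roughness, m.
#' @param top_slab list with `conductivity` (W/m/K), `thickness_m`, and
#'   `temperature` (deg C) of the uppermost slab.
#' @param latent_on logical; enable latent heat flux.
#' @param beta soil-moisture availability factor in [0, 1] for latent heat.
#' @param emissivity surface emissivity.
#' @param zref reference height of wind/temperature forcing, m.
#' @return list of class `surface_energy_result`: `skin_temp`,
#'   `net_shortwave`, `net_longwave`, `sensible`, `latent`,
#'   `ground_heat_flux` (positive downward), `residual`.
#' @export
surface_energy_balance <- function(forcing, albedo, roughness_length,
                                   top_slab, latent_on = FALSE, beta = 1,
                                   emissivity = 0.98, zref = 10) {
  g_cond <- top_slab$conductivity / (0.5 * top_slab$thickness_m)
  res <- cpp_surface_energy_balance(
    forcing$shortwave, forcing$longwave_down, forcing$air_temp,
    forcing$rel_humidity, forcing$wind, albedo, roughness_length,
    emissivity, g_cond, top_slab$temperature, latent_on, beta, zref)
  structure(res, class = "surface_energy_result")
}

#' Advance the stack one conduction time step
#'
#' Unconditionally stable implicit (backward Euler) step with
#' enthalpy-conserving apparent heat capacity on soil slabs crossing the
#' freezing range (range width `delta_tf` below 0 deg C). The lower boundary
#' is zero-flux unless `bottom_temp` is given (Dirichlet test mode, so
#' analytic steady-state oracles are expressible); the upper boundary is a
#' prescribed flux unless `top_temp` is given.
#'
#' @param stack a [conduction_stack()].
#' @param dt time step, h (> 0).
#' @param flux_top prescribed downward surface flux, W/m^2 (ignored when
#'   `top_temp` is given).
#' @param top_temp optional Dirichlet skin temperature, deg C.
#' @param bottom_temp optional Dirichlet bottom temperature, deg C.
#' @param delta_tf freezing-range width, deg C.
#' @return the updated stack; attributes `flux_top`, `flux_bottom`,
#'   `energy_change` (J/m^2), `closure_error` (J/m^2), `liquid_fraction`.
#' @export
step_heat_conduction <- function(stack, dt, flux_top = 0, top_temp = NULL,
                                 bottom_temp = NULL, delta_tf = 0.5) {
  stopifnot(inherits(stack, "conduction_stack"))
  if (dt <= 0) stop("dt must be positive")
  res <- cpp_step_conduction(
    stack$thickness_m, stack$conductivity, stack$heat_capacity,
    stack$temperature, stack$is_soil, stack$theta,
    dt * 3600, delta_tf,
    if (is.null(top_temp)) 0L else 1L, flux_top,
    if (is.null(top_temp)) 0 else top_temp,
    if (is.null(bottom_temp)) 0L else 1L,
    if (is.null(bottom_temp)) 0 else bottom_temp)
  out <- stack
  out$temperature <- res$temp
  attr(out, "flux_top") <- res$flux_top
  attr(out, "flux_bottom") <- res$flux_bottom
  attr(out, "energy_change") <- res$energy_change
  attr(out, "closure_error") <- res$closure_error
  attr(out, "liquid_fraction") <- res$liquid_fraction
  out
}

#' Interpolate the soil temperature at a given depth
#'
#' Linear interpolation between the bracketing soil node temperatures (nodes
#' at soil-layer midpoints: 2.5, 7.5, 15, 25, 35, 50, 70, 90, 125, 175,
#' 225 cm on the standard grid). Snow and residue slabs are excluded from
#' the soil depth coordinate; depths above the first node or below the last
#' take the nearest node value.
#'
#' @param stack a [conduction_stack()] containing soil slabs, or a numeric
#'   vector of 11 soil-layer temperatures on the standard grid.
#' @param depth probe depth, cm, in [0, 250].
#' @return temperature, deg C.
#' @export
temperature_at_depth <- function(stack, depth) {
  if (any(depth < 0 | depth > 250)) stop("depth must be within [0, 250] cm")
  if (inherits(stack, "conduction_stack")) {
    soil <- stack[stack$is_soil, ]
    if (nrow(soil) == 0) stop("stack contains no soil slabs")
    thick_cm <- soil$thickness_m * 100
    nodes <- cumsum(thick_cm) - thick_cm / 2
    temps <- soil$temperature
  } else {
    stopifnot(length(stack) == 11)
    nodes <- cumsum(.SOIL_THICK_CM) - .SOIL_THICK_CM / 2
    temps <- stack
  }
  vapply(depth, function(d) {
    if (d <= nodes[1]) return(temps[1])
    if (d >= nodes[length(nodes)]) return(temps[length(temps)])
    i <- findInterval(d, nodes)
    w <- (d - nodes[i]) / (nodes[i + 1] - nodes[i])
    temps[i] * (1 - w) + temps[i + 1] * w
  }, numeric(1))
}
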