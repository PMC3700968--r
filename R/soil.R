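# Soil column: 11-layer grid, texture look-up, bucket moisture accounting,
# moisture/ice-dependent thermal properties, and freeze/thaw partitioning.

# layer thicknesses, cm, fixed
.SOIL_THICK_CM <- c(5, 5, 10, 10, 10, 20, 20, 20, 50, 50, 50)

.texture_cache <- new.env(parent = emptyenv())

#' Soil texture parameter look-up table
#'
#' Hydraulic and thermal parameters for the 11 USDA texture classes, from
#' the standard Clapp-Hornberger/Campbell parameter set (porosity, air-entry
#' potential, Campbell b, saturated conductivity), with field capacity and
#' wilting point evaluated from the Campbell retention curve at -33 and
#' -1500 kPa, and Johansen dry conductivity from bulk density. Shipped as a
#' CSV in `extdata` so users can substitute their own values.
#'
#' @return data.frame, one row per texture class.
#' @export
soil_texture_table <- function() {
  if (is.null(.texture_cache$tab)) {
    path <- system.file("extdata", "soil_textures.csv", package = "frosthatch")
    .texture_cache$tab <- read.csv(path, stringsAsFactors = FALSE)
  }
  .texture_cache$tab
}

#' Look up the parameter bundle for one texture class
#'
#' @param texture_class one of the 11 USDA-style class labels in
#'   `soil_texture_table()$texture_class`.
#' @return an object of class `soil_texture_params`: a list with fields
#'   `texture_class`, `porosity`, `field_capacity`, `wilting_point`,
#'   `sat_hydraulic_conductivity` (mm/h), `air_entry_potential` (kPa),
#'   `campbell_b`, `dry_conductivity` (W/m/K), `solids_conductivity`
#'   (W/m/K), `solids_heat_capacity` (J/m^3/K).
#' @export
texture_lookup <- function(texture_class) {
  tab <- soil_texture_table()
  i <- match(texture_class, tab$texture_class)
  if (is.na(i))
    stop("unknown texture class '", texture_class, "'; valid classes: ",
         paste(tab$texture_class, collapse = ", "))
  structure(list(texture_class = tab$texture_class[i],
                 porosity = tab$porosity[i],
                 field_capacity = tab$field_capacity[i],
                 wilting_point = tab$wilting_point[i],
                 sat_hydraulic_conductivity = tab$sat_hydraulic_conductivity_mm_h[i],
                 air_entry_potential = tab$air_entry_potential_kpa[i],
                 campbell_b = tab$campbell_b[i],
                 dry_conductivity = tab$dry_conductivity_w_m_k[i],
                 solids_conductivity = tab$solids_conductivity_w_m_k[i],
                 solids_heat_capacity = tab$solids_heat_capacity_j_m3_k[i]),
            class = "soil_texture_params")
}

#' The 11-layer soil grid to 250 cm
#'
#' Layer thicknesses are fixed at 5, 5, 10, 10, 10, 20, 20, 20, 50, 50,
#' 50 cm (250 cm total); nodes sit at layer midpoints.
#'
#' @param texture a single texture class label applied to all layers, or a
#'   vector of 11 labels (one per layer).
#' @return object of class `soil_grid`: list with `layer_thicknesses_cm`,
#'   `node_depths_cm`, `texture_by_layer`, and per-layer parameter vectors.
#' @export
soil_grid <- function(texture = "loam") {
  tex <- if (length(texture) == 1) rep(texture, 11) else texture
  if (length(tex) != 11) stop("texture must have length 1 or 11")
  params <- lapply(tex, texture_lookup)
  pick <- function(f) vapply(params, `[[`, numeric(1), f)
  thick <- .SOIL_THICK_CM
  structure(list(
    layer_thicknesses_cm = thick,
    node_depths_cm = cumsum(thick) - thick / 2,
    texture_by_layer = tex,
    porosity = pick("porosity"),
    field_capacity = pick("field_capacity"),
    wilting_point = pick("wilting_point"),
    dry_conductivity = pick("dry_conductivity"),
    solids_conductivity = pick("solids_conductivity"),
    solids_heat_capacity = pick("solids_heat_capacity")),
    class = "soil_grid")
}

#' Soil thermal conductivity and volumetric heat capacity
#'
#' Johansen-style interpolation between dry and saturated conductivities
#' with a Kersten number (logarithmic unfrozen, linear frozen, blended by
#' the liquid/ice ratio); volumetric heat capacity is the volume-weighted
#' sum of solids, liquid water (4.18 MJ/m^3/K), ice (1.9 MJ/m^3/K) and air.
#'
#' @param layer_params a `soil_texture_params` object.
#' @param liquid,ice volumetric contents, m^3/m^3 (`liquid + ice` must not
#'   exceed porosity).
#' @return list with `conductivity` (W/m/K) and `heat_capacity` (J/m^3/K).
#' @export
soil_thermal_properties <- function(layer_params, liquid, ice) {
  stopifnot(inherits(layer_params, "soil_texture_params"))
  cpp_soil_thermal_properties(liquid, ice, layer_params$porosity,
                              layer_params$dry_conductivity,
                              layer_params$solids_conductivity,
                              layer_params$solids_heat_capacity)
}

#' Initial soil column state
#'
#' Default initial condition: uniform temperature (typically the site annual
#' mean), moisture at field capacity, no ice.
#'
#' @param grid a [soil_grid()].
#' @param mean_temp initial uniform temperature, deg C.
#' @return list of class `soil_column_state` with `temperature`, `liquid`,
#'   `ice` (length-11 vectors).
#' @export
initial_soil_state <- function(grid, mean_temp = 8) {
  stopifnot(inherits(grid, "soil_grid"))
  structure(list(temperature = rep(mean_temp, 11),
                 liquid = grid$field_capacity,
                 ice = rep(0, 11)),
            class = "soil_column_state")
}

#' Update soil moisture with a field-capacity cascade bucket
#'
#' Infiltration fills each layer to field capacity (capped by air-filled
#' porosity) and the excess cascades downward; water passing the bottom
#' layer leaves as drainage. Frozen layers accept no infiltration (water
#' reaching one becomes runoff). Evaporation is drawn from the top layer,
#' floored at its wilting point. Water is conserved exactly:
#' storage change = infiltration - runoff - evaporation - drainage.
#'
#' @param state a `soil_column_state`.
#' @param grid a [soil_grid()].
#' @param infiltration water arriving at the soil surface, mm (>= 0).
#' @param surface_evap evaporative demand, mm (>= 0).
#' @param dt time step, h (> 0; the bucket itself is instantaneous).
#' @return updated `soil_column_state`; attributes `evap_actual`,
#'   `drainage`, `runoff`, `storage_change_mm`, `closure_error_mm`.
#' @export
update_soil_moisture <- function(state, grid, infiltration, surface_evap,
                                 dt = 24) {
  stopifnot(inherits(state, "soil_column_state"), inherits(grid, "soil_grid"))
  if (dt <= 0) stop("dt must be positive")
  if (infiltration < 0 || surface_evap < 0)
    stop("infiltration and surface_evap must be >= 0")
  res <- cpp_bucket_update(state$liquid, state$ice,
                           grid$layer_thicknesses_cm / 100,
                           grid$porosity, grid$field_capacity,
                           grid$wilting_point, infiltration, surface_evap)
  out <- state
  out$liquid <- res$liquid
  attr(out, "evap_actual") <- res$evap_actual
  attr(out, "drainage") <- res$drainage
  attr(out, "runoff") <- res$runoff
  attr(out, "storage_change_mm") <- res$storage_change_mm
  attr(out, "closure_error_mm") <- res$closure_error_mm
  out
}

#' Column water storage, mm
#'
#' @param state a `soil_column_state`.
#' @param grid a [soil_grid()].
#' @return total liquid + ice storage in mm of water.
#' @export
column_water_mm <- function(state, grid) {
  sum((state$liquid + state$ice) * grid$layer_thicknesses_cm / 100 * 1000)
}

#' Apply an energy residual to one layer with freeze/thaw partitioning
#'
#' Latent heat (334 kJ/kg) is exchanged as water changes phase; total water
#' mass is conserved exactly, and the temperature is held inside the
#' freezing range `[-delta_tf, 0]` deg C while both phases coexist
#' (apparent-heat-capacity treatment; the phase split is the equilibrium one
#' for the resulting temperature).
#'
#' @param layer_temp layer temperature, deg C.
#' @param liquid,ice volumetric contents, m^3/m^3.
#' @param energy_residual energy applied to the layer, J/m^2 (negative =
#'   cooling).
#' @param layer_params a `soil_texture_params` (for sensible heat capacity).
#' @param dz layer thickness, m.
#' @param delta_tf width of the freezing range, deg C.
#' @return list with `liquid`, `ice`, `temp`.
#' @export
freeze_thaw_partition <- function(layer_temp, liquid, ice, energy_residual,
                                  layer_params = texture_lookup("loam"),
                                  dz = 0.05, delta_tf = 0.5) {
  theta <- liquid + ice
  c_base <- layer_params$solids_heat_capacity * (1 - layer_params$porosity) +
    1212 * (layer_params$porosity - theta)
  res <- cpp_apply_energy_layer(layer_temp, liquid, ice, energy_residual,
                                c_base, dz, delta_tf)
  list(liquid = res$liquid, ice = res$ice, temp = res$temp)
}
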