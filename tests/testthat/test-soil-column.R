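# Soil column: texture look-up, thermal mixing model, bucket hydrology,
# freeze/thaw energy accounting.

test_that("texture table encodes the expected qualitative orderings", {
  sand <- texture_lookup("sand")
  clay <- texture_lookup("clay")
  expect_lt(sand$porosity, clay$porosity)
  expect_gt(sand$sat_hydraulic_conductivity, clay$sat_hydraulic_conductivity)
  for (cls in soil_texture_table()$texture_class) {
    p <- texture_lookup(cls)
    expect_lt(p$wilting_point, p$field_capacity)
    expect_lt(p$field_capacity, p$porosity)
    expect_lt(p$porosity, 1)
    expect_gt(p$campbell_b, 0)
  }
  expect_identical(texture_lookup("loam"), texture_lookup("loam"))
})

test_that("unknown texture labels are rejected with the valid list", {
  expect_error(texture_lookup("peat"), "sand")
})

test_that("the soil grid covers 250 cm with increasing node depths", {
  g <- soil_grid("silt loam")
  expect_equal(sum(g$layer_thicknesses_cm), 250)
  expect_equal(g$layer_thicknesses_cm, c(5, 5, 10, 10, 10, 20, 20, 20, 50, 50, 50))
  expect_true(all(diff(g$node_depths_cm) > 0))
  expect_equal(g$node_depths_cm[2], 7.5)
  expect_error(soil_grid(rep("loam", 7)), "length")
})

test_that("dry soil takes the tabulated dry conductivity and solids+air capacity", {
  p <- texture_lookup("loam")
  tp <- soil_thermal_properties(p, 0, 0)
  expect_equal(tp$conductivity, p$dry_conductivity)
  expect_equal(tp$heat_capacity,
               p$solids_heat_capacity * (1 - p$porosity) + 1212 * p$porosity)
})

test_that("conductivity rises with water content and more with ice", {
  p <- texture_lookup("loam")
  k10 <- soil_thermal_properties(p, 0.10, 0)$conductivity
  k30 <- soil_thermal_properties(p, 0.30, 0)$conductivity
  expect_gt(k30, k10)
  k_ice <- soil_thermal_properties(p, 0, 0.30)$conductivity
  expect_gt(k_ice, k30)
})

test_that("saturated sand matches a hand evaluation of the mixing formula", {
  p <- texture_lookup("sand")
  phi <- p$porosity
  tp <- soil_thermal_properties(p, phi, 0)
  # Johansen: saturated, unfrozen -> Kersten number 1, geometric-mean k_sat
  k_sat <- p$solids_conductivity^(1 - phi) * 0.57^phi
  expect_equal(tp$conductivity, p$dry_conductivity + 1 * (k_sat - p$dry_conductivity),
               tolerance = 1e-12)
  expect_equal(tp$heat_capacity,
               p$solids_heat_capacity * (1 - phi) + 4.18e6 * phi,
               tolerance = 1e-12)
})

test_that("thermal properties are monotone in total water at fixed phase ratio", {
  set.seed(31)
  for (cls in c("sand", "loam", "clay")) {
    p <- texture_lookup(cls)
    for (fl in c(1, 0.5, 0)) {
      theta <- sort(runif(20, 0.01, p$porosity))
      k <- vapply(theta, function(th)
        soil_thermal_properties(p, th * fl, th * (1 - fl))$conductivity,
        numeric(1))
      expect_true(all(diff(k) >= -1e-12))
    }
  }
})

test_that("supersaturation and negative contents are rejected", {
  p <- texture_lookup("loam")
  expect_error(soil_thermal_properties(p, 0.4, 0.2), "porosity")
  expect_error(soil_thermal_properties(p, -0.1, 0), "negative")
})

test_that("the bucket is inert at field capacity with no forcing", {
  g <- soil_grid("loam")
  s <- initial_soil_state(g, 8)
  s2 <- update_soil_moisture(s, g, 0, 0)
  expect_equal(s2$liquid, s$liquid)
  expect_equal(attr(s2, "closure_error_mm"), 0)
})

test_that("small infiltration stays in the top layer; excess cascades with exact mass balance", {
  g <- soil_grid("loam")
  s <- initial_soil_state(g, 8)
  s$liquid <- g$wilting_point           # dry column
  s2 <- update_soil_moisture(s, g, 3, 0)
  expect_equal((s2$liquid[1] - s$liquid[1]) * 50, 3, tolerance = 1e-9)
  expect_equal(s2$liquid[-1], s$liquid[-1])

  s3 <- update_soil_moisture(s, g, 30, 0)
  gain <- column_water_mm(s3, g) - column_water_mm(s, g)
  expect_equal(gain + attr(s3, "drainage") + attr(s3, "runoff"), 30,
               tolerance = 1e-6)
  expect_gt(s3$liquid[2], s$liquid[2])  # cascade reached layer 2
  expect_lte(abs(attr(s3, "closure_error_mm")), 1e-6)
})

test_that("frozen layers accept no infiltration", {
  g <- soil_grid("loam")
  s <- initial_soil_state(g, 0)
  s$ice[1] <- 0.05
  s2 <- update_soil_moisture(s, g, 10, 0)
  expect_equal(attr(s2, "runoff"), 10)
  expect_equal(s2$liquid, s$liquid)
})

test_that("evaporation is floored at the wilting point", {
  g <- soil_grid("loam")
  s <- initial_soil_state(g, 8)
  avail <- (s$liquid[1] - g$wilting_point[1]) * 50
  s2 <- update_soil_moisture(s, g, 0, avail + 5)
  expect_equal(attr(s2, "evap_actual"), avail, tolerance = 1e-9)
  expect_equal(s2$liquid[1], g$wilting_point[1], tolerance = 1e-12)
})

test_that("invalid bucket arguments are rejected", {
  g <- soil_grid("loam")
  s <- initial_soil_state(g, 8)
  expect_error(update_soil_moisture(s, g, 1, 0, dt = 0), "dt")
  expect_error(update_soil_moisture(s, g, -1, 0), ">= 0")
})

test_that("cooling a dry layer is purely sensible", {
  p <- texture_lookup("loam")
  c_base <- p$solids_heat_capacity * (1 - p$porosity) + 1212 * p$porosity
  e <- -50000
  r <- freeze_thaw_partition(2, 0, 0, e, p, dz = 0.05)
  expect_equal(r$temp, 2 + e / (c_base * 0.05), tolerance = 1e-9)
  expect_equal(r$ice, 0)
})

test_that("extracting exactly the freezing enthalpy freezes all liquid at the range bottom", {
  p <- texture_lookup("loam")
  theta <- 0.3; dz <- 0.05; dTf <- 0.5
  c_base <- p$solids_heat_capacity * (1 - p$porosity) + 1212 * (p$porosity - theta)
  # independent energy budget: latent L*rho*theta*dz dominates (>99%), plus
  # the sensible term to reach the range bottom with fully frozen capacity
  latent <- 334000 * 1000 * theta * dz
  sensible <- (c_base + theta * 1.9e6) * dz * dTf
  expect_gt(latent / (latent + sensible), 0.95)
  r <- freeze_thaw_partition(0, theta, 0, -(latent + sensible), p, dz = dz,
                             delta_tf = dTf)
  expect_equal(r$ice, theta, tolerance = 1e-9)
  expect_equal(r$liquid, 0, tolerance = 1e-9)
  expect_equal(r$temp, -dTf, tolerance = 1e-9)
})

test_that("freeze then thaw with equal energy is reversible and conserves mass", {
  p <- texture_lookup("silt loam")
  e <- -2e6
  a <- freeze_thaw_partition(0.2, 0.30, 0, e, p)
  expect_equal(a$liquid + a$ice, 0.30, tolerance = 1e-12)
  expect_gt(a$ice, 0)                       # latent exchange happened
  expect_gte(a$temp, -0.5 - 1e-9)           # held inside the freezing range
  expect_lte(a$temp, 0)
  b <- freeze_thaw_partition(a$temp, a$liquid, a$ice, -e, p)
  expect_equal(b$temp, 0.2, tolerance = 1e-9)
  expect_equal(b$liquid, 0.30, tolerance = 1e-9)
  expect_equal(b$ice, 0, tolerance = 1e-9)
})

test_that("phase partition never creates negative contents on random states", {
  set.seed(77)
  p <- texture_lookup("loam")
  for (i in 1:50) {
    theta <- runif(1, 0, p$porosity)
    liq <- runif(1, 0, theta)
    r <- freeze_thaw_partition(runif(1, -3, 3), liq, theta - liq,
                               runif(1, -5e6, 5e6), p)
    expect_gte(r$liquid, -1e-12)
    expect_gte(r$ice, -1e-12)
    expect_equal(r$liquid + r$ice, theta, tolerance = 1e-9)
  }
})
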