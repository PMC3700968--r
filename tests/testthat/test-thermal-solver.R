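# Surface energy balance and implicit conduction: analytic oracles
# (resistance network, damping depth), equilibria, zero-curtain.

test_that("net shortwave is (1 - albedo) * S", {
  f <- list(air_temp = 5, shortwave = 500, longwave_down = 300,
            rel_humidity = 60, wind = 3)
  top <- list(conductivity = 1, thickness_m = 0.05, temperature = 5)
  r <- surface_energy_balance(f, albedo = 0.25, roughness_length = 0.01, top)
  expect_equal(r$net_shortwave, 375)
  expect_lt(abs(r$residual), 0.1)
})

test_that("a radiatively balanced calm night is in equilibrium", {
  ta <- -3
  lwd <- 5.670374419e-8 * (ta + 273.15)^4   # emissivity-balanced sky
  f <- list(air_temp = ta, shortwave = 0, longwave_down = lwd,
            rel_humidity = 70, wind = 0)
  top <- list(conductivity = 1, thickness_m = 0.05, temperature = ta)
  r <- surface_energy_balance(f, albedo = 0.2, roughness_length = 0.01, top)
  expect_equal(r$skin_temp, ta, tolerance = 1e-4)
  expect_lt(abs(r$sensible), 0.01)
  expect_lt(abs(r$ground_heat_flux), 0.01)
})

test_that("higher albedo reduces the daily-mean ground heat flux", {
  # oracle = two full balance evaluations over a fixed diurnal cycle
  top <- list(conductivity = 1, thickness_m = 0.05, temperature = 2)
  g_mean <- function(albedo) {
    g <- 0
    for (h in 0:23) {
      sw <- max(0, 600 * sin(pi * (h - 6) / 12))
      f <- list(air_temp = 2 + 5 * sin(pi * (h - 9) / 12), shortwave = sw,
                longwave_down = 300, rel_humidity = 70, wind = 3)
      g <- g + surface_energy_balance(f, albedo, 0.01, top)$ground_heat_flux
    }
    g / 24
  }
  expect_gt(g_mean(0.15), g_mean(0.50))
})

test_that("invalid surface-balance inputs are rejected", {
  f <- list(air_temp = 0, shortwave = 0, longwave_down = 300,
            rel_humidity = 70, wind = -1)
  top <- list(conductivity = 1, thickness_m = 0.05, temperature = 0)
  expect_error(surface_energy_balance(f, 0.2, 0.01, top), "wind")
  f$wind <- 3
  expect_error(surface_energy_balance(f, 1.5, 0.01, top), "albedo")
})

test_that("a uniform stack with zero boundary fluxes does not drift", {
  st <- uniform_stack(temp = 10)
  st2 <- step_heat_conduction(st, dt = 1, flux_top = 0)
  expect_equal(st2$temperature, rep(10, 11), tolerance = 1e-12)
  expect_lt(abs(attr(st2, "closure_error")), 1e-6)
})

test_that("steady state under Dirichlet ends matches the resistance-network closed form", {
  # heterogeneous multi-slab stack: snow-like, residue-like, soil layers
  thick <- c(0.10, 0.05, 0.05, 0.05, 0.10, 0.10, 0.20, 0.50)
  k <- c(0.13, 0.08, 1.2, 1.2, 1.0, 0.9, 1.4, 1.6)
  st <- conduction_stack(thick, k, rep(2e6, 8), rep(5, 8))
  t_top <- 0; t_bot <- 10
  for (i in 1:60) st <- step_heat_conduction(st, dt = 1e5, top_temp = t_top,
                                             bottom_temp = t_bot)
  # closed form: series resistances from the top surface to each node
  r_half <- 0.5 * thick / k
  r_interfaces <- c(r_half[1], r_half[-length(r_half)] + r_half[-1],
                    r_half[length(r_half)])
  r_total <- sum(r_interfaces)
  q <- (t_bot - t_top) / r_total
  t_expect <- t_top + q * cumsum(r_interfaces)[seq_along(thick)]
  expect_equal(st$temperature, t_expect, tolerance = 1e-6)
})

test_that("a sinusoidal surface wave decays with the analytic damping depth", {
  # homogeneous unfrozen column, 16-day period resolved by the grid
  kc <- 1; cc <- 2e6
  st <- conduction_stack(rep(0.05, 50), rep(kc, 50), rep(cc, 50), rep(10, 50))
  period_h <- 16 * 24
  omega <- 2 * pi / (period_h * 3600)
  d <- sqrt(2 * (kc / cc) / omega)
  n_per <- 6
  temps <- matrix(NA_real_, period_h, 4)
  for (cyc in 1:n_per) for (h in 1:period_h) {
    st <- step_heat_conduction(st, dt = 1,
                               top_temp = 10 + 5 * sin(omega * 3600 *
                                                       ((cyc - 1) * period_h + h)))
    if (cyc == n_per) temps[h, ] <- st$temperature[c(2, 4, 6, 8)]
  }
  nodes_m <- (cumsum(rep(0.05, 50)) - 0.025)[c(2, 4, 6, 8)]
  amp <- apply(temps, 2, function(x) (max(x) - min(x)) / 2)
  # log-amplitude slope across depth = -1/d within 5 %
  slope <- coef(lm(log(amp) ~ nodes_m))[2]
  expect_equal(unname(slope), -1 / d, tolerance = 0.05)
})

test_that("a freezing wet layer shows the zero-curtain plateau", {
  p <- texture_lookup("loam")
  theta <- 0.30
  c_base <- p$solids_heat_capacity * (1 - p$porosity) + 1212 * (p$porosity - theta)
  st <- conduction_stack(rep(0.05, 4), rep(1.2, 4), rep(c_base, 4),
                         rep(0.5, 4), is_soil = TRUE, theta = theta)
  in_range <- 0; frozen_seen <- FALSE
  for (i in 1:400) {
    st <- step_heat_conduction(st, dt = 1, flux_top = -60)
    lf <- attr(st, "liquid_fraction")[1]
    t1 <- st$temperature[1]
    if (lf > 0 && lf < 1) {
      in_range <- in_range + 1
      expect_gte(t1, -0.5 - 1e-9)   # held inside the freezing range
      expect_lte(t1, 1e-9)
    }
    if (lf == 0) { frozen_seen <- TRUE; break }
  }
  expect_gt(in_range, 20)    # latent-heat plateau lasted many steps
  expect_true(frozen_seen)   # and the layer did eventually freeze through
  expect_lt(st$temperature[1], -0.5 + 1e-6)
})

test_that("conduction conserves energy across phase change", {
  p <- texture_lookup("loam")
  theta <- 0.25
  c_base <- p$solids_heat_capacity * (1 - p$porosity) + 1212 * (p$porosity - theta)
  st <- conduction_stack(rep(0.05, 6), rep(1.2, 6), rep(c_base, 6),
                         c(1, 0.5, 0.2, 0, -0.3, -1), is_soil = TRUE,
                         theta = theta)
  total <- 0
  for (f in c(-150, -80, -20, 30, 90)) {
    st <- step_heat_conduction(st, dt = 1, flux_top = f)
    expect_lt(abs(attr(st, "closure_error")),
              1e-6 * max(1, abs(attr(st, "energy_change"))))
    total <- total + abs(attr(st, "closure_error"))
  }
  expect_lt(total, 1e-3)
})

test_that("temperature_at_depth interpolates between soil nodes", {
  expect_equal(temperature_at_depth(rep(3, 11), 10), 3)
  temps <- rep(0, 11); temps[2] <- -4; temps[3] <- -1
  expect_equal(temperature_at_depth(temps, 10), -4 + (10 - 7.5) / 7.5 * 3)
  expect_equal(temperature_at_depth(temps, 7.5), -4)  # exact node
  expect_error(temperature_at_depth(temps, 260), "depth")
  st <- uniform_stack(temp = 2)
  st$is_soil <- TRUE
  expect_equal(temperature_at_depth(st, 125), 2)
})

test_that("halving the time step barely moves the annual extreme minimum", {
  cfg1 <- short_cold_config(n_years = 2, seed = 5)
  cfg2 <- short_cold_config(n_years = 2, seed = 5, dt_hours = 0.5)
  r1 <- annual_extreme_minima(run_scenario(cfg1))
  r2 <- annual_extreme_minima(run_scenario(cfg2))
  expect_lt(max(abs(r1$extreme_min_t10 - r2$extreme_min_t10)), 0.1)
})
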