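# Shared fixtures: small, fast configurations used across test files.

# a cold-continental short run (4 calendar years -> 3 complete winters)
short_cold_config <- function(scenario = "MAIZE+TILL", n_years = 4, seed = 3,
                              ...) {
  scenario_config(scenario, climate = site_climate("north-plains"),
                  n_years = n_years, seed = seed, ...)
}

# deterministic three-day daily weather frame for disaggregation tests
flat_day <- function(tmax = 5, tmin = 5, precip = 0, solar = 10, rh = 70,
                     wind = 3, doy = 180) {
  data.frame(doy = doy, tmax_c = tmax, tmin_c = tmin, precip_mm = precip,
             rh_pct = rh, wind_ms = wind, solar_mj = solar)
}

# uniform non-freezing soil-like conduction stack
uniform_stack <- function(n = 11, temp = 10, k = 1, C = 2e6, dz = 0.05) {
  conduction_stack(rep(dz, n), rep(k, n), rep(C, n), rep(temp, n))
}
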