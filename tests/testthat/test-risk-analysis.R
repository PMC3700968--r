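# Risk statistics: running means, annual extremes, exceedance counting,
# response curves, bias correction, trends.

test_that("running mean reproduces direct arithmetic", {
  expect_equal(running_mean(c(1, 2, 3))[2], 2)
  expect_equal(running_mean(rep(4.2, 10))[2:9], rep(4.2, 8))
  rm4 <- running_mean(c(0, -6, 0, 0))
  expect_true(all(is.na(rm4[c(1, 4)])))       # boundary days excluded
  expect_equal(rm4[2:3], c(-2, -2))
  # smoothing is more conservative than the raw daily minimum
  expect_gt(min(rm4, na.rm = TRUE), -6)
  expect_equal(running_mean(c(3, 1, 4), window = 1), c(3, 1, 4))
})

test_that("running mean validates its window", {
  expect_error(running_mean(1:10, window = 2), "odd")
  expect_error(running_mean(1:2, window = 3), "length")
})

test_that("annual extremes count complete winter years and locate cold spells", {
  # two complete winter years: Jul year1 .. Jun year3
  n <- 3 * 365
  doy <- rep(1:365, 3); year <- rep(1:3, each = 365)
  t10 <- rep(5, n)
  # one injected cold spell per winter, centred mid-January
  spell1 <- which(year == 2 & doy %in% 10:20)
  spell2 <- which(year == 3 & doy %in% 25:35)
  t10[spell1] <- -8; t10[spell2] <- -5
  daily <- data.frame(year = year, doy = doy, t10cm_daily_mean = t10,
                      date = as.Date("2000-12-31") + seq_len(n))
  rec <- annual_extreme_minima(daily)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$winter_year_label, c(2, 3))
  expect_equal(rec$extreme_min_t10, c(-8, -5))
  expect_true(all(format(rec$date_of_min, "%m") %in% c("01", "02")))
  # empty input -> empty output
  expect_equal(nrow(annual_extreme_minima(daily[0, ])), 0)
})

test_that("annual extremes equal a brute-force recomputation on a long run", {
  out <- run_scenario(short_cold_config(n_years = 6, seed = 17))
  rec <- annual_extreme_minima(out)
  # independent recomputation: explicit 3-day means, explicit winter split
  x <- out$t10cm_daily_mean
  n <- length(x)
  rm3 <- c(NA, (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3, NA)
  wy <- out$year + as.integer(out$doy >= 182)
  brute <- sapply(sort(unique(wy))[table(wy)[as.character(sort(unique(wy)))] >= 363],
                  function(y) min(rm3[wy == y], na.rm = TRUE))
  expect_equal(rec$extreme_min_t10, unname(brute), tolerance = 1e-12)
})

test_that("exceedance counts ties as at-or-below and is threshold-monotone", {
  expect_equal(exceedance_frequency(c(-4, -2, -5, -1), -3.5), 0.5)
  expect_equal(exceedance_frequency(-3.5, threshold_spec(-3.5)), 1.0)
  expect_equal(exceedance_frequency(c(-4, -2), -100), 0.0)
  expect_error(exceedance_frequency(numeric(0), -3.5), "undefined")
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(30, -5, 3)
    th <- sort(runif(2, -10, 0))
    expect_lte(exceedance_frequency(x, th[1]), exceedance_frequency(x, th[2]))
    # brute-force counting oracle
    expect_equal(exceedance_frequency(x, th[1]), sum(x <= th[1]) / 30)
  }
})

test_that("the shipped thresholds are the two rhizome LT50 values", {
  th <- lethal_thresholds()
  expect_equal(vapply(th, `[[`, numeric(1), "value"), c(-3.5, -6.0))
})

test_that("response curve ratios follow the warming map arithmetic", {
  ext <- list("0" = c(-10, -10), "5" = c(-7, -7), "10" = c(-5.8, -5.8),
              "20" = c(-5, -5))
  rc <- response_curve(ext)
  expect_equal(rc$warming_vs_bare, c(0, 3, 4.2, 5))
  expect_equal(rc$fraction_of_max, c(0, 0.6, 0.84, 1.0))
  expect_error(response_curve(list("0" = c(-10, -9))), "two non-zero")
  expect_error(response_curve(list("5" = -7, "10" = -6)), "reference")
  flat <- list("0" = c(-5, -5), "5" = c(-5, -5), "10" = c(-5, -5))
  expect_warning(rcf <- response_curve(flat), "undefined")
  expect_true(all(is.na(rcf$fraction_of_max)))
})

test_that("bias correction recovers exact relations", {
  sim <- seq(-12, -2, length.out = 25)
  m_id <- fit_bias_correction(sim, sim)
  expect_equal(unname(coef(m_id)), c(0, 1, 0), tolerance = 1e-8)
  obs <- 0.02 * sim^2 + 1.15 * sim + 0.8
  m <- fit_bias_correction(sim, obs)
  expect_equal(unname(coef(m)), c(0.02, 1.15, 0.8), tolerance = 1e-6)
  expect_equal(apply_bias_correction(m, sim), obs, tolerance = 1e-6)
  expect_gt(m$r_squared, 0.999)
})

test_that("bias correction under noise is unbiased within Monte-Carlo error", {
  truth <- c(0.02, 1.1, 0.5)
  sims <- matrix(runif(125 * 100, -12, -2), ncol = 100)
  est <- sapply(1:100, function(i) {
    obs <- make_pseudo_observations(sims[, i], truth, noise_sd = 0.5,
                                    seed = 1000 + i)
    coef(fit_bias_correction(sims[, i], obs))
  })
  for (j in 1:3) {
    se <- stats::sd(est[j, ]) / sqrt(ncol(est))
    expect_lt(abs(mean(est[j, ]) - truth[j]), 3 * se + 1e-12)
  }
  # corrected-vs-observed regression slope near unity
  obs <- make_pseudo_observations(sims[, 1], truth, 0.5, 7)
  m <- fit_bias_correction(sims[, 1], obs)
  sl <- coef(lm(obs ~ apply_bias_correction(m, sims[, 1])))[2]
  expect_gt(sl, 0.9); expect_lt(sl, 1.1)
})

test_that("bias correction rejects degenerate input and extrapolation", {
  expect_error(fit_bias_correction(rep(-5, 10), rnorm(10)), "constant")
  expect_error(fit_bias_correction(1:3, 1:3), "4")
  m <- fit_bias_correction(seq(-10, -4, length.out = 10),
                           seq(-9, -3, length.out = 10))
  expect_error(apply_bias_correction(m, -15), "extrapolate")
})

test_that("bias correction preserves cross-site ordering", {
  set.seed(5)
  site_means <- runif(30, -12, -2)
  obs <- make_pseudo_observations(site_means, c(0.03, 1.2, 1.0), 0.4, 11)
  m <- fit_bias_correction(site_means, obs)
  corrected <- apply_bias_correction(m, site_means)
  expect_gte(stats::cor(corrected, site_means, method = "spearman"), 0.95)
})

test_that("linear trend handles exact, flat, and short series", {
  yrs <- 1971:2000
  tr <- linear_trend(0.05 * (yrs - 1971) + 2, yrs)
  expect_equal(tr$slope_per_decade, 0.5, tolerance = 1e-10)
  expect_lt(tr$p_value, 1e-10)
  expect_true(tr$significant)
  expect_equal(tr$total_change, 0.05 * 29, tolerance = 1e-10)
  flat <- linear_trend(rep(3, 10))
  expect_equal(flat$slope_per_decade, 0)
  expect_false(flat$significant)
  expect_error(linear_trend(c(1, 2)), "3")
})

test_that("trend recovery is unbiased on noisy series", {
  yrs <- 1:27
  est <- sapply(1:200, function(i) {
    set.seed(3000 + i)
    linear_trend(0.088 * yrs + rnorm(27, 0, 0.8), yrs)$slope_per_decade
  })
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.88), 3 * se)
})
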