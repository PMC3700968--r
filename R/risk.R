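# Risk statistics: running-mean annual extremes, threshold exceedance,
# residue response curves, quadratic bias correction, and linear trends.

#' Centered running mean
#'
#' The first and last `(window - 1)/2` values are `NA` (boundary days are
#' excluded rather than padded) so they never enter extreme statistics.
#'
#' @param series numeric vector of daily values.
#' @param window odd window length, >= 1, <= `length(series)`.
#' @return numeric vector, same length as `series`.
#' @export
running_mean <- function(series, window = 3) {
  if (window < 1 || window %% 2 == 0)
    stop("window must be odd and >= 1")
  if (window > length(series))
    stop("window (", window, ") exceeds series length (", length(series), ")")
  if (window == 1) return(as.numeric(series))
  as.numeric(stats::filter(series, rep(1 / window, window), sides = 2))
}

#' A lethal-temperature threshold
#'
#' @param value threshold, deg C.
#' @param label descriptive label.
#' @return list of class `threshold_spec`.
#' @export
threshold_spec <- function(value, label = paste0(value, "C")) {
  structure(list(label = label, value = value), class = "threshold_spec")
}

#' The shipped rhizome-lethality thresholds
#'
#' -3.5 deg C (LT50 for M. x giganteus and M. sacchariflorus rhizomes) and
#' -6.0 deg C (the hardier M. sinensis hybrid).
#'
#' @return list of two [threshold_spec()] objects.
#' @export
lethal_thresholds <- function() {
  list(threshold_spec(-3.5, "LT50 M. giganteus"),
       threshold_spec(-6.0, "LT50 hardy M. sinensis"))
}

#' Annual extreme minima of the running-mean 10 cm temperature
#'
#' For each complete winter year (July 1 - June 30, labelled by the ending
#' calendar year, so a single cold season is never split) the minimum of the
#' `window`-day centered running mean of daily-mean 10 cm temperature and
#' its date. Incomplete boundary years are dropped. A calendar-year
#' convention is available behind `year_mode`.
#'
#' @param daily a [run_scenario()] result, or any data.frame with columns
#'   `t10cm_daily_mean` and either (`year`, `doy`) or `date`.
#' @param window running-mean window, days (odd; default 3).
#' @param year_mode `"winter"` (Jul-Jun) or `"calendar"`.
#' @return data.frame of class `annual_extremes` with `winter_year_label`,
#'   `extreme_min_t10`, `date_of_min`.
#' @export
annual_extreme_minima <- function(daily, window = 3,
                                  year_mode = c("winter", "calendar")) {
  year_mode <- match.arg(year_mode)
  if (is.null(daily) || nrow(daily) == 0)
    return(structure(data.frame(winter_year_label = integer(0),
                                extreme_min_t10 = numeric(0),
                                date_of_min = as.Date(character(0))),
                     class = c("annual_extremes", "data.frame")))
  if (!all(c("year", "doy") %in% names(daily))) {
    stopifnot("date" %in% names(daily))
    daily$year <- as.integer(format(daily$date, "%Y"))
    daily$doy <- pmin(365L, as.integer(format(daily$date, "%j")))
  }
  rm3 <- running_mean(daily$t10cm_daily_mean, window)
  label <- if (year_mode == "winter")
    daily$year + as.integer(daily$doy >= 182L) else daily$year
  counts <- table(label)
  complete <- as.integer(names(counts)[counts >= 363])
  recs <- lapply(complete, function(y) {
    i <- which(label == y & !is.na(rm3))
    j <- i[which.min(rm3[i])]
    data.frame(winter_year_label = y,
               extreme_min_t10 = rm3[j],
               date_of_min = if ("date" %in% names(daily)) daily$date[j]
               else as.Date(NA))
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(winter_year_label = integer(0),
                      extreme_min_t10 = numeric(0),
                      date_of_min = as.Date(character(0)))
  structure(out, class = c("annual_extremes", "data.frame"))
}

#' Fraction of years at or below a lethal threshold
#'
#' Ties count as exceedance ("at or below").
#'
#' @param records an `annual_extremes` frame from [annual_extreme_minima()]
#'   or a numeric vector of annual extreme minima.
#' @param threshold a [threshold_spec()] or a numeric threshold, deg C.
#' @return fraction in [0, 1].
#' @export
exceedance_frequency <- function(records, threshold) {
  x <- if (is.data.frame(records)) records$extreme_min_t10 else records
  if (length(x) == 0)
    stop("exceedance fraction is undefined for zero records")
  th <- if (inherits(threshold, "threshold_spec")) threshold$value
  else threshold
  mean(x <= th)
}

#' Residue-thickness response curve
#'
#' Mean warming of the annual extreme minimum versus the bare (0 cm)
#' reference at each thickness, and the fraction of the warming achieved at
#' the maximum thickness swept.
#'
#' @param sweep a `frost_sweep` over thickness (see [thickness_sweep()]), or
#'   a named list mapping thickness (as names, cm) to numeric vectors of
#'   annual extreme minima, including the `"0"` reference.
#' @return data.frame of class `response_curve` with `thickness_cm`,
#'   `mean_extreme`, `sd_extreme`, `warming_vs_bare`, `fraction_of_max`.
#' @export
response_curve <- function(sweep) {
  if (inherits(sweep, "frost_sweep")) {
    if (sweep$param != "thickness")
      stop("response_curve requires a thickness sweep")
    values <- sweep$values
    extremes <- lapply(sweep$extremes, function(r) r$extreme_min_t10)
  } else {
    values <- as.numeric(names(sweep))
    extremes <- lapply(sweep, function(r)
      if (is.data.frame(r)) r$extreme_min_t10 else as.numeric(r))
  }
  ord <- order(values)
  values <- values[ord]; extremes <- extremes[ord]
  if (!any(values == 0))
    stop("sweep must include the 0 cm (bare) reference")
  if (sum(values > 0) < 2)
    stop("sweep must include at least two non-zero thicknesses")
  means <- vapply(extremes, mean, numeric(1))
  sds <- vapply(extremes, stats::sd, numeric(1))
  warm <- means - means[values == 0]
  wmax <- warm[which.max(values)]
  frac <- if (abs(wmax) < 1e-12) {
    warning("zero warming at the maximum thickness; fraction_of_max undefined")
    rep(NA_real_, length(values))
  } else warm / wmax
  structure(data.frame(thickness_cm = values, mean_extreme = means,
                       sd_extreme = sds, warming_vs_bare = warm,
                       fraction_of_max = frac, row.names = NULL),
            class = c("response_curve", "data.frame"))
}

#' Fit a quadratic bias correction of simulated against observed extremes
#'
#' Least-squares fit of `obs = a*sim^2 + b*sim + c`, the standard adjustment
#' when a simulator develops an increasing cold bias at the coldest observed
#' extremes. Applying the model maps raw simulated values onto the observed
#' scale.
#'
#' @param sim simulated annual extreme minima (deg C), length >= 4, not
#'   constant.
#' @param obs observed annual extreme minima, same length.
#' @return object of class `bias_correction` with `coefficients`
#'   (named `a`, `b`, `c`), `r_squared`, `residual_sd`, `sim_range`, `n`.
#' @export
fit_bias_correction <- function(sim, obs) {
  if (length(sim) != length(obs)) stop("sim and obs must have equal length")
  if (length(sim) < 4) stop("at least 4 paired values are required")
  if (!all(is.finite(sim)) || !all(is.finite(obs)))
    stop("sim and obs must be finite")
  if (stats::sd(sim) < 1e-12)
    stop("sim is (near-)constant; the quadratic fit is degenerate")
  fit <- lm(obs ~ sim + I(sim^2))
  cf <- coef(fit)
  s <- suppressWarnings(summary(fit))
  structure(list(coefficients = c(a = unname(cf[3]), b = unname(cf[2]),
                                  c = unname(cf[1])),
                 r_squared = s$r.squared,
                 residual_sd = s$sigma,
                 sim_range = range(sim),
                 n = length(sim)),
            class = "bias_correction")
}

#' Apply a fitted bias correction
#'
#' Refuses extrapolation beyond the fitted `sim` range by more than
#' `margin` times the range width.
#'
#' @param model a [fit_bias_correction()] result.
#' @param sim simulated values to correct.
#' @param margin allowed extrapolation as a fraction of the fitted range.
#' @return corrected values.
#' @export
apply_bias_correction <- function(model, sim, margin = 0.1) {
  stopifnot(inherits(model, "bias_correction"))
  rng <- model$sim_range
  slack <- margin * diff(rng)
  if (any(sim < rng[1] - slack | sim > rng[2] + slack))
    stop("refusing to extrapolate the bias correction beyond [",
         signif(rng[1] - slack, 4), ", ", signif(rng[2] + slack, 4), "] C")
  cf <- model$coefficients
  cf["a"] * sim^2 + cf["b"] * sim + cf["c"]
}

#' @export
predict.bias_correction <- function(object, newdata, ...) {
  apply_bias_correction(object, newdata, ...)
}

#' @export
coef.bias_correction <- function(object, ...) object$coefficients

#' @export
print.bias_correction <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<bias_correction> obs = %.4g*sim^2 + %.4g*sim + %.4g\n",
              cf["a"], cf["b"], cf["c"]))
  cat(sprintf("  n = %d, r^2 = %.3f, residual sd = %.3f C, sim range [%.2f, %.2f]\n",
              x$n, x$r_squared, x$residual_sd, x$sim_range[1], x$sim_range[2]))
  invisible(x)
}

#' Linear trend in an annual series
#'
#' Ordinary least squares of value on year; the slope is rescaled to deg C
#' per decade and tested against zero with a two-sided t-test (P < 0.05
#' significance). An optional AR(1) effective-sample-size correction
#' (off by default) inflates the slope standard error by the lag-1 residual
#' autocorrelation.
#'
#' @param annual_values numeric vector of annual values, or a data.frame
#'   with columns `year` and `value`.
#' @param years years matching `annual_values` (defaults to names or a
#'   unit-spaced sequence).
#' @param ar1_correct apply the AR(1) effective-df correction.
#' @return object of class `soil_trend`: `slope_per_decade`, `intercept`,
#'   `p_value`, `significant`, `total_change`, `n`, `span_years`.
#' @export
linear_trend <- function(annual_values, years = NULL, ar1_correct = FALSE) {
  if (is.data.frame(annual_values)) {
    years <- annual_values$year
    annual_values <- annual_values$value
  }
  if (is.null(years)) years <- seq_along(annual_values)
  if (length(annual_values) < 3)
    stop("linear_trend requires at least 3 annual values")
  fit <- lm(annual_values ~ years)
  s <- suppressWarnings(summary(fit))$coefficients
  slope <- s["years", "Estimate"]
  se <- s["years", "Std. Error"]
  n <- length(annual_values)
  df <- n - 2
  if (ar1_correct) {
    r <- stats::cor(stats::residuals(fit)[-n], stats::residuals(fit)[-1])
    r <- max(min(r, 0.99), 0)
    neff <- n * (1 - r) / (1 + r)
    se <- se * sqrt((n - 2) / max(neff - 2, 1))
    df <- max(neff - 2, 1)
  }
  p <- if (se < 1e-14) {
    if (abs(slope) < 1e-14) 1 else 0   # exact line: flat or perfectly sloped
  } else 2 * pt(-abs(slope / se), df)
  span <- diff(range(years))
  structure(list(slope_per_decade = slope * 10,
                 intercept = s["(Intercept)", "Estimate"],
                 p_value = p,
                 significant = p < 0.05,
                 total_change = slope * span,
                 n = n, span_years = span),
            class = "soil_trend")
}

#' @export
print.soil_trend <- function(x, ...) {
  cat(sprintf("<soil_trend> %.3f C per decade over %g years (n = %d)\n",
              x$slope_per_decade, x$span_years, x$n))
  cat(sprintf("  total change %.3f C, p = %.4g (%ssignificant at P<0.05)\n",
              x$total_change, x$p_value, if (x$significant) "" else "not "))
  invisible(x)
}
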