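#' Configuration for the synthetic sub-arctic weather generator
#'
#' Describes a multi-decade series of daily mean temperatures at a single
#' boreal station. Each year follows a Gaussian-bump seasonal curve over the
#' snow-free trapping window (mid-May to mid-October); a linear warming trend
#' can be applied separately to the ascending (spring) and descending
#' (autumn) limbs, a year-level anomaly shifts whole summers up or down, and
#' iid daily noise sits on top.
#'
#' Defaults emulate a station where the July mean is about +13 degC, the
#' thermal growing season (days at or above 10 degC) averages roughly 55-75
#' days with an interannual standard deviation near 14 days, and the season
#' lengthens by about half a day per year, driven mostly by autumn warming
#' with a smaller spring contribution.
#'
#' @param n_years Number of years to generate (>= 1).
#' @param year0 First calendar year.
#' @param peak_temp Seasonal peak mean temperature, degC.
#' @param winter_temp Baseline (asymptotic off-season) temperature, degC.
#' @param peak_day Julian day of the thermal peak.
#' @param season_width Gaussian width (days) of the seasonal curve.
#' @param spring_warming_rate degC added per year to the ascending limb.
#' @param autumn_warming_rate degC added per year to the descending limb.
#' @param anomaly_sd SD (degC) of the smooth within-season weather-regime
#'   anomaly (a spline through iid knot values).
#' @param anomaly_scale Knot spacing (days) of the anomaly process; larger
#'   values give more persistent warm/cold spells.
#' @param noise_sd SD (degC) of iid daily noise (>= 0).
#' @param first_day,last_day Julian-day window covered by the series; the
#'   defaults span mid-May (day 135) to mid-October (day 288).
#' @param seed Integer seed; every simulation draw flows from it.
#' @return A list of class `weather_config`.
#' @export
weather_config <- function(n_years = 37L,
                           year0 = 1977L,
                           peak_temp = 13,
                           winter_temp = -8,
                           peak_day = 200L,
                           season_width = 50,
                           spring_warming_rate = 0.0434,
                           autumn_warming_rate = 0.077,
                           anomaly_sd = 2.0,
                           anomaly_scale = 15,
                           noise_sd = 1.5,
                           first_day = 135L,
                           last_day = 288L,
                           seed = 1L) {
  if (n_years < 1) abort("`n_years` must be at least 1.", class = "mothshift_config_error")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.", class = "mothshift_config_error")
  if (anomaly_sd < 0) abort("`anomaly_sd` must be non-negative.", class = "mothshift_config_error")
  if (anomaly_scale < 2) abort("`anomaly_scale` must be at least 2 days.", class = "mothshift_config_error")
  if (last_day <= first_day) abort("`last_day` must exceed `first_day`.", class = "mothshift_config_error")
  if (season_width <= 0) abort("`season_width` must be positive.", class = "mothshift_config_error")
  structure(list(
    n_years = as.integer(n_years), year0 = as.integer(year0),
    peak_temp = peak_temp, winter_temp = winter_temp,
    peak_day = as.integer(peak_day), season_width = season_width,
    spring_warming_rate = spring_warming_rate,
    autumn_warming_rate = autumn_warming_rate,
    anomaly_sd = anomaly_sd, anomaly_scale = anomaly_scale,
    noise_sd = noise_sd,
    first_day = as.integer(first_day), last_day = as.integer(last_day),
    seed = as.integer(seed)
  ), class = "weather_config")
}

# Knot grid of the within-season anomaly process.
anomaly_knots <- function(cfg) {
  seq(cfg$first_day - 2 * cfg$anomaly_scale,
      cfg$last_day + 2 * cfg$anomaly_scale, by = cfg$anomaly_scale)
}

# Smooth anomaly curve through iid knot values (natural cubic spline).
anomaly_fun <- function(cfg, knot_values) {
  knots <- anomaly_knots(cfg)
  function(d) stats::spline(knots, knot_values, xout = d, method = "natural")$y
}

# Noiseless seasonal curve for year index t (0-based), evaluated at Julian
# days d. The warming trend blends smoothly from the spring to the autumn
# rate across the peak (probit ramp, 15-day scale); `anomaly` is a numeric
# offset or a function of day.
weather_curve_value <- function(cfg, t, d, anomaly = 0) {
  wa <- pnorm((d - cfg$peak_day) / 15)
  bump <- (cfg$peak_temp - cfg$winter_temp) *
    exp(-(d - cfg$peak_day)^2 / (2 * cfg$season_width^2))
  a <- if (is.function(anomaly)) anomaly(d) else anomaly
  cfg$winter_temp + bump +
    t * (cfg$spring_warming_rate * (1 - wa) + cfg$autumn_warming_rate * wa) +
    a
}

# Integer-day threshold crossings of the noiseless curve: first and last day
# with temperature >= threshold, or NAs when never reached.
analytic_crossings <- function(cfg, t, threshold, anomaly = 0) {
  days <- seq(cfg$first_day, cfg$last_day)
  temp <- weather_curve_value(cfg, t, days, anomaly)
  hit <- which(temp >= threshold)
  if (length(hit) == 0) return(c(NA_integer_, NA_integer_))
  c(days[hit[1]], days[hit[length(hit)]])
}

# Generator-analytic season metrics for one year (noiseless curve).
analytic_season_metrics <- function(cfg, t, anomaly = 0,
                                    thresholds = climate_thresholds()) {
  cr10 <- analytic_crossings(cfg, t, thresholds$grow, anomaly)
  cr8 <- analytic_crossings(cfg, t, thresholds$start, anomaly)
  cr3 <- analytic_crossings(cfg, t, thresholds$end, anomaly)
  tibble::tibble(
    year = cfg$year0 + t,
    start_true = cr8[1], end_true = cr3[2],
    length_true = if (is.na(cr10[1])) 0L else cr10[2] - cr10[1] + 1L,
    mean_anomaly = if (is.function(anomaly)) {
      mean(anomaly(seq(cfg$first_day, cfg$last_day)))
    } else anomaly
  )
}

#' Simulate a multi-year daily temperature series
#'
#' Generates one row per day per year over the configured window, with a
#' ground-truth attribute recording, for every year, the noiseless-curve
#' season start (first 8 degC crossing), season end (last 3 degC crossing)
#' and season length (days at or above 10 degC), evaluated on the integer
#' day grid. Deterministic for a fixed configuration and seed.
#'
#' @param cfg A [weather_config()].
#' @return A tibble (`year`, `date`, `day`, `temp_c`) of class
#'   `moth_weather`; `weather_truth()` extracts the per-year ground truth.
#' @examples
#' w <- simulate_weather(weather_config(n_years = 3, seed = 42))
#' weather_truth(w)
#' @export
simulate_weather <- function(cfg = weather_config()) {
  stopifnot(inherits(cfg, "weather_config"))
  set.seed(cfg$seed)
  n_knots <- length(anomaly_knots(cfg))
  anomalies <- purrr::map(seq_len(cfg$n_years), function(i) {
    anomaly_fun(cfg, rnorm(n_knots, 0, cfg$anomaly_sd))
  })
  days <- seq(cfg$first_day, cfg$last_day)
  out <- purrr::map_dfr(seq_len(cfg$n_years) - 1L, function(t) {
    temp <- weather_curve_value(cfg, t, days, anomalies[[t + 1L]]) +
      rnorm(length(days), 0, cfg$noise_sd)
    tibble::tibble(
      year = cfg$year0 + t,
      day = days,
      temp_c = temp
    )
  })
  out$date <- as.Date(paste0(out$year, "-01-01")) + (out$day - 1L)
  out <- out[, c("year", "date", "day", "temp_c")]
  truth <- purrr::map_dfr(seq_len(cfg$n_years) - 1L, function(t) {
    analytic_season_metrics(cfg, t, anomalies[[t + 1L]])
  })
  structure(out, class = c("moth_weather", class(out)),
            config = cfg, truth = truth)
}

#' Ground-truth season metrics of a simulated weather series
#'
#' @param weather A series from [simulate_weather()].
#' @return Tibble with `year`, `start_true`, `end_true`, `length_true`,
#'   `mean_anomaly` -- the noiseless-curve metrics the smoother-based estimates
#'   should recover.
#' @export
weather_truth <- function(weather) {
  truth <- attr(weather, "truth")
  if (is.null(truth)) {
    abort("`weather` carries no ground truth; was it built by `simulate_weather()`?")
  }
  truth
}
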