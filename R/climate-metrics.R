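#' Temperature thresholds defining the favorable season
#'
#' The growing season is the run of days with mean daily temperature at or
#' above `grow` (10 degC by default, the point below which larval growth of
#' most boreal moths effectively ceases). Season start and end are the first
#' crossing of `start` (8 degC) and the last crossing of `end` (3 degC) on
#' the smoothed curve -- long-run mean temperatures on the days the first
#' spring and last autumn moths fly. "At or above" is applied uniformly.
#'
#' @param grow,start,end Thresholds in degC; must satisfy `end <= start <= grow`.
#' @return A list of class `climate_thresholds`.
#' @export
climate_thresholds <- function(grow = 10, start = 8, end = 3) {
  if (!(end <= start && start <= grow)) {
    abort("Thresholds must satisfy end <= start <= grow.",
          class = "mothshift_config_error")
  }
  structure(list(grow = grow, start = start, end = end),
            class = "climate_thresholds")
}

#' Fit a penalized-spline smoother to one year of daily temperatures
#'
#' A penalized cubic regression spline (basis dimension `k`, penalty chosen
#' by generalized cross-validation) fitted to the observed days only. If
#' fewer than `k + 2` days are available the basis is reduced with a
#' warning; an all-missing series is an error.
#'
#' @param series Data frame with columns `day` and `temp_c` for one year.
#' @param k Basis dimension of the spline (default 20).
#' @return An object of class `daily_smoother`: call `predict()` on it (or
#'   use it via [season_metrics()]) to evaluate the smooth curve at any day
#'   within the observed span.
#' @export
fit_daily_smoother <- function(series, k = 20) {
  series <- series[!is.na(series$temp_c) & !is.na(series$day), ]
  if (nrow(series) == 0) {
    abort("No non-missing temperature observations.", class = "mothshift_data_error")
  }
  n <- nrow(series)
  if (n < k + 2) {
    k_new <- max(3L, n - 2L)
    warn(sprintf("Only %d days observed; reducing spline basis from %d to %d.",
                 n, k, k_new))
    k <- k_new
  }
  fit <- mgcv::gam(temp_c ~ s(day, k = k, bs = "cr"), data = series,
                   method = "GCV.Cp")
  structure(list(fit = fit,
                 day_range = range(series$day)),
            class = "daily_smoother")
}

#' @export
predict.daily_smoother <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- data.frame(day = seq(object$day_range[1], object$day_range[2]))
  }
  if (is.numeric(newdata)) newdata <- data.frame(day = newdata)
  as.numeric(predict(object$fit, newdata = newdata))
}

#' First and last day a smoothed curve reaches a threshold
#'
#' Evaluates the curve on the integer-day grid of `day_range` and returns
#' the first and the last day with value at or above the threshold. Multiple
#' up/down crossings of a noisy curve are collapsed to the outermost pair; a
#' curve that never reaches the threshold yields an all-`NA` row (season of
#' length zero), not an error.
#'
#' @param curve A `daily_smoother`, or any function mapping day to degC.
#' @param threshold Temperature threshold, degC.
#' @param day_range Integer vector `c(first, last)`; defaults to the
#'   smoother's observed span.
#' @return One-row tibble with `first_day`, `last_day` (integer or `NA`).
#' @export
threshold_crossing_dates <- function(curve, threshold, day_range = NULL) {
  if (inherits(curve, "daily_smoother")) {
    day_range <- day_range %||% curve$day_range
    f <- function(d) predict(curve, d)
  } else if (is.function(curve)) {
    if (is.null(day_range)) abort("`day_range` is required for a bare function.")
    f <- curve
  } else {
    abort("`curve` must be a daily_smoother or a function.")
  }
  days <- seq(ceiling(day_range[1]), floor(day_range[2]))
  vals <- f(days)
  hit <- which(vals >= threshold)
  if (length(hit) == 0) {
    return(tibble::tibble(first_day = NA_integer_, last_day = NA_integer_))
  }
  tibble::tibble(first_day = as.integer(days[hit[1]]),
                 last_day = as.integer(days[hit[length(hit)]]))
}

season_metrics_one <- function(series, thresholds, mode, k) {
  sm <- fit_daily_smoother(series, k = k)
  cr_start <- threshold_crossing_dates(sm, thresholds$start)
  cr_end <- threshold_crossing_dates(sm, thresholds$end)
  cr_grow <- threshold_crossing_dates(sm, thresholds$grow)
  length_days <- if (mode == "smoothed-span") {
    if (is.na(cr_grow$first_day)) 0L else cr_grow$last_day - cr_grow$first_day + 1L
  } else {
    sum(series$temp_c >= thresholds$grow, na.rm = TRUE)
  }
  tibble::tibble(
    start_day = cr_start$first_day,
    end_day = cr_end$last_day,
    length_days = as.integer(length_days),
    mode = mode
  )
}

#' Season start, end and length per year
#'
#' For each year: fits the daily smoother, takes the first smoothed crossing
#' of the start threshold (8 degC) as season start, the last smoothed
#' crossing of the end threshold (3 degC) as season end, and computes season
#' length from the growth threshold (10 degC) either as the smoothed-curve
#' span between outermost crossings (`"smoothed-span"`, the default) or as
#' the raw count of observed days at or above the threshold (`"raw-count"`).
#' On noiseless unimodal data the two modes agree exactly.
#'
#' @param weather Data frame with columns `year`, `day`, `temp_c` (one or
#'   more years; [simulate_weather()] output works directly).
#' @param thresholds A [climate_thresholds()].
#' @param mode `"smoothed-span"` or `"raw-count"`.
#' @param k Spline basis dimension passed to [fit_daily_smoother()].
#' @return Tibble with one row per year: `year`, `start_day`, `end_day`,
#'   `length_days`, `mode`. An empty growth season gives `length_days = 0`;
#'   start/end are still reported when their own thresholds are met.
#' @export
season_metrics <- function(weather,
                           thresholds = climate_thresholds(),
                           mode = c("smoothed-span", "raw-count"),
                           k = 20) {
  mode <- match.arg(mode)
  stopifnot(all(c("year", "day", "temp_c") %in% names(weather)))
  weather |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$year) |>
    dplyr::group_modify(~ season_metrics_one(.x, thresholds, mode, k)) |>
    dplyr::ungroup()
}

#' Linear temporal trend with Durbin-Watson diagnostics
#'
#' Ordinary least squares of an annual metric on calendar year, with the
#' two-sided t test on the slope, the Durbin-Watson statistic and the lag-1
#' residual autocorrelation (values of |rho| below about 0.35 indicate the
#' independence assumption is tenable).
#'
#' @param data Data frame of yearly values.
#' @param value,year Column names (strings) of the metric and the year.
#' @return One-row tibble: `slope`, `se`, `t_stat`, `p_value`,
#'   `dw_statistic`, `rho`, `n`.
#' @export
trend_regression <- function(data, value, year = "year") {
  d <- data[stats::complete.cases(data[, c(value, year)]), ]
  if (nrow(d) < 3) abort("Need at least 3 years for a trend.", class = "mothshift_data_error")
  if (length(unique(d[[year]])) < 2) {
    abort("Year is constant; trend undefined.", class = "mothshift_data_error")
  }
  fit <- lm(d[[value]] ~ d[[year]])
  sm <- summary(fit)$coefficients
  e <- stats::residuals(fit)
  dw <- sum(diff(e)^2) / sum(e^2)
  rho <- sum(e[-1] * e[-length(e)]) / sum(e^2)
  tibble::tibble(
    slope = sm[2, 1], se = sm[2, 2], t_stat = sm[2, 3], p_value = sm[2, 4],
    dw_statistic = dw, rho = rho, n = nrow(d)
  )
}

#' Pearson correlation between two annual climate metrics
#'
#' Used to verify that predictors entered together in the abundance model
#' (season length and season end) are not collinear.
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble: `r`, `t`, `df`, `p`.
#' @export
correlate_metrics <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("Need at least 3 paired values.", class = "mothshift_data_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in one of the series.", class = "mothshift_data_error")
  }
  n <- length(x)
  r <- cor(x, y)
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Plot annual season metrics with their linear trends
#'
#' @param metrics Output of [season_metrics()].
#' @return A ggplot: one panel per metric with an OLS trend line.
#' @export
plot_season_trends <- function(metrics) {
  long <- metrics |>
    tidyr::pivot_longer(c("start_day", "end_day", "length_days"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Julian day / days",
                  title = "Temporal trends in season metrics")
}
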