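#' Species-selection criteria
#'
#' The base analysis set keeps species observed in at least `min_years`
#' distinct years with a mean annual catch of more than `min_mean_catch`
#' individuals. The flight-period subset further requires an annual
#' abundance of more than `flight_min_abundance` individuals in more than
#' `flight_min_years` years. All boundaries are strict where the wording
#' says "more than".
#'
#' @param min_years,min_mean_catch Base-set filters (defaults 30 years,
#'   mean catch > 7).
#' @param flight_min_abundance,flight_min_years Flight-set filters
#'   (defaults > 30 individuals, > 20 qualifying years).
#' @return List of class `selection_criteria`.
#' @export
selection_criteria <- function(min_years = 30, min_mean_catch = 7,
                               flight_min_abundance = 30,
                               flight_min_years = 20) {
  vals <- c(min_years, min_mean_catch, flight_min_abundance, flight_min_years)
  if (any(vals <= 0)) abort("All criteria must be strictly positive.",
                            class = "mothshift_config_error")
  structure(list(min_years = min_years, min_mean_catch = min_mean_catch,
                 flight_min_abundance = flight_min_abundance,
                 flight_min_years = flight_min_years),
            class = "selection_criteria")
}

#' Apply the species-selection filters
#'
#' Deterministic filters with a per-species audit trail. The mean annual
#' catch divides a species' total by the number of years spanned by the
#' record (zero-catch years count in the denominator).
#'
#' @param catches Catch records.
#' @param criteria A [selection_criteria()].
#' @return Tibble: `species`, `n_years_observed`, `mean_annual_catch`,
#'   `n_high_years`, `in_base`, `in_flight`.
#' @export
select_species <- function(catches, criteria = selection_criteria()) {
  record_years <- dplyr::n_distinct(catches$year)
  catches |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$species, .data$year) |>
    dplyr::summarise(annual = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_years_observed = dplyr::n(),
      mean_annual_catch = sum(.data$annual) / record_years,
      n_high_years = sum(.data$annual > criteria$flight_min_abundance),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      in_base = .data$n_years_observed >= criteria$min_years &
        .data$mean_annual_catch > criteria$min_mean_catch,
      in_flight = .data$in_base &
        .data$n_high_years > criteria$flight_min_years
    )
}

#' Flight-period duration from one year's daily catch curve
#'
#' Smooths the log10(n + 1)-transformed across-trap mean daily catch with a
#' penalized spline and counts the integer days on which the smoothed value
#' exceeds the threshold (0.2 by default, i.e. a mean daily catch of about
#' 1.6 individuals), which screens out single exceptionally early or late
#' individuals. With fewer than 5 non-zero days the raw transformed values
#' are thresholded instead, with a warning.
#'
#' @param daily Tibble `day`, `mean_catch` covering the full trapping
#'   window of one species-year (zero days included).
#' @param threshold Threshold on the log10(n + 1) scale (> 0).
#' @param k Spline basis dimension (default 12).
#' @return One-row tibble: `duration_days`, `first_day`, `last_day`,
#'   `smoothed`.
#' @export
flight_period_duration <- function(daily, threshold = 0.2, k = 12) {
  if (threshold <= 0) abort("`threshold` must be positive.",
                            class = "mothshift_config_error")
  z <- log10(daily$mean_catch + 1)
  if (all(daily$mean_catch == 0)) {
    return(tibble::tibble(duration_days = 0L, first_day = NA_integer_,
                          last_day = NA_integer_, smoothed = FALSE))
  }
  if (sum(daily$mean_catch > 0) < 5) {
    warn("Fewer than 5 non-zero days; thresholding raw transformed catches.")
    over <- daily$day[z > threshold]
    return(tibble::tibble(
      duration_days = length(over),
      first_day = if (length(over)) as.integer(min(over)) else NA_integer_,
      last_day = if (length(over)) as.integer(max(over)) else NA_integer_,
      smoothed = FALSE
    ))
  }
  d <- tibble::tibble(day = daily$day, temp_c = z)  # reuse the daily smoother
  sm <- suppressWarnings(fit_daily_smoother(d, k = k))
  grid <- seq(min(daily$day), max(daily$day))
  zs <- predict(sm, grid)
  over <- grid[zs > threshold]
  tibble::tibble(
    duration_days = length(over),
    first_day = if (length(over)) as.integer(min(over)) else NA_integer_,
    last_day = if (length(over)) as.integer(max(over)) else NA_integer_,
    smoothed = TRUE
  )
}

#' Across-trap mean daily catch curves
#'
#' "Average daily catch" is the mean over the traps of the transect
#' (treated as one population sample); days without captures contribute
#' zeros across the full trapping window.
#'
#' @param catches Catch records for the species of interest.
#' @param n_traps Number of operating traps (defaults to the number of
#'   distinct traps in `catches`).
#' @param day_range Integer `c(first, last)` trapping window (defaults to
#'   the observed day range).
#' @return Tibble: `species`, `year`, `day`, `mean_catch`.
#' @export
daily_mean_catch <- function(catches, n_traps = NULL, day_range = NULL) {
  n_traps <- n_traps %||% dplyr::n_distinct(catches$trap_id)
  day_range <- day_range %||% range(catches$day)
  grid <- tidyr::expand_grid(
    dplyr::distinct(catches, .data$species, .data$year),
    day = seq(day_range[1], day_range[2])
  )
  catches |>
    dplyr::group_by(.data$species, .data$year, .data$day) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::right_join(grid, by = c("species", "year", "day")) |>
    dplyr::mutate(mean_catch = dplyr::coalesce(.data$total, 0L) / n_traps) |>
    dplyr::select("species", "year", "day", "mean_catch") |>
    dplyr::arrange(.data$species, .data$year, .data$day)
}

#' Weather covariates within a flight window
#'
#' Mean and coefficient of variation (sample SD over mean) of mean daily
#' temperatures across the days of the flight period. The CV is ill-behaved
#' when the mean is near 0 degC; windows with mean below 5 degC are flagged
#' and a non-positive mean yields `NA`.
#'
#' @param weather_year Tibble `day`, `temp_c` for one year.
#' @param window Integer `c(first_day, last_day)`.
#' @return One-row tibble: `temp_mean`, `temp_cv`, `flagged`.
#' @export
flight_weather <- function(weather_year, window) {
  d <- weather_year[weather_year$day >= window[1] & weather_year$day <= window[2], ]
  if (nrow(d) == 0) abort("Empty flight window.", class = "mothshift_data_error")
  m <- mean(d$temp_c)
  cv <- if (m <= 0) NA_real_ else sd(d$temp_c) / m
  tibble::tibble(temp_mean = m, temp_cv = cv, flagged = m < 5)
}

#' Annual flight-period estimates for a species set
#'
#' For every species-year: the smoothed flight-period duration, the annual
#' abundance, and the weather covariates over the threshold-exceedance hull
#' (the species' flight window that year). Years with no estimated flight
#' period carry `duration_days = 0` and no weather covariates.
#'
#' @param catches Catch records (pre-filtered to the flight species set).
#' @param weather Daily weather (`year`, `day`, `temp_c`).
#' @param threshold,k Passed to [flight_period_duration()].
#' @param n_traps,day_range Passed to [daily_mean_catch()].
#' @return Tibble: `species`, `year`, `duration_days`, `abundance`,
#'   `log_abundance`, `temp_mean`, `temp_cv`, `flagged`.
#' @export
flight_period_table <- function(catches, weather, threshold = 0.2, k = 12,
                                n_traps = NULL, day_range = NULL) {
  curves <- daily_mean_catch(catches, n_traps, day_range)
  abund <- catches |>
    dplyr::group_by(.data$species, .data$year) |>
    dplyr::summarise(abundance = sum(.data$count), .groups = "drop")
  durations <- curves |>
    dplyr::group_by(.data$species, .data$year) |>
    dplyr::group_modify(~ flight_period_duration(.x, threshold, k)) |>
    dplyr::ungroup()
  out <- durations |>
    dplyr::left_join(abund, by = c("species", "year")) |>
    dplyr::mutate(abundance = dplyr::coalesce(.data$abundance, 0L),
                  log_abundance = log10(.data$abundance + 1))
  wx <- out |>
    dplyr::filter(!is.na(.data$first_day)) |>
    dplyr::group_by(.data$species, .data$year) |>
    dplyr::group_modify(function(d, key) {
      flight_weather(weather[weather$year == key$year, ],
                     c(d$first_day, d$last_day))
    }) |>
    dplyr::ungroup()
  out |>
    dplyr::left_join(wx, by = c("species", "year")) |>
    dplyr::select("species", "year", "duration_days", "first_day", "last_day",
                  "abundance", "log_abundance", "temp_mean", "temp_cv",
                  "flagged")
}

#' Mixed model for flight-period variation
#'
#' Duration (days) against year, log10 abundance, mean flight-window
#' temperature, its coefficient of variation, and the temperature x CV
#' interaction, with species-specific random intercepts. Year is centred
#' internally for mixing; its coefficient is per calendar year. A warning
#' reports the design condition number when year and temperature are
#' strongly collinear.
#'
#' @param estimates Output of [flight_period_table()] (rows with missing
#'   covariates are dropped with a message).
#' @param mcmc An [mcmc_config()].
#' @return Tibble of class `moth_flight_model` (posterior summaries);
#'   `gibbs_lmm` fit in attribute `fit`.
#' @export
flight_period_model <- function(estimates, mcmc = mcmc_config()) {
  d <- estimates[stats::complete.cases(
    estimates[, c("duration_days", "year", "log_abundance", "temp_mean", "temp_cv")]), ]
  dropped <- nrow(estimates) - nrow(d)
  if (dropped > 0) inform(sprintf("Dropping %d rows with missing covariates.", dropped))
  if (dplyr::n_distinct(d$species) < 2) {
    abort("Need at least 2 species.", class = "mothshift_data_error")
  }
  d$year_c <- d$year - mean(range(d$year))
  d$temp_int <- d$temp_mean * d$temp_cv
  Xc <- scale(d[, c("year_c", "temp_mean")])
  kappa_xy <- kappa(cbind(1, Xc), exact = TRUE)
  if (abs(cor(d$year_c, d$temp_mean)) > 0.9) {
    warn(sprintf("Year and mean temperature are strongly collinear (condition number %.1f).",
                 kappa_xy))
  }
  fit <- gibbs_lmm(
    d, duration_days ~ year_c + log_abundance + temp_mean + temp_cv + temp_int,
    random = list(ranef_block("species")),
    mcmc = mcmc
  )
  out <- dplyr::bind_rows(tidy(fit, "fixed"), tidy(fit, "var")) |>
    dplyr::mutate(parameter = dplyr::recode(.data$parameter,
                                            year_c = "year",
                                            temp_int = "temp_mean:temp_cv"))
  structure(out, class = c("moth_flight_model", class(out)), fit = fit)
}

#' Plot a species' daily catch curve and flight window
#'
#' @param curves Output of [daily_mean_catch()] filtered to one species.
#' @param estimates Optional matching rows of [flight_period_table()] to
#'   shade the estimated flight windows.
#' @return A ggplot of log10(n + 1) mean daily catch by year.
#' @export
plot_flight_curves <- function(curves, estimates = NULL) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$day,
                                    y = log10(.data$mean_catch + 1))) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = 0.2, linetype = 2, colour = "tomato") +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(x = "Julian day", y = "log10(mean daily catch + 1)")
  if (!is.null(estimates)) {
    est <- estimates[!is.na(estimates$first_day), ]
    p <- p + ggplot2::geom_rect(
      data = est,
      ggplot2::aes(xmin = .data$first_day, xmax = .data$last_day),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  p
}
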