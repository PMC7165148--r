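#' Count-weighted elevational centre of gravity
#'
#' The abundance-weighted mean elevation of a species' captures. Invariant
#' to rescaling all counts and always inside the trap elevation range.
#'
#' @param elevation_m Trap elevations of the capturing traps.
#' @param count Individuals captured at each elevation.
#' @return Centre of gravity in m a.s.l.
#' @export
center_of_gravity <- function(elevation_m, count) {
  keep <- !is.na(elevation_m) & !is.na(count)
  elevation_m <- elevation_m[keep]; count <- count[keep]
  if (sum(count) <= 0) {
    abort("Centre of gravity undefined for zero total count.",
          class = "mothshift_data_error")
  }
  sum(elevation_m * count) / sum(count)
}

#' Annual centre of gravity per species
#'
#' Species-years with zero total catch are skipped (no row emitted).
#'
#' @param catches Catch records (`species`, `year`, `elevation_m`, `count`).
#' @return Tibble: `species`, `year`, `cog`, `n` (individuals).
#' @export
cog_by_year <- function(catches) {
  catches |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$species, .data$year) |>
    dplyr::summarise(
      cog = sum(.data$elevation_m * .data$count) / sum(.data$count),
      n = sum(.data$count), .groups = "drop"
    )
}

classify_hpd <- function(lower, upper) {
  dplyr::case_when(lower > 0 ~ "increased",
                   upper < 0 ~ "decreased",
                   TRUE ~ "stable")
}

#' Species-specific elevational trend slopes
#'
#' Primary estimator: a hierarchical model on individual capture
#' elevations, with a fixed intercept only and a per-species correlated
#' (intercept, year) random block -- each captured individual contributes
#' one observation whose value is the elevation of the trap that caught it,
#' and the species' slope (m/yr) is its random year-slope. Individuals that
#' share a species, year and trap are collapsed to a weighted cell, which
#' leaves the posterior unchanged. The year covariate is centred at the
#' series midpoint; slopes are unaffected. A secondary two-stage estimator
#' (annual centre of gravity, then per-species OLS on year) is reported
#' alongside as a non-hierarchical check.
#'
#' Classification by the HPD-sign rule: `increased` if the 95% HPD lower
#' limit exceeds 0, `decreased` if the upper limit is below 0, otherwise
#' `stable`.
#'
#' @param catches Catch records (`species`, `year`, `elevation_m`, `count`).
#' @param mcmc An [mcmc_config()].
#' @param min_years Species observed in fewer distinct years are excluded
#'   (with a message).
#' @return Tibble of class `moth_slopes`: `species`, `slope`, `hpd_lower`,
#'   `hpd_upper`, `classification`, `slope_ols`, `ols_lower`, `ols_upper`,
#'   `n_years`; the full `gibbs_lmm` fit is attached as attribute `fit`.
#' @export
species_slopes <- function(catches, mcmc = mcmc_config(), min_years = 2) {
  # All individuals of a species-year share the covariates (1, year), so the
  # individual-level model collapses exactly to per-species-year sufficient
  # statistics: total count, mean capture elevation, and the within-cell sum
  # of squares that feeds the residual update.
  cells <- catches |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$species, .data$year) |>
    dplyr::summarise(
      elev_mean = sum(.data$elevation_m * .data$count) / sum(.data$count),
      ss = sum(.data$count * (.data$elevation_m -
                                sum(.data$elevation_m * .data$count) /
                                sum(.data$count))^2),
      count = sum(.data$count), .groups = "drop"
    )
  years_per <- cells |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_years = dplyr::n_distinct(.data$year), .groups = "drop")
  drop <- years_per$species[years_per$n_years < min_years]
  if (length(drop)) {
    inform(paste("Excluding species observed in fewer than", min_years,
                 "years:", paste(drop, collapse = ", ")))
    cells <- dplyr::filter(cells, !(.data$species %in% drop))
  }
  if (nrow(cells) == 0) abort("No species left after the year filter.",
                              class = "mothshift_data_error")
  mid <- mean(range(cells$year))
  cells$year_c <- cells$year - mid

  fit <- gibbs_lmm(cells, elev_mean ~ 1,
                   random = list(ranef_block("species", slope = "year_c")),
                   weights = "count", ss_extra = sum(cells$ss), mcmc = mcmc)
  sl <- ranef_draws(fit, "species", "slope")
  hier <- purrr::map_dfr(colnames(sl), function(spp) {
    h <- hpd_interval(sl[, spp])
    tibble::tibble(species = spp, slope = mean(sl[, spp]),
                   hpd_lower = h[["lower"]], hpd_upper = h[["upper"]])
  })
  two_stage <- cog_by_year(catches |>
                             dplyr::filter(!(.data$species %in% drop))) |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        return(tibble::tibble(slope_ols = NA_real_, ols_lower = NA_real_,
                              ols_upper = NA_real_))
      }
      f <- lm(cog ~ year, data = d)
      ci <- stats::confint(f)["year", ]
      tibble::tibble(slope_ols = coef(f)[["year"]],
                     ols_lower = ci[[1]], ols_upper = ci[[2]])
    }) |>
    dplyr::ungroup()
  out <- hier |>
    dplyr::mutate(classification = classify_hpd(.data$hpd_lower, .data$hpd_upper)) |>
    dplyr::left_join(two_stage, by = "species") |>
    dplyr::left_join(years_per, by = "species")
  structure(out, class = c("moth_slopes", class(out)), fit = fit)
}

#' Count species by trend class
#'
#' Pure function of the HPD signs: re-derives the classification from
#' `hpd_lower`/`hpd_upper` and tallies it.
#'
#' @param slopes Data frame with `hpd_lower` and `hpd_upper` columns
#'   ([species_slopes()] output, or any published slope table).
#' @return One-row tibble: `increased`, `stable`, `decreased`.
#' @export
classify_trends <- function(slopes) {
  if (nrow(slopes) == 0) abort("Empty slope table.", class = "mothshift_data_error")
  cls <- classify_hpd(slopes$hpd_lower, slopes$hpd_upper)
  tibble::tibble(
    increased = sum(cls == "increased"),
    stable = sum(cls == "stable"),
    decreased = sum(cls == "decreased")
  )
}

#' Species' historical centre of gravity
#'
#' Mean centre of gravity over the first `n_years` of the record (counts
#' pooled across those years), the "historical range" covariate of the
#' trait model.
#'
#' @param catches Catch records.
#' @param n_years Width of the historical window (default 5 years).
#' @return Tibble: `species`, `cog_hist`.
#' @export
historical_cog <- function(catches, n_years = 5) {
  y0 <- min(catches$year)
  catches |>
    dplyr::filter(.data$year < y0 + n_years, .data$count > 0) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      cog_hist = sum(.data$elevation_m * .data$count) / sum(.data$count),
      .groups = "drop"
    )
}

#' Standardize historical centre-of-gravity values
#'
#' Subtracts the sample mean and divides by the sample standard deviation
#' (n - 1 denominator), returning the first- and second-order terms used by
#' the trait model.
#'
#' @param values Numeric vector of historical COG values.
#' @return Tibble: `z`, `z_sq`; `mean(z)` is 0 and `sd(z)` is 1.
#' @export
standardize_historical_range <- function(values) {
  if (length(unique(values)) < 2) {
    abort("Need at least two distinct values to standardize.",
          class = "mothshift_data_error")
  }
  z <- (values - mean(values)) / sd(values)
  tibble::tibble(z = z, z_sq = z^2)
}

#' Trait model for elevational slope variation
#'
#' Explains species-specific slope values (displayed on a x100 scale so a
#' coefficient of 20 corresponds to +0.2 m/yr) by the standardized
#' historical centre of gravity (first- and second-order terms),
#' over-wintering stage, life cycle, host type and host specificity, with
#' nested taxonomic random intercepts (genus, family, superfamily) standing
#' in for phylogeny. Reference levels: adult / annual / dwarf shrubs /
#' polyphagy. Factor levels with no species are dropped with a warning.
#'
#' @param slopes Tibble with `species` and `slope` (m/yr).
#' @param traits Trait table (`species`, trait columns, `genus`, `family`,
#'   `superfamily`, and `cog_hist` or precomputed `z`).
#' @param mcmc An [mcmc_config()].
#' @param scale Display scale for the response (default 100).
#' @return Tibble of class `moth_trait_model` (posterior summaries for all
#'   fixed effects and variance components); `gibbs_lmm` fit in attribute
#'   `fit`.
#' @export
trait_model <- function(slopes, traits, mcmc = mcmc_config(), scale = 100) {
  d <- dplyr::inner_join(tibble::as_tibble(slopes), tibble::as_tibble(traits),
                         by = "species")
  if (!"z" %in% names(d)) {
    if (!"cog_hist" %in% names(d)) {
      abort("Traits must supply `cog_hist` (or a precomputed `z`).")
    }
    sz <- standardize_historical_range(d$cog_hist)
    d$z <- sz$z
  }
  d$z_sq <- d$z^2
  lv <- trait_levels()
  for (tr in names(lv)) {
    bad <- setdiff(unique(d[[tr]]), lv[[tr]])
    if (length(bad)) abort(paste("Unknown", tr, "level(s):",
                                 paste(bad, collapse = ", ")))
    present <- lv[[tr]][lv[[tr]] %in% unique(d[[tr]])]
    if (length(present) < length(lv[[tr]])) {
      warn(paste("Dropping empty", tr, "level(s):",
                 paste(setdiff(lv[[tr]], present), collapse = ", ")))
    }
    d[[tr]] <- factor(d[[tr]], levels = present)
  }
  d$slope_scaled <- d$slope * scale
  terms <- c("z", "z_sq")
  for (tr in names(lv)) {
    if (nlevels(d[[tr]]) >= 2) {
      terms <- c(terms, tr)
    } else {
      warn(paste("Trait", tr, "has a single observed level; term dropped."))
    }
  }
  fml <- stats::reformulate(terms, response = "slope_scaled")
  fit <- gibbs_lmm(
    d, fml,
    random = list(ranef_block("genus"), ranef_block("family"),
                  ranef_block("superfamily")),
    mcmc = mcmc
  )
  out <- dplyr::bind_rows(tidy(fit, "fixed"), tidy(fit, "var"))
  structure(out, class = c("moth_trait_model", class(out)), fit = fit,
            scale = scale)
}

#' Published species slope table
#'
#' The 57 printed species-specific centre-of-gravity slopes with their 95%
#' HPD limits, bundled so the trend classification can be re-derived from
#' the published values ([classify_trends()] on this table gives 39
#' increased, 15 stable, 3 decreased).
#'
#' @return Tibble: `species`, `slope`, `hpd_lower`, `hpd_upper`.
#' @export
published_slope_table <- function() {
  readr::read_csv(system.file("extdata", "table2_slopes_published.csv",
                              package = "mothshift"),
                  show_col_types = FALSE)
}

#' Moran's I with group-membership weights
#'
#' Relational autocorrelation of species-level values under binary weights
#' `w_ij = 1` when two distinct species share a group (e.g. a genus):
#' `I = (n / sum(w)) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Its expectation under random permutation is `-1 / (n - 1)`. Used to
#' gauge taxonomic (phylogenetic) signal in slope values.
#'
#' @param values Numeric vector (one per species).
#' @param groups Group labels at one taxonomic level.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, groups) {
  n <- length(values)
  if (n < 3) abort("Need at least 3 species.", class = "mothshift_data_error")
  if (length(groups) != n) abort("`values` and `groups` lengths differ.")
  w <- outer(groups, groups, "==") & !diag(n)
  s0 <- sum(w)
  if (s0 == 0) abort("No within-group pairs.", class = "mothshift_data_error")
  xc <- values - mean(values)
  (n / s0) * sum(w * outer(xc, xc)) / sum(xc^2)
}

#' Moran's I across nested taxonomic levels
#'
#' @param data Data frame with a value column and taxonomic columns.
#' @param value Name of the value column.
#' @param levels Taxonomic column names, finest first.
#' @return Tibble: `level`, `morans_i`.
#' @export
morans_i_taxonomic <- function(data, value = "slope",
                               levels = c("genus", "family", "superfamily")) {
  purrr::map_dfr(levels, function(lv) {
    tibble::tibble(level = lv,
                   morans_i = morans_i(data[[value]], data[[lv]]))
  })
}

#' Caterpillar plot of species elevational slopes
#'
#' @param object A [species_slopes()] result.
#' @param ... Unused.
#' @return A ggplot ordering species by slope with HPD bars coloured by
#'   trend class.
#' @export
autoplot.moth_slopes <- function(object, ...) {
  d <- dplyr::arrange(tibble::as_tibble(object), .data$slope)
  d$species <- factor(d$species, levels = d$species)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slope, y = .data$species,
                                  colour = .data$classification)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hpd_lower,
                                          xmax = .data$hpd_upper)) +
    ggplot2::labs(x = "Elevational slope (m/yr)", y = NULL,
                  colour = "Trend",
                  title = "Centre-of-gravity change per species")
}
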