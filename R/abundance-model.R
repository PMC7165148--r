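#' Annual catch table with lagged climate covariates
#'
#' One row per species x trap x year with the log10(n + 1) annual catch
#' (zeros retained), the vegetation zone and centred elevation
#' (elevation - 340 m, giving the 0-130 m continuous scale), joined to the
#' previous year's season length and season end. Years whose preceding
#' season metrics are unavailable are dropped with a message.
#'
#' @param catches Catch records.
#' @param metrics Season metrics from [season_metrics()].
#' @param layout Trap layout ([trap_layout()]).
#' @return Tibble: `species`, `trap_id`, `zone`, `year`, `n`, `log_catch`,
#'   `elevation_centered`, `season_length_prev`, `season_end_prev`.
#' @export
build_catch_table <- function(catches, metrics, layout = trap_layout()) {
  years <- sort(unique(catches$year))
  grid <- tidyr::expand_grid(
    species = sort(unique(catches$species)),
    trap_id = layout$trap_id,
    year = years
  )
  annual <- catches |>
    dplyr::group_by(.data$species, .data$trap_id, .data$year) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  lag <- metrics |>
    dplyr::transmute(year = .data$year + 1L,
                     season_length_prev = as.numeric(.data$length_days),
                     season_end_prev = as.numeric(.data$end_day))
  out <- grid |>
    dplyr::left_join(annual, by = c("species", "trap_id", "year")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  log_catch = log10(.data$n + 1)) |>
    dplyr::left_join(layout, by = "trap_id") |>
    dplyr::mutate(elevation_centered = .data$elevation_m - min(layout$elevation_m)) |>
    dplyr::left_join(lag, by = "year")
  miss <- is.na(out$season_length_prev) | is.na(out$season_end_prev)
  if (any(miss)) {
    inform(sprintf("Dropping %d rows (%d year(s)) without previous-season metrics.",
                   sum(miss), dplyr::n_distinct(out$year[miss])))
    out <- out[!miss, ]
  }
  dplyr::select(out, "species", "trap_id", "zone", "year", "n", "log_catch",
                "elevation_centered", "season_length_prev", "season_end_prev")
}

#' Mixed model for annual abundance against previous-season climate
#'
#' log10(n + 1) annual catch per species and trap explained by vegetation
#' zone (reference: the lowest, spruce zone `a`), the previous year's
#' season length and season end, and the zone x climate interactions.
#' Random effects: trap intercepts (traps as repeated measurements within a
#' zone), year intercepts, and a species-level correlated
#' (intercept, elevation) block with elevation continuous on the 0-130 m
#' scale. Climate covariates are standardized internally for mixing and
#' coefficients are back-transformed to the per-day scale for reporting.
#'
#' @param table Output of [build_catch_table()].
#' @param mcmc An [mcmc_config()].
#' @return Tibble of class `moth_abundance_model` (posterior summaries on
#'   the raw per-unit scale); `gibbs_lmm` fit in attribute `fit`.
#' @export
abundance_climate_model <- function(table, mcmc = mcmc_config()) {
  if (dplyr::n_distinct(table$zone) < 2) {
    abort("Need at least 2 elevation zones.", class = "mothshift_data_error")
  }
  if (dplyr::n_distinct(table$year) < 10) {
    abort("Need at least 10 years.", class = "mothshift_data_error")
  }
  traps_per_zone <- table |>
    dplyr::distinct(.data$zone, .data$trap_id) |>
    dplyr::count(.data$zone)
  if (any(traps_per_zone$n == 1)) {
    warn(paste("Zone(s) with a single trap (trap variance weakly identified):",
               paste(traps_per_zone$zone[traps_per_zone$n == 1], collapse = ", ")))
  }
  d <- table
  d$zone <- factor(d$zone)
  d$year_f <- factor(d$year)
  m_l <- mean(d$season_length_prev); s_l <- sd(d$season_length_prev)
  m_e <- mean(d$season_end_prev); s_e <- sd(d$season_end_prev)
  d$len_z <- (d$season_length_prev - m_l) / s_l
  d$end_z <- (d$season_end_prev - m_e) / s_e

  fit <- gibbs_lmm(
    d, log_catch ~ zone + len_z + end_z + zone:len_z + zone:end_z,
    random = list(ranef_block("trap_id"), ranef_block("year_f"),
                  ranef_block("species", slope = "elevation_centered")),
    mcmc = mcmc
  )

  # back-transform the fixed-effect draws to the raw per-day scale
  draws <- fit$draws[, fit$fixed_names, drop = FALSE]
  zones <- levels(d$zone)[-1]
  raw <- draws
  for (cn in colnames(draws)) {
    if (cn == "len_z") raw[, cn] <- draws[, cn] / s_l
    else if (cn == "end_z") raw[, cn] <- draws[, cn] / s_e
    else if (grepl(":len_z$", cn)) raw[, cn] <- draws[, cn] / s_l
    else if (grepl(":end_z$", cn)) raw[, cn] <- draws[, cn] / s_e
  }
  raw[, "(Intercept)"] <- draws[, "(Intercept)"] -
    draws[, "len_z"] * m_l / s_l - draws[, "end_z"] * m_e / s_e
  for (z in zones) {
    zn <- paste0("zone", z)
    raw[, zn] <- draws[, zn] -
      draws[, paste0(zn, ":len_z")] * m_l / s_l -
      draws[, paste0(zn, ":end_z")] * m_e / s_e
  }
  nice <- function(cn) {
    cn <- sub("^zone([^:]+)$", "zone_\\1", cn)
    cn <- sub("^zone([^:]+):len_z$", "zone_\\1:season_length", cn)
    cn <- sub("^zone([^:]+):end_z$", "zone_\\1:season_end", cn)
    cn[cn == "len_z"] <- "season_length"
    cn[cn == "end_z"] <- "season_end"
    cn
  }
  colnames(raw) <- nice(colnames(raw))
  out <- dplyr::bind_rows(posterior_summary(raw), tidy(fit, "var"))
  structure(out, class = c("moth_abundance_model", class(out)), fit = fit,
            scaling = list(m_l = m_l, s_l = s_l, m_e = m_e, s_e = s_e))
}
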