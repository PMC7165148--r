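#' Light-trap transect layout
#'
#' Default layout: 11 fixed traps on a north-facing slope, three in a spruce
#' ravine (zone `a`, 340-344 m), three in pine forest (zone `b`, 360-366 m),
#' three in mountain birch (zone `c`, 385-418 m) and two on the treeless
#' summit (zone `d`, 462-470 m). Trap positions never move between years.
#'
#' @param traps Optional tibble (`trap_id`, `elevation_m`, `zone`) replacing
#'   the default; elevations must lie in 340-470 m.
#' @return Tibble with columns `trap_id`, `elevation_m`, `zone`.
#' @export
trap_layout <- function(traps = NULL) {
  if (is.null(traps)) {
    traps <- tibble::tibble(
      trap_id = sprintf("T%02d", 1:11),
      elevation_m = c(340, 342, 344, 360, 363, 366, 385, 400, 418, 462, 470),
      zone = c(rep("a", 3), rep("b", 3), rep("c", 3), rep("d", 2))
    )
  }
  traps <- tibble::as_tibble(traps)
  stopifnot(all(c("trap_id", "elevation_m", "zone") %in% names(traps)))
  if (any(traps$elevation_m < 340 | traps$elevation_m > 470)) {
    abort("Trap elevations must lie within [340, 470] m.",
          class = "mothshift_config_error")
  }
  traps
}

#' Configuration for one synthetic species
#'
#' Ground-truth parameters of a species' capture process: annual abundance,
#' Gaussian elevation preference (with an optional linear drift of its
#' realized centre of gravity), a Gaussian flight curve, the response of
#' log10 abundance to the previous season's length, and trait/taxonomy
#' labels used by the trait model.
#'
#' @param species_id Species label.
#' @param base_abundance Expected individuals per year at an average-length
#'   previous season (>= 0).
#' @param elevation_mean0 Elevation-preference mean in the first catch year,
#'   m a.s.l.
#' @param elevation_sd SD of the elevation preference, m (> 0).
#' @param elevation_drift Ground-truth change in the species' realized
#'   centre of gravity, m per year.
#' @param flight_peak_day,flight_sd Gaussian flight-curve peak (Julian day)
#'   and width in days (> 0).
#' @param season_length_effect Slope of log10 annual abundance on the
#'   previous year's season length (per day).
#' @param climate_response Species-level scaling of the season-length
#'   effect (1 = fully responsive; 0 for fell-top species whose abundance
#'   does not track season length).
#' @param overwinter_stage,life_cycle,host_type,host_specificity Trait
#'   levels (see [trait_levels()]).
#' @param genus,family,superfamily Taxonomic labels.
#' @return One-row tibble.
#' @export
species_config <- function(species_id,
                           base_abundance = 100,
                           elevation_mean0 = 380,
                           elevation_sd = 40,
                           elevation_drift = 0,
                           flight_peak_day = 200,
                           flight_sd = 10,
                           season_length_effect = 0.0026,
                           climate_response = 1,
                           overwinter_stage = "larva-fullgrown-or-pupa",
                           life_cycle = "annual",
                           host_type = "dwarf shrubs",
                           host_specificity = "polyphagy",
                           genus = "Genus01",
                           family = "Family01",
                           superfamily = "Superfamily01") {
  if (elevation_sd <= 0 || flight_sd <= 0 || base_abundance < 0) {
    abort("Require elevation_sd > 0, flight_sd > 0, base_abundance >= 0.",
          class = "mothshift_config_error")
  }
  tibble::tibble(
    species_id = species_id, base_abundance = base_abundance,
    elevation_mean0 = elevation_mean0, elevation_sd = elevation_sd,
    elevation_drift = elevation_drift, flight_peak_day = flight_peak_day,
    flight_sd = flight_sd, season_length_effect = season_length_effect,
    climate_response = climate_response,
    overwinter_stage = overwinter_stage, life_cycle = life_cycle,
    host_type = host_type, host_specificity = host_specificity,
    genus = genus, family = family, superfamily = superfamily
  )
}

#' Recognized trait levels
#'
#' Level sets for the four species traits used by the trait model, with the
#' reference level first (adult / annual / dwarf shrubs / polyphagy).
#' @return Named list of character vectors.
#' @export
trait_levels <- function() {
  list(
    overwinter_stage = c("adult", "egg", "larva-unspecified",
                         "larva-adolescent", "larva-fullgrown-or-pupa"),
    life_cycle = c("annual", "biennial"),
    host_type = c("dwarf shrubs", "herbaceous", "mixed", "trees/bushes",
                  "non-vascular", "non-plants"),
    host_specificity = c("polyphagy", "oligophagy", "monophagy", "unspecified")
  )
}

#' The standard 20-species synthetic community
#'
#' A fixed roster spanning the study conditions: five mid-gradient species
#' drifting uphill at +1 m/yr (including one at base abundance 300), two
#' retreating at -0.5 m/yr, and thirteen stationary species across the
#' elevational gradient including tundra and spruce-zone specialists and two
#' rare species designed to fail the abundance selection filters. Expected
#' totals come to roughly 150,000 individuals over a 35-year record.
#'
#' @return Tibble of species configurations.
#' @export
standard_species_set <- function() {
  cfg <- dplyr::bind_rows(
    species_config("sp01", 800, 370, 40, 1.0, 195, 10, genus = "Genus01", family = "Family01", superfamily = "Superfamily01"),
    species_config("sp02", 480, 385, 40, 1.0, 205, 12, genus = "Genus01", family = "Family01", superfamily = "Superfamily01", host_type = "trees/bushes"),
    species_config("sp03", 320, 375, 35, 1.0, 185, 9, genus = "Genus02", family = "Family01", superfamily = "Superfamily01", overwinter_stage = "egg"),
    species_config("sp04", 240, 395, 45, 1.0, 210, 11, genus = "Genus03", family = "Family02", superfamily = "Superfamily01", host_specificity = "monophagy"),
    species_config("sp05", 300, 380, 40, 1.0, 200, 10, genus = "Genus03", family = "Family02", superfamily = "Superfamily01"),
    species_config("sp06", 400, 350, 30, 0, 190, 8, genus = "Genus04", family = "Family02", superfamily = "Superfamily01", host_type = "trees/bushes", overwinter_stage = "adult"),
    species_config("sp07", 280, 360, 35, 0, 200, 10, genus = "Genus05", family = "Family03", superfamily = "Superfamily02", life_cycle = "biennial"),
    species_config("sp08", 200, 400, 40, 0, 215, 12, genus = "Genus05", family = "Family03", superfamily = "Superfamily02", host_type = "herbaceous"),
    species_config("sp09", 120, 430, 45, 0, 180, 9, genus = "Genus06", family = "Family03", superfamily = "Superfamily02", overwinter_stage = "larva-adolescent", climate_response = 0),
    species_config("sp10", 95, 470, 40, 0, 205, 10, genus = "Genus06", family = "Family03", superfamily = "Superfamily02", host_type = "non-vascular", climate_response = 0),
    species_config("sp11", 80, 340, 25, 0, 195, 7, genus = "Genus07", family = "Family04", superfamily = "Superfamily02", host_specificity = "oligophagy"),
    species_config("sp12", 65, 390, 50, 0, 225, 14, genus = "Genus07", family = "Family04", superfamily = "Superfamily02"),
    species_config("sp13", 55, 365, 30, 0, 170, 8, genus = "Genus08", family = "Family04", superfamily = "Superfamily02", overwinter_stage = "egg"),
    species_config("sp14", 48, 410, 45, 0, 230, 15, genus = "Genus08", family = "Family05", superfamily = "Superfamily03", host_type = "non-plants"),
    species_config("sp15", 40, 355, 35, 0, 200, 10, genus = "Genus09", family = "Family05", superfamily = "Superfamily03", life_cycle = "biennial"),
    species_config("sp16", 160, 420, 40, -0.5, 190, 10, genus = "Genus09", family = "Family05", superfamily = "Superfamily03", host_type = "herbaceous"),
    species_config("sp17", 95, 385, 35, -0.5, 210, 12, genus = "Genus10", family = "Family05", superfamily = "Superfamily03", host_specificity = "monophagy"),
    species_config("sp18", 32, 375, 40, 0, 185, 9, genus = "Genus10", family = "Family06", superfamily = "Superfamily03", host_specificity = "unspecified"),
    species_config("sp19", 20, 360, 35, 0, 205, 11, genus = "Genus11", family = "Family06", superfamily = "Superfamily03", overwinter_stage = "larva-unspecified", host_type = "mixed"),
    species_config("sp20", 5, 395, 45, 0, 200, 10, genus = "Genus11", family = "Family06", superfamily = "Superfamily03", host_type = "mixed")
  )
  cfg
}

# Centre of gravity over the trap set implied by a Gaussian elevation
# preference with mean mu: normalized trap weights (optionally distorted by
# per-trap multiplicative factors such as a zone-specific climate response)
# times elevations.
cog_of_preference <- function(mu, sd, elevations, fac = 1) {
  w <- dnorm(elevations, mu, sd) * fac
  if (sum(w) == 0) {
    # preference far outside the transect: all mass on the nearest trap
    nearest <- which.min(abs(elevations - mu))
    return(elevations[nearest])
  }
  sum(elevations * w) / sum(w)
}

# Invert cog_of_preference: preference mean whose induced COG equals the
# target under the given per-trap factors. The drift parameter is defined
# on the realized COG scale, so the preference mean follows the (nonlinear)
# inverse path, absorbing any deterministic weight distortion.
preference_for_cog <- function(target, sd, elevations, fac = 1) {
  lo <- min(elevations) - 6 * sd
  hi <- max(elevations) + 6 * sd
  clo <- cog_of_preference(lo, sd, elevations, fac)
  chi <- cog_of_preference(hi, sd, elevations, fac)
  if (target <= clo) return(lo)
  if (target >= chi) return(hi)
  uniroot(function(m) cog_of_preference(m, sd, elevations, fac) - target,
          c(lo, hi), tol = 1e-8)$root
}

#' Simulate light-trap catch records with a known ground truth
#'
#' Daily counts for every (species, trap, day) follow a counting process
#' whose expectation factorizes into an annual abundance (log10-linear in
#' the previous year's true season length), a Gaussian flight-curve day
#' weight, and a Gaussian elevation-preference trap weight normalized to
#' sum to one over the transect. Elevation drift moves the species'
#' realized centre of gravity linearly at `elevation_drift` m/yr (the
#' preference mean follows the matching inverse path, traps stay fixed).
#' The season-length response is scaled per species (`climate_response`),
#' so fell-top species can be made unresponsive while forest species track
#' the climate, which is what produces a negative tundra x season-length
#' interaction in the abundance model. Multiplicative lognormal noise
#' operates at the year level (shared across species), the species-year
#' level, and optionally the zone-year level.
#'
#' @param weather Output of [simulate_weather()] (supplies the true season
#'   lengths for the abundance coupling).
#' @param layout Trap layout from [trap_layout()].
#' @param species Tibble of species configurations.
#' @param seed Integer seed for all catch randomness.
#' @param years Catch years; defaults to all weather years except the first
#'   (needed as the abundance lag) and the last.
#' @param family Count noise: `"poisson"` (minimal counting assumption) or
#'   `"nbinom"` with `dispersion` as the size parameter.
#' @param dispersion Negative-binomial size (ignored for Poisson).
#' @param year_noise_sd SD (log10) of the shared year-level abundance noise.
#' @param species_year_noise_sd SD (log10) of species-by-year noise.
#' @param zone_response Named numeric per zone scaling the season-length
#'   response of the traps in that zone (uniform 1 by default). A
#'   non-uniform setting (e.g. `d = 0`) makes the climate benefit
#'   zone-specific; because trap weights are normalized, this also distorts
#'   the realized centre of gravity, which the ledger records as
#'   `cog_expected` next to the drift target `cog_true`.
#' @param zone_noise_sd Named numeric: SD (log10) of zone-by-year-by-species
#'   noise per zone. Zero by default, which keeps the expected counts
#'   exactly factorized (abundance x day weight x trap weight); set a
#'   larger tundra value to inject the elevated environmental
#'   stochasticity of the treeless summit for dispersion analyses.
#' @return A list of class `moth_catch_sim`:
#'   `catches` (tibble `date`, `year`, `day`, `trap_id`, `elevation_m`,
#'   `zone`, `species`, `count`, positive counts only) and `truth`, the
#'   ground-truth ledger (per-species parameters; per species-year true COG,
#'   expected and realized totals, and the noiseless flight window; grand
#'   totals). Tests read the ledger, the pipeline never does.
#' @export
generate_catches <- function(weather,
                             layout = trap_layout(),
                             species = standard_species_set(),
                             seed = 1L,
                             years = NULL,
                             family = c("poisson", "nbinom"),
                             dispersion = 5,
                             year_noise_sd = 0.15,
                             species_year_noise_sd = 0.2,
                             zone_response = c(a = 1, b = 1, c = 1, d = 1),
                             zone_noise_sd = c(a = 0, b = 0, c = 0, d = 0)) {
  family <- match.arg(family)
  if (nrow(species) < 1 || nrow(layout) < 1) {
    abort("Need at least one species and one trap.", class = "mothshift_config_error")
  }
  truth_w <- weather_truth(weather)
  wyears <- sort(unique(truth_w$year))
  if (is.null(years)) {
    years <- if (length(wyears) > 2) wyears[2:(length(wyears) - 1)] else wyears[-1]
  }
  if (!all((years - 1) %in% wyears)) {
    abort("Every catch year needs weather for the preceding year.",
          class = "mothshift_alignment_error")
  }
  if (length(years) < 1) abort("Need at least one catch year.", class = "mothshift_config_error")
  if (!all(layout$zone %in% names(zone_response))) {
    abort("`zone_response` must cover every zone in the layout.")
  }
  missing_zones <- setdiff(layout$zone, names(zone_noise_sd))
  if (length(missing_zones)) {
    abort(paste("No zone_noise_sd for zone(s):", paste(missing_zones, collapse = ", ")))
  }

  set.seed(seed)
  elevations <- layout$elevation_m
  zones <- layout$zone
  n_traps <- nrow(layout)
  cfgw <- attr(weather, "config")
  days <- seq(cfgw$first_day, cfgw$last_day)
  n_days <- length(days)
  len_by_year <- setNames(truth_w$length_true, truth_w$year)
  len_ref <- mean(len_by_year[as.character(years - 1)])

  year_noise <- setNames(rnorm(length(years), 0, year_noise_sd), years)
  thr_catch <- 10^0.2 - 1  # flight threshold back-transformed to a mean catch

  records <- vector("list", nrow(species) * length(years))
  truth_cog <- vector("list", nrow(species) * length(years))
  k <- 0L
  for (s in seq_len(nrow(species))) {
    sp <- species[s, ]
    cog0 <- cog_of_preference(sp$elevation_mean0, sp$elevation_sd, elevations)
    day_w <- dnorm(days, sp$flight_peak_day, sp$flight_sd)
    day_w <- day_w / sum(day_w)
    for (ti in seq_along(years)) {
      yr <- years[ti]
      t_idx <- ti - 1L
      cog_target <- cog0 + sp$elevation_drift * t_idx
      l_prev <- len_by_year[[as.character(yr - 1)]]
      mu_t <- if (sp$elevation_drift == 0) sp$elevation_mean0 else
        preference_for_cog(cog_target, sp$elevation_sd, elevations)
      trap_w <- dnorm(elevations, mu_t, sp$elevation_sd)
      if (sum(trap_w) == 0) {
        trap_w <- as.numeric(elevations == elevations[which.min(abs(elevations - mu_t))])
      }
      trap_w <- trap_w / sum(trap_w)
      # zone noise is drawn per zone (shared by its traps), per species-year
      zdraw <- setNames(10^(rnorm(length(unique(zones)), 0,
                                  zone_noise_sd[unique(zones)])), unique(zones))
      zfac <- unname(zdraw[zones])
      a_base <- sp$base_abundance *
        10^(year_noise[[as.character(yr)]] + rnorm(1, 0, species_year_noise_sd))
      cfac <- 10^(sp$season_length_effect * sp$climate_response *
                    unname(zone_response[zones]) * (l_prev - len_ref))
      a_trap <- a_base * trap_w * cfac * zfac
      lam <- outer(a_trap, day_w)  # traps x days
      cnt <- if (family == "poisson") {
        rpois(length(lam), lam)
      } else {
        rnbinom(length(lam), size = dispersion, mu = as.numeric(lam))
      }
      cnt <- matrix(cnt, n_traps, n_days)
      nz <- which(cnt > 0, arr.ind = TRUE)
      k <- k + 1L
      if (nrow(nz) > 0) {
        records[[k]] <- tibble::tibble(
          year = yr,
          day = days[nz[, 2]],
          trap_id = layout$trap_id[nz[, 1]],
          elevation_m = elevations[nz[, 1]],
          zone = zones[nz[, 1]],
          species = sp$species_id,
          count = as.integer(cnt[nz])
        )
      }
      mean_curve <- colSums(lam) / n_traps  # noiseless across-trap daily mean
      fly <- which(mean_curve > thr_catch)
      truth_cog[[k]] <- tibble::tibble(
        species = sp$species_id, year = yr,
        cog_true = cog_target,
        cog_expected = sum(elevations * trap_w * cfac) / sum(trap_w * cfac),
        pref_mean = mu_t,
        expected_total = sum(lam), realized_total = sum(cnt),
        flight_first = if (length(fly)) days[fly[1]] else NA_integer_,
        flight_last = if (length(fly)) days[fly[length(fly)]] else NA_integer_,
        flight_width = length(fly)
      )
    }
  }
  catches <- dplyr::bind_rows(records)
  catches$date <- as.Date(paste0(catches$year, "-01-01")) + (catches$day - 1L)
  catches <- catches[, c("date", "year", "day", "trap_id", "elevation_m",
                         "zone", "species", "count")]
  truth_cog <- dplyr::bind_rows(truth_cog)
  truth <- list(
    species = species,
    cog = truth_cog,
    totals = list(total_individuals = sum(catches$count),
                  total_expected = sum(truth_cog$expected_total)),
    seed = seed,
    years = years
  )
  structure(list(catches = catches, truth = truth), class = "moth_catch_sim")
}

#' Attach trait-driven ground-truth slopes to a species roster
#'
#' Builds a trait table and the per-species true centre-of-gravity slope
#' implied by a baseline, additive trait-level offsets, and iid taxonomic
#' random offsets at genus, family and superfamily level. Offsets are on the
#' display scale of the trait model (slope x 100), so an offset of 20 means
#' +0.2 m/yr.
#'
#' @param species Species roster (tibble with trait and taxonomy columns).
#' @param effect_map Named numeric vector of offsets for trait levels, e.g.
#'   `c("larva-fullgrown-or-pupa" = 20)`. Names must be known trait levels.
#' @param seed Integer seed for the taxonomic offsets.
#' @param baseline Baseline slope (x 100 scale).
#' @param taxo_sd Named SDs of the taxonomic random offsets.
#' @return List: `traits` (tibble `species`, four trait columns, taxonomy)
#'   and `truth` (tibble `species`, `true_slope_x100`, `true_slope` in m/yr).
#' @export
generate_traits <- function(species, effect_map = numeric(0), seed = 1L,
                            baseline = 0,
                            taxo_sd = c(genus = 3, family = 2, superfamily = 1)) {
  lv <- unlist(trait_levels(), use.names = FALSE)
  unknown <- setdiff(names(effect_map), lv)
  if (length(unknown)) {
    abort(paste("Unknown trait level(s) in effect_map:",
                paste(unknown, collapse = ", ")),
          class = "mothshift_config_error")
  }
  set.seed(seed)
  offsets_for <- function(values) {
    out <- numeric(length(values))
    for (nm in names(effect_map)) out <- out + effect_map[[nm]] * (values == nm)
    out
  }
  g_off <- setNames(rnorm(length(unique(species$genus)), 0, taxo_sd[["genus"]]),
                    unique(species$genus))
  f_off <- setNames(rnorm(length(unique(species$family)), 0, taxo_sd[["family"]]),
                    unique(species$family))
  sf_off <- setNames(rnorm(length(unique(species$superfamily)), 0,
                           taxo_sd[["superfamily"]]), unique(species$superfamily))
  slope <- baseline +
    offsets_for(species$overwinter_stage) + offsets_for(species$life_cycle) +
    offsets_for(species$host_type) + offsets_for(species$host_specificity) +
    g_off[species$genus] + f_off[species$family] + sf_off[species$superfamily]
  traits <- dplyr::select(species, "species_id", "overwinter_stage",
                          "life_cycle", "host_type", "host_specificity",
                          "genus", "family", "superfamily")
  traits <- dplyr::rename(traits, species = "species_id")
  truth <- tibble::tibble(species_id = species$species_id,
                          true_slope_x100 = unname(slope),
                          true_slope = unname(slope) / 100)
  truth <- dplyr::rename(truth, species = "species_id")
  list(traits = traits, truth = truth)
}

#' A randomized species roster for calibration studies
#'
#' Generates `n` species with randomized abundances, elevation preferences,
#' flight curves, trait levels and a nested taxonomy (superfamilies >
#' families > genera), for null-calibration and recovery studies that need
#' more species than the standard set.
#'
#' @param n Number of species.
#' @param seed Integer seed.
#' @return Tibble of species configurations.
#' @export
make_species_roster <- function(n = 60, seed = 1L) {
  set.seed(seed)
  lv <- trait_levels()
  n_sf <- max(2L, round(n / 15))
  n_fam <- max(3L, round(n / 5))
  n_gen <- max(4L, round(n / 2.5))
  fam_sf <- sample(seq_len(n_sf), n_fam, replace = TRUE)
  gen_fam <- sample(seq_len(n_fam), n_gen, replace = TRUE)
  gen_of <- sample(seq_len(n_gen), n, replace = TRUE)
  tibble::tibble(
    species_id = sprintf("rsp%03d", seq_len(n)),
    base_abundance = round(10^stats::runif(n, 1.2, 3)),
    elevation_mean0 = stats::runif(n, 345, 465),
    elevation_sd = stats::runif(n, 25, 55),
    elevation_drift = 0,
    flight_peak_day = round(stats::runif(n, 165, 235)),
    flight_sd = stats::runif(n, 6, 15),
    season_length_effect = 0.0026,
    climate_response = 1,
    overwinter_stage = sample(lv$overwinter_stage, n, replace = TRUE),
    life_cycle = sample(lv$life_cycle, n, replace = TRUE, prob = c(0.8, 0.2)),
    host_type = sample(lv$host_type, n, replace = TRUE),
    host_specificity = sample(lv$host_specificity, n, replace = TRUE),
    genus = sprintf("Genus%02d", gen_of),
    family = sprintf("Family%02d", gen_fam[gen_of]),
    superfamily = sprintf("Superfamily%02d", fam_sf[gen_fam[gen_of]])
  )
}
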