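#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- season metrics from the
#' weather, species selection, then the abundance model, elevational
#' trends (plus trait model when a trait table is given), flight-period
#' analysis and community ordination -- writing one CSV per stage to
#' `out_dir` and a JSON manifest listing every artifact with its MD5
#' checksum, row count and status. A failed stage is recorded and its
#' dependants are skipped rather than aborting the run. Every output file
#' carries the seed and a configuration hash in its comment header.
#'
#' @param weather Daily weather tibble (`year`, `day`, `temp_c`).
#' @param catches Catch records tibble.
#' @param traits Optional trait table with `species`, trait columns and
#'   taxonomy (enables the trait model).
#' @param out_dir Output directory (created if needed).
#' @param thresholds [climate_thresholds()].
#' @param criteria [selection_criteria()].
#' @param mcmc [mcmc_config()] shared by the model stages.
#' @param periods [period_spec()] for the community stage; defaults to
#'   nine periods tiling the catch years.
#' @param layout [trap_layout()].
#' @param seed Master seed recorded in the outputs and used for stages
#'   with their own randomness (ordination restarts, permutations).
#' @return Tibble manifest (`stage`, `status`, `file`, `md5`, `rows`,
#'   `message`); also written as `manifest.json`.
#' @export
run_pipeline <- function(weather, catches, traits = NULL,
                         out_dir = tempfile("mothshift_run_"),
                         thresholds = climate_thresholds(),
                         criteria = selection_criteria(),
                         mcmc = mcmc_config(),
                         periods = NULL,
                         layout = trap_layout(),
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = seed,
               config_hash = config_hash(list(thresholds = unclass(thresholds),
                                              criteria = unclass(criteria),
                                              mcmc = unclass(mcmc),
                                              seed = seed)))
  manifest <- list()
  done <- character(0)
  note <- function(stage, status, file = NA_character_, rows = NA_integer_,
                   message = "") {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, status = status, file = file,
      md5 = if (is.na(file)) NA_character_ else unname(tools::md5sum(file)),
      rows = rows, message = message)
    if (status == "ok") done <<- c(done, stage)
  }
  stage <- function(name, needs, expr) {
    if (!all(needs %in% done)) {
      note(name, "skipped", message = paste("needs", paste(setdiff(needs, done), collapse = ", ")))
      return(NULL)
    }
    tryCatch(expr, error = function(e) {
      note(name, "failed", message = conditionMessage(e))
      NULL
    })
  }

  metrics <- stage("seasons", character(0), {
    m <- season_metrics(weather, thresholds)
    f <- file.path(out_dir, "season_metrics.csv")
    write_with_metadata(m, f, meta)
    note("seasons", "ok", f, nrow(m))
    m
  })

  selection <- stage("selection", character(0), {
    s <- select_species(catches, criteria)
    f <- file.path(out_dir, "species_selection.csv")
    write_with_metadata(s, f, meta)
    note("selection", "ok", f, nrow(s))
    s
  })

  base_catches <- if (!is.null(selection)) {
    dplyr::semi_join(catches, dplyr::filter(selection, .data$in_base),
                     by = "species")
  } else catches

  stage("abundance", c("seasons", "selection"), {
    tab <- suppressMessages(build_catch_table(base_catches, metrics, layout))
    fitt <- abundance_climate_model(tab, mcmc)
    f <- file.path(out_dir, "abundance_model.csv")
    write_with_metadata(tibble::as_tibble(fitt), f, meta)
    note("abundance", "ok", f, nrow(fitt))
    fitt
  })

  slopes <- stage("elevation", "selection", {
    sl <- species_slopes(base_catches, mcmc)
    f <- file.path(out_dir, "elevation_slopes.csv")
    write_with_metadata(tibble::as_tibble(sl), f, meta)
    note("elevation", "ok", f, nrow(sl))
    sl
  })

  if (!is.null(traits)) {
    stage("traits", "elevation", {
      hist_cog <- historical_cog(base_catches)
      tt <- dplyr::inner_join(tibble::as_tibble(traits), hist_cog,
                              by = "species")
      tm <- trait_model(slopes, tt, mcmc)
      f <- file.path(out_dir, "trait_model.csv")
      write_with_metadata(tibble::as_tibble(tm), f, meta)
      note("traits", "ok", f, nrow(tm))
      tm
    })
  }

  stage("phenology", "selection", {
    flight_sp <- dplyr::filter(selection, .data$in_flight)$species
    if (length(flight_sp) < 2) abort("Fewer than 2 species pass the flight filters.")
    fp <- flight_period_table(
      dplyr::filter(catches, .data$species %in% flight_sp), weather,
      n_traps = nrow(layout))
    f <- file.path(out_dir, "flight_periods.csv")
    write_with_metadata(fp, f, meta)
    note("phenology", "ok", f, nrow(fp))
    fm <- suppressMessages(flight_period_model(fp, mcmc))
    f2 <- file.path(out_dir, "flight_model.csv")
    write_with_metadata(tibble::as_tibble(fm), f2, meta)
    note("phenology_model", "ok", f2, nrow(fm))
    fp
  })

  stage("community", "seasons", {
    ps <- periods %||% period_spec(start_year = min(catches$year),
                                   period_length = 4,
                                   n_periods = ceiling(dplyr::n_distinct(catches$year) / 4),
                                   end_year = max(catches$year))
    asm <- aggregate_periods(catches, ps, layout)
    mat <- assemblage_matrix(asm)
    ord <- nmds(bray_curtis(mat), seed = seed)
    env <- build_env_table(asm, layout, metrics, ps)
    ef <- envfit_ord(ord, env[, c("elevation_m", "period", "min_season_length")],
                     n_perm = 999, seed = seed)
    coords <- tibble::as_tibble(ord$points, rownames = "assemblage")
    coords$stress <- ord$stress
    f <- file.path(out_dir, "nmds_coordinates.csv")
    write_with_metadata(coords, f, meta)
    note("community", "ok", f, nrow(coords))
    f2 <- file.path(out_dir, "envfit.csv")
    write_with_metadata(tibble::as_tibble(ef), f2, meta)
    note("community_envfit", "ok", f2, nrow(ef))
    ord
  })

  manifest <- dplyr::bind_rows(manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  manifest
}
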