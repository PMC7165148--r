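#' @name moth_io
#' @title Read and write the pipeline's CSV formats
#'
#' @description All files are RFC-4180 UTF-8 CSVs with a header row.
#' Writers prepend comment lines (`# key: value`) recording the seed and a
#' configuration hash so any numeric output can be reproduced
#' bit-identically; readers skip `#` lines.
#'
#' Catch CSV columns: `date` (ISO-8601), `trap_id`, `elevation_m`, `zone`,
#' `species`, `count`. Weather CSV: `date`, `temp_c`. Traits CSV:
#' `species`, trait columns, taxonomy.
NULL

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

write_with_metadata <- function(data, path, metadata = list()) {
  lines <- c(
    sprintf("# written_by: mothshift %s", as.character(utils::packageVersion("mothshift"))),
    purrr::imap_chr(metadata, ~ sprintf("# %s: %s", .y, as.character(.x)))
  )
  writeLines(lines, path)
  readr::write_csv(data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname moth_io
#' @param weather,catches,traits,data Tibbles to write.
#' @param path File path.
#' @param metadata Named list written as `# key: value` header comments.
#' @export
write_weather_csv <- function(weather, path, metadata = list()) {
  write_with_metadata(dplyr::select(tibble::as_tibble(weather),
                                    "date", "temp_c"), path, metadata)
}

#' @rdname moth_io
#' @export
read_weather_csv <- function(path) {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(date = readr::col_date(),
                                               temp_c = readr::col_double()))
  d$year <- as.integer(format(d$date, "%Y"))
  d$day <- as.integer(format(d$date, "%j"))
  d[, c("year", "date", "day", "temp_c")]
}

#' @rdname moth_io
#' @export
write_catch_csv <- function(catches, path, metadata = list()) {
  write_with_metadata(dplyr::select(tibble::as_tibble(catches), "date",
                                    "trap_id", "elevation_m", "zone",
                                    "species", "count"), path, metadata)
}

#' @rdname moth_io
#' @export
read_catch_csv <- function(path) {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(
                         date = readr::col_date(),
                         trap_id = readr::col_character(),
                         elevation_m = readr::col_double(),
                         zone = readr::col_character(),
                         species = readr::col_character(),
                         count = readr::col_integer()))
  d$year <- as.integer(format(d$date, "%Y"))
  d$day <- as.integer(format(d$date, "%j"))
  d
}

#' @rdname moth_io
#' @export
write_traits_csv <- function(traits, path, metadata = list()) {
  write_with_metadata(tibble::as_tibble(traits), path, metadata)
}

#' @rdname moth_io
#' @export
read_traits_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write the ground-truth ledger of a simulation
#'
#' The ledger (per-species parameters, per species-year true centre of
#' gravity and flight window, grand totals, seed) is written as JSON next
#' to the catch CSV; tests read it, the analysis pipeline never does.
#'
#' @param sim A [generate_catches()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger_json <- function(sim, path) {
  stopifnot(inherits(sim, "moth_catch_sim"))
  jsonlite::write_json(sim$truth, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate a catch CSV
#'
#' Schema check plus per-row validation: parseable dates, non-negative
#' integer counts, and elevation/zone consistency against a trap layout.
#'
#' @param path File path.
#' @param layout Trap layout giving the valid trap/elevation/zone triples.
#' @return Tibble of violations (`row`, `field`, `problem`); zero rows for
#'   a valid file.
#' @export
validate_catch_csv <- function(path, layout = trap_layout()) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path),
                                class = "mothshift_io_error")
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("date", "trap_id", "elevation_m", "zone", "species", "count")
  missing <- setdiff(required, names(raw))
  out <- list()
  if (length(missing)) {
    return(tibble::tibble(row = NA_integer_, field = missing,
                          problem = "missing column"))
  }
  dates <- suppressWarnings(as.Date(raw$date))
  bad <- which(is.na(dates))
  if (length(bad)) out <- c(out, list(tibble::tibble(
    row = bad, field = "date", problem = "unparseable date")))
  cnt <- suppressWarnings(as.numeric(raw$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad)) out <- c(out, list(tibble::tibble(
    row = bad, field = "count", problem = "not a non-negative integer")))
  key <- paste(raw$trap_id, raw$elevation_m, raw$zone)
  valid <- paste(layout$trap_id, layout$elevation_m, layout$zone)
  bad <- which(!(key %in% valid))
  if (length(bad)) out <- c(out, list(tibble::tibble(
    row = bad, field = "trap_id/elevation_m/zone",
    problem = "inconsistent with trap layout")))
  if (length(out) == 0) {
    return(tibble::tibble(row = integer(0), field = character(0),
                          problem = character(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$row)
}
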