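#' Read and write the standard table dialects
#'
#' All tables are UTF-8 comma-delimited CSV with '.' decimal separators and
#' a header row; header order is irrelevant and identifiers are read as
#' opaque strings. Each reader validates its table on the way in; each
#' writer emits numbers at full precision, so every writer/reader pair
#' round-trips exactly.
#'
#' Dialects: zones (`zone_id,county_id,lat,lon,population,coastal`),
#' exposure (`subzone_id,zone_id,slr_m,population,affected_population`),
#' flows (`origin_id,dest_id,migrants,year`).
#'
#' @param path file path.
#' @name table_io
NULL

read_csv_strict <- function(path, cols, what) {
  if (!file.exists(path)) stop_slrmig("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_columns(df, cols, what)
  df
}

#' @rdname table_io
#' @export
read_zones <- function(path) {
  df <- read_csv_strict(path, c("zone_id", "county_id", "lat", "lon",
                                "population", "coastal"), "zone file")
  zone_set(df$zone_id, df$county_id, as.numeric(df$lat), as.numeric(df$lon),
           as.numeric(df$population),
           as.logical(df$coastal) | df$coastal %in% c("1", "true", "TRUE"))
}

#' @rdname table_io
#' @param zones a [zone_set()].
#' @export
write_zones <- function(zones, path) {
  utils::write.csv(as.data.frame(zones), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_exposure <- function(path) {
  df <- read_csv_strict(path, c("subzone_id", "zone_id", "slr_m",
                                "population", "affected_population"),
                        "exposure file")
  for (col in c("slr_m", "population", "affected_population")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  exposure_table(df)
}

#' @rdname table_io
#' @param exposure an [exposure_table()].
#' @export
write_exposure <- function(exposure, path) {
  utils::write.csv(as.data.frame(exposure), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_flow_table <- function(path) {
  df <- read_csv_strict(path, c("origin_id", "dest_id", "migrants"),
                        "flow file")
  df$migrants <- as.numeric(df$migrants)
  if (!"year" %in% names(df)) df$year <- NA_real_ else
    df$year <- as.numeric(df$year)
  df <- df[c("origin_id", "dest_id", "migrants", "year")]
  neg <- which(df$migrants < 0)
  if (length(neg) > 0L) {
    stop_slrmig("negative migrant count at row(s): ",
                paste(neg, collapse = ", "))
  }
  key <- paste(df$origin_id, df$dest_id, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop_slrmig("duplicate flow key (origin, dest, year): (",
                dup$origin_id, ", ", dup$dest_id, ", ", dup$year, ")")
  }
  df
}

#' @rdname table_io
#' @param flows a flow table.
#' @export
write_flow_table <- function(flows, path) {
  utils::write.csv(as.data.frame(flows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_timeline <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  sched <- as.data.frame(cfg$schedule)
  names(sched) <- c("slr_m", "year")
  slr_timeline(cfg$name, schedule = sched)
}

#' @rdname table_io
#' @param timeline an [slr_timeline()].
#' @export
write_timeline <- function(timeline, path) {
  jsonlite::write_json(list(name = timeline$name,
                            schedule = unname(as.matrix(timeline$schedule))),
                       path, digits = NA)
  invisible(path)
}

#' Write migration matrices from a scenario run
#'
#' One long CSV with columns
#' `origin_id,dest_id,flow,year,component` covering every step's climate and
#' business-as-usual flows, plus a county roll-up CSV, plus a JSON metadata
#' file recording the run settings.
#'
#' @param scenario an `slr_scenario`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "slr_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  roll <- list()
  for (s in scenario$steps) {
    if (nrow(s$total) > 0L) {
      r <- as.data.frame(s$total)
      r$year <- s$year
      rows[[length(rows) + 1L]] <-
        r[c("origin_id", "dest_id", "flow", "year", "component")]
      cr <- county_rollup(s$total)
      cr$year <- s$year
      roll[[length(roll) + 1L]] <- cr
    }
  }
  mat_path <- file.path(dir, "migration_matrix.csv")
  roll_path <- file.path(dir, "migration_matrix_county.csv")
  meta_path <- file.path(dir, "run_metadata.json")
  empty <- data.frame(origin_id = character(0), dest_id = character(0),
                      flow = numeric(0), year = numeric(0),
                      component = character(0))
  utils::write.csv(if (length(rows)) do.call(rbind, rows) else empty,
                   mat_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(if (length(roll)) do.call(rbind, roll) else
    empty[c("origin_id", "dest_id", "flow", "year")],
    roll_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(scenario = scenario$timeline$name,
                            mode = scenario$mode,
                            model_mode = scenario$model_mode,
                            rate_C = scenario$rate_C,
                            rate_S = scenario$rate_S,
                            years = vapply(scenario$steps, `[[`, 0, "year")),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(mat_path, roll_path, meta_path))
}

#' Write an effects report
#'
#' Emits the per-county table (one CSV covering every step) and a summary
#' JSON keyed by step with the directly affected population and, for every
#' configured threshold `d`, the indirectly-affected county count and
#' population. Numbers are serialised at full precision.
#'
#' @param report an `effects_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_effects_report <- function(report, dir) {
  stopifnot(inherits(report, "effects_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(dir, "effects_by_county.csv")
  json_path <- file.path(dir, "effects_summary.json")
  county <- do.call(rbind, report$by_county)
  if (is.null(county)) {
    county <- data.frame(county_id = character(0), year = numeric(0),
                         slr_m = numeric(0))
  }
  utils::write.csv(county, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(d = report$d, summary = report$summary),
                       json_path, digits = NA, dataframe = "columns")
  invisible(c(csv_path, json_path))
}

#' Read and write a run configuration
#'
#' A JSON run configuration collects paths, scenario name, mode flags,
#' model hyperparameters, production rates, thresholds and seed. Every run
#' driven by the command-line interface writes a resolved copy of its
#' configuration alongside its outputs for reproducibility.
#'
#' @param path JSON file path.
#' @param config a named list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(scenario = "high", mode = "exogenous",
                   model_mode = "dual", rate_C = 1, rate_S = 0.03,
                   d = c(0.5, 1, 3, 6, 9), seed = 1, intra_km = 1)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
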