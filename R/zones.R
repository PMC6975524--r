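#' Construct a validated zone table
#'
#' A zone is the spatial unit of the simulation (a county equivalent): an
#' identifier, the county it belongs to, a centroid in decimal degrees, a
#' nonnegative population, and a flag marking it as coastal. Identifiers are
#' treated as opaque strings throughout.
#'
#' @param zone_id character vector of unique zone identifiers.
#' @param county_id character vector mapping each zone to a county. Defaults
#'   to `zone_id` (zone = county granularity, the usual case).
#' @param lat,lon centroid coordinates in decimal degrees.
#' @param population nonnegative zone populations (reals are accepted;
#'   projections may be fractional).
#' @param coastal logical flag; coastal zones are the candidates for flooding
#'   exposure and for the hurricane shock filter.
#' @return A `data.frame` of class `zone_set` with columns `zone_id`,
#'   `county_id`, `lat`, `lon`, `population`, `coastal`.
#' @examples
#' zone_set(c("a", "b"), lat = c(30, 31), lon = c(-90, -89),
#'          population = c(1000, 2000), coastal = c(TRUE, FALSE))
#' @export
zone_set <- function(zone_id, county_id = zone_id, lat, lon, population,
                     coastal = FALSE) {
  zone_id <- as.character(zone_id)
  county_id <- as.character(county_id)
  n <- length(zone_id)
  coastal <- rep_len(as.logical(coastal), n)
  df <- data.frame(zone_id = zone_id, county_id = county_id,
                   lat = as.numeric(lat), lon = as.numeric(lon),
                   population = as.numeric(population), coastal = coastal,
                   stringsAsFactors = FALSE)
  validate_zone_set(df)
}

validate_zone_set <- function(df) {
  check_columns(df, c("zone_id", "county_id", "lat", "lon", "population",
                      "coastal"), "zone table")
  if (anyDuplicated(df$zone_id)) {
    dup <- unique(df$zone_id[duplicated(df$zone_id)])
    stop_slrmig("duplicate zone_id: ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(df$population)) || any(df$population < 0)) {
    stop_slrmig("zone populations must be finite and nonnegative")
  }
  if (any(df$lat < -90 | df$lat > 90)) {
    stop_slrmig("latitude out of [-90, 90]")
  }
  if (any(df$lon < -180 | df$lon > 180)) {
    stop_slrmig("longitude out of [-180, 180]")
  }
  class(df) <- c("zone_set", "data.frame")
  df
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("Zone set: %d zones in %d counties (%d coastal), population %s\n",
              nrow(x), length(unique(x$county_id)), sum(x$coastal),
              format(sum(x$population), big.mark = ",")))
  NextMethod()
}

#' Built-in and custom sea-level-rise timelines
#'
#' A timeline schedules when each sea-level-rise increment is reached under a
#' named scenario. Two standard schedules are built in: `"medium"` reaches
#' 0.3, 0.6 and 0.9 m in 2055, 2080 and 2100; `"high"` reaches 0.3 through
#' 1.8 m in 2042, 2059, 2071, 2082, 2091 and 2100. Custom schedules may be
#' supplied as a two-column structure of (increment in metres, calendar year),
#' both strictly increasing.
#'
#' @param name scenario name, `"medium"` or `"high"`, or an arbitrary label
#'   when `schedule` is given.
#' @param schedule optional data.frame or matrix with columns `slr_m`, `year`.
#' @return An object of class `slr_timeline`.
#' @examples
#' slr_timeline("medium")
#' timeline_lookup(slr_timeline("high"), 2082)  # 1.2
#' @export
slr_timeline <- function(name = c("medium", "high"), schedule = NULL) {
  if (is.null(schedule)) {
    name <- match.arg(name)
    schedule <- switch(name,
      medium = data.frame(slr_m = c(0.3, 0.6, 0.9),
                          year = c(2055, 2080, 2100)),
      high = data.frame(slr_m = c(0.3, 0.6, 0.9, 1.2, 1.5, 1.8),
                        year = c(2042, 2059, 2071, 2082, 2091, 2100))
    )
  } else {
    name <- as.character(name)[1L]
    schedule <- as.data.frame(schedule)
    if (ncol(schedule) < 2L) stop_slrmig("schedule needs (slr_m, year) columns")
    if (!all(c("slr_m", "year") %in% names(schedule))) {
      names(schedule)[1:2] <- c("slr_m", "year")
    }
    schedule <- schedule[c("slr_m", "year")]
  }
  schedule$slr_m <- as.numeric(schedule$slr_m)
  schedule$year <- as.numeric(schedule$year)
  if (nrow(schedule) == 0L) stop_slrmig("timeline schedule is empty")
  if (any(diff(schedule$year) <= 0)) {
    stop_slrmig("timeline years must be strictly increasing")
  }
  if (any(diff(schedule$slr_m) <= 0)) {
    stop_slrmig("timeline increments must be strictly increasing")
  }
  structure(list(name = name, schedule = schedule), class = "slr_timeline")
}

#' @rdname slr_timeline
#' @param timeline an `slr_timeline`.
#' @param year calendar year(s) to query.
#' @return `timeline_lookup` returns the largest scheduled increment whose
#'   year is at or before `year`, and 0 before the first scheduled year: a
#'   nondecreasing step function of time.
#' @export
timeline_lookup <- function(timeline, year) {
  stopifnot(inherits(timeline, "slr_timeline"))
  sched <- timeline$schedule
  idx <- findInterval(year, sched$year)
  ifelse(idx == 0L, 0, sched$slr_m[pmax(idx, 1L)])
}

#' @export
print.slr_timeline <- function(x, ...) {
  cat(sprintf("SLR timeline '%s':\n", x$name))
  print(x$schedule, row.names = FALSE)
  invisible(x)
}
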