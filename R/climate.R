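#' Validate a flooding exposure table
#'
#' Exposure arrives as a long table with one row per sub-zone (block-group
#' analogue) and sea-level-rise increment, carrying the sub-zone's projected
#' population at that increment and the number of those people on land
#' flooded at that increment. Flooding must be physically consistent:
#' `0 <= affected_population <= population`, and for a fixed sub-zone the
#' affected population must be nondecreasing in the increment (flooded land
#' stays flooded as the sea rises).
#'
#' @param exposure data.frame with columns `subzone_id`, `zone_id`, `slr_m`,
#'   `population`, `affected_population`.
#' @param zones optional `zone_set`; when given, every `zone_id` in the
#'   exposure table must exist in it.
#' @param check_nesting verify monotone flooding across increments
#'   (default TRUE).
#' @return The validated exposure table (class `exposure_table`).
#' @export
exposure_table <- function(exposure, zones = NULL, check_nesting = TRUE) {
  exposure <- as.data.frame(exposure)
  check_columns(exposure, c("subzone_id", "zone_id", "slr_m", "population",
                            "affected_population"), "exposure table")
  exposure$subzone_id <- as.character(exposure$subzone_id)
  exposure$zone_id <- as.character(exposure$zone_id)
  for (col in c("slr_m", "population", "affected_population")) {
    exposure[[col]] <- as.numeric(exposure[[col]])
  }
  if (any(exposure$population < 0) || any(exposure$affected_population < 0)) {
    stop_slrmig("exposure populations must be nonnegative")
  }
  bad <- exposure$affected_population > exposure$population + 1e-9
  if (any(bad)) {
    stop_slrmig("affected_population exceeds population for subzone(s): ",
                paste(unique(exposure$subzone_id[bad]), collapse = ", "))
  }
  if (!is.null(zones)) {
    unknown <- setdiff(unique(exposure$zone_id), zones$zone_id)
    if (length(unknown) > 0L) {
      stop_slrmig("exposure references unknown zone_id: ",
                  paste(unknown, collapse = ", "))
    }
  }
  if (check_nesting) {
    ord <- order(exposure$subzone_id, exposure$slr_m)
    e <- exposure[ord, ]
    same <- e$subzone_id[-1L] == e$subzone_id[-nrow(e)]
    if (nrow(e) > 1L) {
      drop <- diff(e$affected_population) < -1e-9 & same
      if (any(drop)) {
        stop_slrmig("affected_population decreases with slr_m for subzone(s): ",
                    paste(unique(e$subzone_id[-1L][drop]), collapse = ", "))
      }
    }
  }
  class(exposure) <- c("exposure_table", "data.frame")
  exposure
}

#' Partition zones into affected and unaffected portions
#'
#' The climate-impacts step: at a given sea-level-rise increment, every zone
#' is split into an affected portion (its population on flooded land, summed
#' over the zone's sub-zones) and an unaffected portion (the rest). Both
#' halves inherit the parent zone's centroid and county. Zones with no
#' exposure records keep their full population in the unaffected half; zones
#' whose habitable population reaches zero are flagged fully flooded and are
#' excluded from every destination set downstream.
#'
#' When exposure records exist for a zone at the requested increment, the
#' zone's population at that increment is the sum of its sub-zone populations
#' (projections are per increment); otherwise the zone table's population is
#' used. The two halves always sum to that parent population exactly.
#'
#' @param zones a [zone_set()].
#' @param exposure an [exposure_table()] (may be empty or `NULL` for a
#'   no-flooding partition).
#' @param slr_m the sea-level-rise increment in metres; 0 means no flooding.
#' @return A `data.frame` of class `zone_partition` with columns `zone_id`,
#'   `county_id`, `lat`, `lon`, `coastal`, `affected`, `unaffected`,
#'   `fully_flooded`, and attribute `slr_m`.
#' @examples
#' z <- zone_set("z1", lat = 30, lon = -90, population = 600, coastal = TRUE)
#' ex <- exposure_table(data.frame(
#'   subzone_id = c("s1", "s2", "s3"), zone_id = "z1", slr_m = 0.9,
#'   population = c(100, 200, 300), affected_population = c(50, 0, 300)))
#' partition_zones(z, ex, 0.9)  # affected 350, unaffected 250
#' @export
partition_zones <- function(zones, exposure = NULL, slr_m = 0) {
  zones <- validate_zone_set(as.data.frame(zones))
  part <- data.frame(zone_id = zones$zone_id, county_id = zones$county_id,
                     lat = zones$lat, lon = zones$lon, coastal = zones$coastal,
                     affected = 0, unaffected = zones$population,
                     stringsAsFactors = FALSE)
  if (!is.null(exposure) && nrow(exposure) > 0L && slr_m > 0) {
    exposure <- exposure_table(exposure, zones = zones)
    sub <- exposure[abs(exposure$slr_m - slr_m) < 1e-9, , drop = FALSE]
    if (nrow(sub) == 0L && any(exposure$slr_m > 0)) {
      stop_slrmig("slr_m = ", slr_m, " not present in the exposure table")
    }
    if (nrow(sub) > 0L) {
      pop <- tapply(sub$population, sub$zone_id, sum)
      aff <- tapply(sub$affected_population, sub$zone_id, sum)
      idx <- match(names(pop), part$zone_id)
      part$affected[idx] <- as.numeric(aff)
      part$unaffected[idx] <- as.numeric(pop) - as.numeric(aff)
    }
  }
  part$fully_flooded <- part$unaffected <= 1e-9
  structure(part, slr_m = slr_m, class = c("zone_partition", "data.frame"))
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf(
    "Zone partition at %.1f m SLR: %d zones, affected %.0f, unaffected %.0f, %d fully flooded\n",
    attr(x, "slr_m"), nrow(x), sum(x$affected), sum(x$unaffected),
    sum(x$fully_flooded)))
  invisible(x)
}

#' Total directly affected population
#'
#' The direct effect of an increment: the number of people living on land
#' flooded at that increment, i.e. the sum of the affected halves over all
#' zones in a partition.
#'
#' @param partitions a `zone_partition` from [partition_zones()].
#' @return total affected persons (numeric scalar).
#' @export
direct_effects <- function(partitions) {
  stopifnot(inherits(partitions, "zone_partition"))
  sum(partitions$affected)
}
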