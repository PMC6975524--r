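#' Incoming migrants per county
#'
#' Sums a flow table by destination county, excluding flows whose origin
#' county equals the destination county. Intra-county relocation (a flooded
#' portion moving into its own county's habitable portion) is excluded by
#' default: those people are existing residents, and counting them would
#' mark every flooded county as indirectly affected, collapsing the
#' direct/indirect distinction. Set `include_intra = TRUE` to count them.
#'
#' @param flows a `migration_flows` table (with `origin_county`,
#'   `dest_county` columns) or any flow table plus a `county_map` named
#'   vector from zone id to county id.
#' @param county_map optional named character vector `zone_id -> county_id`,
#'   required when `flows` lacks county columns.
#' @param counties character vector of all county ids the result must cover
#'   (zero-filled); defaults to the counties present in `flows`.
#' @param include_intra count same-county flows too (default FALSE).
#' @return named numeric vector of incoming persons per county.
#' @export
incoming_by_county <- function(flows, county_map = NULL, counties = NULL,
                               include_intra = FALSE) {
  flows <- as.data.frame(flows)
  if (!all(c("origin_county", "dest_county") %in% names(flows))) {
    if (is.null(county_map)) {
      stop_slrmig("flows lack county columns and no county_map was given")
    }
    unmapped <- setdiff(unique(c(flows$origin_id, flows$dest_id)),
                        names(county_map))
    if (length(unmapped) > 0L) {
      stop_slrmig("zone(s) not mapped to a county: ",
                  paste(unmapped, collapse = ", "))
    }
    flows$origin_county <- county_map[flows$origin_id]
    flows$dest_county <- county_map[flows$dest_id]
  }
  if (is.null(counties)) {
    counties <- sort(unique(c(flows$origin_county, flows$dest_county)))
  }
  inc <- stats::setNames(rep(0, length(counties)), counties)
  if (nrow(flows) > 0L) {
    keep <- if (include_intra) rep(TRUE, nrow(flows)) else
      flows$origin_county != flows$dest_county
    f <- flows[keep, , drop = FALSE]
    if (nrow(f) > 0L) {
      s <- rowsum(f$flow, f$dest_county)
      inc[rownames(s)] <- inc[rownames(s)] + s[, 1L]
    }
  }
  inc
}

#' Classify indirectly affected counties
#'
#' A county is indirectly affected at level `d` when its extra incoming
#' migrants under the scenario — incoming in the flooding scenario minus
#' incoming in the matched no-flooding baseline — exceed `d`% of the
#' county's population (strict inequality). Flag sets are nested: flagged at
#' a higher `d` implies flagged at every lower `d`.
#'
#' @param incoming_scenario,incoming_baseline named vectors of incoming
#'   persons per county (same county universe).
#' @param county_pops named vector of county populations for the step being
#'   classified.
#' @param d threshold in percent (scalar).
#' @return named logical vector of flags.
#' @export
classify_indirect <- function(incoming_scenario, incoming_baseline,
                              county_pops, d) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    stop_slrmig("d must be a single positive percentage")
  }
  counties <- names(incoming_scenario)
  if (!setequal(counties, names(incoming_baseline))) {
    stop_slrmig("scenario and baseline county universes differ")
  }
  missing <- setdiff(counties, names(county_pops))
  if (length(missing) > 0L) {
    stop_slrmig("no population for county(ies): ",
                paste(missing, collapse = ", "))
  }
  extra <- incoming_scenario - incoming_baseline[counties]
  stats::setNames(as.logical(extra > d / 100 * county_pops[counties]),
                  counties)
}

#' Direct- and indirect-effects report for a scenario run
#'
#' For every step of a fitted scenario, computes the directly affected
#' population (people on flooded land), per-county incoming migrants under
#' the scenario and the baseline, the extra migrants, and indirect-effect
#' flags at each threshold `d`. County population for the `d`% test is the
#' step's population (the sum of both partition halves per county).
#'
#' @param scenario an `slr_scenario` from [run_scenario()].
#' @param d percentage thresholds (default `c(0.5, 1, 3, 6, 9)`).
#' @param include_intra forward to [incoming_by_county()].
#' @return an object of class `effects_report`: list with `by_county` (one
#'   data.frame per step) and `summary` (one row per step: `year`, `slr_m`,
#'   `directly_affected`, and per threshold the flagged-county count
#'   `indirect_n_d<d>` and flagged-county population `indirect_pop_d<d>`).
#' @export
effects_report <- function(scenario, d = c(0.5, 1, 3, 6, 9),
                           include_intra = FALSE) {
  stopifnot(inherits(scenario, "slr_scenario"))
  if (any(d <= 0)) stop_slrmig("thresholds d must be positive percentages")
  d <- sort(unique(d))
  by_county <- vector("list", length(scenario$steps))
  summ <- vector("list", length(scenario$steps))
  for (k in seq_along(scenario$steps)) {
    s <- scenario$steps[[k]]
    part <- s$partitions
    cpop <- tapply(part$affected + part$unaffected, part$county_id, sum)
    counties <- sort(names(cpop))
    cpop <- cpop[counties]
    inc_s <- incoming_by_county(s$total, counties = counties,
                                include_intra = include_intra)
    inc_b <- incoming_by_county(s$baseline, counties = counties,
                                include_intra = include_intra)
    flags <- lapply(d, function(dd)
      classify_indirect(inc_s, inc_b, cpop, dd))
    df <- data.frame(county_id = counties, year = s$year, slr_m = s$slr_m,
                     population = as.numeric(cpop),
                     incoming_scenario = as.numeric(inc_s),
                     incoming_baseline = as.numeric(inc_b),
                     extra_migrants = as.numeric(inc_s - inc_b),
                     stringsAsFactors = FALSE, row.names = NULL)
    for (j in seq_along(d)) {
      df[[paste0("flag_d", d[j])]] <- as.logical(flags[[j]])
    }
    by_county[[k]] <- df
    row <- data.frame(year = s$year, slr_m = s$slr_m,
                      directly_affected = direct_effects(part))
    for (j in seq_along(d)) {
      row[[paste0("indirect_n_d", d[j])]] <- sum(flags[[j]])
      row[[paste0("indirect_pop_d", d[j])]] <- sum(cpop[flags[[j]]])
    }
    summ[[k]] <- row
  }
  structure(list(by_county = by_county, summary = do.call(rbind, summ),
                 d = d),
            class = "effects_report")
}

#' @export
print.effects_report <- function(x, ...) {
  cat("Direct and indirect effects by step:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
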