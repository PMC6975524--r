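#' Detect shock-affected origin counties in year-pair flow data
#'
#' Screens consecutive-year county-to-county flow tables for coastal
#' counties whose outgoing migration jumped: an origin is flagged when it is
#' coastal, its outgoing total rose by more than `min_increase` percent over
#' the previous year, and its current-year outgoing total exceeds
#' `min_outgoing` migrants. With the defaults (a >100% increase and >1,000
#' outgoing migrants) this isolates counties hit by hurricanes or other
#' displacement shocks while ignoring noisy small counties. Counties with no
#' previous-year outflow but positive current outflow are treated as an
#' infinite increase (flagged if the other criteria hold, with a warning).
#'
#' A manual exclusion list is supported for counties whose outflow jump has
#' a known non-climate explanation.
#'
#' @param flows_prev,flows_curr flow tables (`origin_id`, `dest_id`,
#'   `migrants`) for the earlier and later year.
#' @param coastal named logical vector `county_id -> coastal`.
#' @param min_increase minimum percent increase (default 100).
#' @param min_outgoing minimum current-year outgoing migrants (default 1000,
#'   applied to the shock year, where the elevated outflow lives).
#' @param exclude character vector of county ids to drop from the result
#'   regardless of the rule.
#' @return a data.frame of class `shock_detection` with one row per origin
#'   county: `county_id`, `outgoing_prev`, `outgoing_curr`, `pct_increase`,
#'   `coastal`, `flagged`.
#' @export
detect_shocked_origins <- function(flows_prev, flows_curr, coastal,
                                   min_increase = 100, min_outgoing = 1000,
                                   exclude = character(0)) {
  check_columns(flows_prev, c("origin_id", "migrants"), "previous flow table")
  check_columns(flows_curr, c("origin_id", "migrants"), "current flow table")
  if (nrow(flows_prev) == 0L || nrow(flows_curr) == 0L) {
    stop_slrmig("flow tables must be nonempty")
  }
  tot_prev <- tapply(flows_prev$migrants, flows_prev$origin_id, sum)
  tot_curr <- tapply(flows_curr$migrants, flows_curr$origin_id, sum)
  ids <- sort(union(names(tot_prev), names(tot_curr)))
  prev <- ifelse(is.na(tot_prev[ids]), 0, tot_prev[ids])
  curr <- ifelse(is.na(tot_curr[ids]), 0, tot_curr[ids])
  pct <- ifelse(prev > 0, 100 * (curr - prev) / prev,
                ifelse(curr > 0, Inf, 0))
  if (any(prev == 0 & curr > 0)) {
    warning("origin(s) with zero previous outflow treated as infinite ",
            "increase: ",
            paste(ids[prev == 0 & curr > 0], collapse = ", "), call. = FALSE)
  }
  is_coastal <- isTRUE_vec(coastal[ids])
  flagged <- is_coastal & pct > min_increase & curr > min_outgoing
  flagged[ids %in% exclude] <- FALSE
  structure(data.frame(county_id = ids, outgoing_prev = as.numeric(prev),
                       outgoing_curr = as.numeric(curr),
                       pct_increase = as.numeric(pct),
                       coastal = is_coastal, flagged = flagged,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("shock_detection", "data.frame"))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.shock_detection <- function(x, ...) {
  cat(sprintf("Shock detection over %d origin counties: %d flagged\n",
              nrow(x), sum(x$flagged)))
  if (any(x$flagged)) print(as.data.frame(x[x$flagged, ]), row.names = FALSE)
  invisible(x)
}

#' Split flows into climate-model and business-as-usual training sets
#'
#' Partitions a flow table by shock status of the endpoints: the climate
#' training set holds every pair with a shocked origin and an unshocked
#' destination (displacement out of the hit counties); the business-as-usual
#' set holds the remaining pairs with unshocked origins. Pairs whose
#' destination is shocked appear in neither set — flows into a
#' disaster-struck county carry neither signal cleanly.
#'
#' @param flows a flow table.
#' @param shocked character vector of shocked county ids.
#' @return list with `climate` and `bau` flow tables (disjoint pair sets).
#' @export
split_training_data <- function(flows, shocked) {
  check_columns(flows, c("origin_id", "dest_id", "migrants"), "flow table")
  universe <- unique(c(flows$origin_id, flows$dest_id))
  unknown <- setdiff(shocked, universe)
  if (length(unknown) > 0L) {
    stop_slrmig("shocked county(ies) absent from the flow table: ",
                paste(unknown, collapse = ", "))
  }
  if (length(shocked) == 0L) {
    warning("empty shocked set: climate training set is empty",
            call. = FALSE)
  }
  o_shocked <- flows$origin_id %in% shocked
  d_shocked <- flows$dest_id %in% shocked
  list(climate = flows[o_shocked & !d_shocked, , drop = FALSE],
       bau = flows[!o_shocked & !d_shocked, , drop = FALSE])
}
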