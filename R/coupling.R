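#' Climate-forced migration flows
#'
#' Routes the affected (flooded) half of every zone through the climate
#' migration model: `T'_ij = g_C(m_i^A) * P'_ij`, where destinations are the
#' habitable halves of all not-fully-flooded zones, *including* the origin
#' zone's own habitable half (people may relocate within their county). With
#' the default identity production every origin's row of `T'` sums to its
#' entire affected population.
#'
#' @param partitions a `zone_partition` from [partition_zones()].
#' @param model a `migration_model` for climate-driven destination choice.
#' @param g production function for climate migrants; default identity
#'   (`production_function(1)`).
#' @param dist optional distance matrix override.
#' @param intra_km intra-zone distance for the own-zone pair, km.
#' @return a flow table (`origin_id`, `dest_id`, `origin_county`,
#'   `dest_county`, `flow`) of class `migration_flows`, attribute
#'   `component = "climate"`. Empty (zero-row) if nothing is flooded.
#' @export
climate_flows <- function(partitions, model, g = production_function(1),
                          dist = NULL, intra_km = 1) {
  stopifnot(inherits(partitions, "zone_partition"),
            inherits(model, "migration_model"))
  origins <- partitions[partitions$affected > 0, , drop = FALSE]
  if (nrow(origins) == 0L) {
    return(empty_flows("climate"))
  }
  dests <- partitions[!partitions$fully_flooded, , drop = FALSE]
  if (nrow(dests) == 0L) {
    stop_slrmig("no habitable destinations remain for climate migrants")
  }
  o <- data.frame(zone_id = origins$zone_id, county_id = origins$county_id,
                  population = origins$affected, lat = origins$lat,
                  lon = origins$lon, stringsAsFactors = FALSE)
  d <- data.frame(zone_id = dests$zone_id, county_id = dests$county_id,
                  population = dests$unaffected, lat = dests$lat,
                  lon = dests$lon, stringsAsFactors = FALSE)
  feats <- build_feature_table(o, d, universe = d, dist = dist,
                               self_pairs = "intra", intra_km = intra_km)
  p <- predict(model, feats)
  flows_from(feats, p * g(feats$m_i), "climate")
}

#' Business-as-usual migration flows
#'
#' Routes the habitable half of every zone through the baseline migration
#' model: `T''_ij = g_S(m_i^U) * P''_ij`. Origins and destinations are both
#' unaffected halves; same-zone pairs are excluded (staying put is not a
#' migration). Every origin's row sums to `rate * m_i^U` (default 3%).
#'
#' @inheritParams climate_flows
#' @param g production function; default `production_function(0.03)`.
#' @return a `migration_flows` table, attribute `component = "bau"`.
#' @export
bau_flows <- function(partitions, model, g = production_function(0.03),
                      dist = NULL) {
  stopifnot(inherits(partitions, "zone_partition"),
            inherits(model, "migration_model"))
  alive <- partitions[!partitions$fully_flooded, , drop = FALSE]
  if (nrow(alive) < 2L) {
    if (nrow(alive) == 0L) stop_slrmig("no habitable zones remain")
    return(empty_flows("bau"))
  }
  if (attr(g, "rate") == 0) {
    return(empty_flows("bau"))
  }
  z <- data.frame(zone_id = alive$zone_id, county_id = alive$county_id,
                  population = alive$unaffected, lat = alive$lat,
                  lon = alive$lon, stringsAsFactors = FALSE)
  feats <- build_feature_table(z, z, universe = z, dist = dist,
                               self_pairs = "exclude")
  p <- predict(model, feats)
  flows_from(feats, p * g(feats$m_i), "bau")
}

flows_from <- function(feats, flow, component) {
  out <- data.frame(origin_id = feats$origin_id, dest_id = feats$dest_id,
                    origin_county = feats$origin_county,
                    dest_county = feats$dest_county,
                    flow = flow, stringsAsFactors = FALSE)
  out <- out[out$flow > 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, component = component,
            class = c("migration_flows", "data.frame"))
}

empty_flows <- function(component) {
  structure(data.frame(origin_id = character(0), dest_id = character(0),
                       origin_county = character(0),
                       dest_county = character(0), flow = numeric(0),
                       stringsAsFactors = FALSE),
            component = component,
            class = c("migration_flows", "data.frame"))
}

#' Aggregate climate and business-as-usual flows
#'
#' Entrywise sum `T = T' + T''` in sparse long form, with a `component`
#' column retained so the parts stay recoverable.
#'
#' @param climate,bau `migration_flows` tables.
#' @return a `migration_flows` table with a `component` column.
#' @export
aggregate_flows <- function(climate, bau) {
  parts <- list(climate, bau)
  labs <- c("climate", "bau")
  for (k in 1:2) {
    if (nrow(parts[[k]]) > 0L) parts[[k]]$component <- labs[k]
  }
  keep <- vapply(parts, nrow, integer(1)) > 0L
  if (!any(keep)) {
    out <- empty_flows("total")
    out$component <- character(0)
    return(out)
  }
  out <- do.call(rbind, lapply(parts[keep], as.data.frame))
  rownames(out) <- NULL
  structure(out, component = "total",
            class = c("migration_flows", "data.frame"))
}

#' Roll flows up to county level
#'
#' Collapses the affected/unaffected halves of each county back onto the
#' county id and sums flows over duplicate (origin county, destination
#' county) pairs.
#'
#' @param flows a `migration_flows` table.
#' @return data.frame `origin_id`, `dest_id`, `flow` at county granularity.
#' @export
county_rollup <- function(flows) {
  if (nrow(flows) == 0L) {
    return(data.frame(origin_id = character(0), dest_id = character(0),
                      flow = numeric(0), stringsAsFactors = FALSE))
  }
  key <- paste(flows$origin_county, flows$dest_county, sep = "\r")
  s <- rowsum(flows$flow, key)
  parts <- strsplit(rownames(s), "\r", fixed = TRUE)
  data.frame(origin_id = vapply(parts, `[`, "", 1L),
             dest_id = vapply(parts, `[`, "", 2L),
             flow = s[, 1L], row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a multi-step sea-level-rise migration scenario
#'
#' Iterates a scenario timeline: at each scheduled year the zones are
#' partitioned at that year's increment, climate flows `T'` and
#' business-as-usual flows `T''` are computed and aggregated into `T`, and a
#' matched baseline (every zone unaffected, business-as-usual flows only) is
#' run on the same populations. The baseline never sees the exposure table,
#' so with zero exposure the scenario reproduces it exactly.
#'
#' Two population modes: `"exogenous"` (default) re-reads populations and
#' per-increment exposure from the inputs at every step, matching
#' per-increment snapshot reporting; `"compounded"` carries populations
#' forward by net migration, displacing at each step only the population
#' newly flooded since the previous increment (nobody is displaced twice).
#' Total population is conserved in compounded mode: migration relocates
#' people, never creates them.
#'
#' The ablation switch `model_mode = "single"` uses the business-as-usual
#' model for both flow components, quantifying what separating the climate
#' and baseline destination-choice models contributes.
#'
#' @param zones a [zone_set()].
#' @param exposure an [exposure_table()] (or `NULL` for no flooding).
#' @param timeline an [slr_timeline()].
#' @param model_C,model_S climate and business-as-usual migration models.
#' @param rate_C,rate_S production rates (defaults 1 and 0.03).
#' @param mode `"exogenous"` or `"compounded"`.
#' @param model_mode `"dual"` or `"single"`.
#' @param dist optional distance matrix override.
#' @param intra_km intra-zone distance, km.
#' @return an object of class `slr_scenario`: a list with `steps` (one entry
#'   per scheduled year holding `year`, `slr_m`, `partitions`, `climate`,
#'   `bau`, `total`, `baseline`), plus the run settings.
#' @export
run_scenario <- function(zones, exposure, timeline, model_C, model_S,
                         rate_C = 1, rate_S = 0.03,
                         mode = c("exogenous", "compounded"),
                         model_mode = c("dual", "single"),
                         dist = NULL, intra_km = 1) {
  mode <- match.arg(mode)
  model_mode <- match.arg(model_mode)
  stopifnot(inherits(timeline, "slr_timeline"))
  zones <- validate_zone_set(as.data.frame(zones))
  if (!is.null(exposure) && nrow(exposure) > 0L) {
    exposure <- exposure_table(exposure, zones = zones)
  }
  sched <- timeline$schedule
  if (nrow(sched) == 0L) stop_slrmig("timeline is empty")
  g_C <- production_function(rate_C)
  g_S <- production_function(rate_S)
  mC <- if (model_mode == "single") model_S else model_C

  cur_zones <- zones        # evolving populations (compounded mode)
  base_zones <- zones       # baseline populations evolve separately
  prev_affected <- stats::setNames(rep(0, nrow(zones)), zones$zone_id)
  steps <- vector("list", nrow(sched))

  for (k in seq_len(nrow(sched))) {
    slr <- sched$slr_m[k]
    yr <- sched$year[k]
    if (mode == "exogenous") {
      part <- partition_zones(zones, exposure, slr)
    } else {
      full <- partition_zones(zones, exposure, slr)
      newly <- pmax(full$affected[match(cur_zones$zone_id, full$zone_id)] -
                      prev_affected[cur_zones$zone_id], 0)
      newly <- pmin(newly, cur_zones$population)
      part <- partition_zones(cur_zones, NULL, 0)
      part$affected <- newly
      part$unaffected <- cur_zones$population - newly
      part$fully_flooded <- part$unaffected <= 1e-9
      attr(part, "slr_m") <- slr
      prev_affected[cur_zones$zone_id] <-
        pmax(prev_affected[cur_zones$zone_id],
             full$affected[match(cur_zones$zone_id, full$zone_id)])
    }
    tc <- climate_flows(part, mC, production_function(rate_C), dist = dist,
                        intra_km = intra_km)
    tb <- bau_flows(part, model_S, production_function(rate_S), dist = dist)
    tot <- aggregate_flows(tc, tb)

    bpart <- partition_zones(base_zones, NULL, 0)
    bflow <- bau_flows(bpart, model_S, production_function(rate_S),
                       dist = dist)

    steps[[k]] <- list(year = yr, slr_m = slr, partitions = part,
                       climate = tc, bau = tb, total = tot,
                       baseline = bflow)

    if (mode == "compounded") {
      cur_zones$population <- settle_populations(part, tot)
      base_zones$population <- settle_baseline(bpart, bflow)
    }
  }

  structure(list(steps = steps, zones = zones, timeline = timeline,
                 mode = mode, model_mode = model_mode,
                 rate_C = rate_C, rate_S = rate_S),
            class = "slr_scenario")
}

# After a compounded step, a zone's next population is its habitable
# population minus out-migrants plus in-migrants (climate arrivals join the
# habitable pool); the affected half has left entirely via the climate flows.
settle_populations <- function(part, flows) {
  pop <- stats::setNames(part$unaffected, part$zone_id)
  if (nrow(flows) > 0L) {
    # climate out-migrants came from the affected half, which is already
    # outside `unaffected`; only bau out-migrants leave the habitable pool
    bau <- flows$component == "bau"
    out_b <- rowsum(flows$flow[bau], flows$origin_id[bau])
    inc <- rowsum(flows$flow, flows$dest_id)
    if (length(out_b)) pop[rownames(out_b)] <- pop[rownames(out_b)] - out_b[, 1L]
    if (length(inc)) pop[rownames(inc)] <- pop[rownames(inc)] + inc[, 1L]
  }
  pmax(as.numeric(pop), 0)
}

settle_baseline <- function(part, flows) {
  pop <- stats::setNames(part$unaffected, part$zone_id)
  if (nrow(flows) > 0L) {
    outg <- rowsum(flows$flow, flows$origin_id)
    inc <- rowsum(flows$flow, flows$dest_id)
    pop[rownames(outg)] <- pop[rownames(outg)] - outg[, 1L]
    pop[rownames(inc)] <- pop[rownames(inc)] + inc[, 1L]
  }
  pmax(as.numeric(pop), 0)
}

#' @export
print.slr_scenario <- function(x, ...) {
  cat(sprintf(
    "SLR migration scenario '%s' (%s populations, %s-model): %d steps\n",
    x$timeline$name, x$mode, x$model_mode, length(x$steps)))
  for (s in x$steps) {
    cat(sprintf(
      "  %d @ %.1f m: displaced %.0f, climate flow %.0f, bau flow %.0f\n",
      s$year, s$slr_m, direct_effects(s$partitions), sum(s$climate$flow),
      sum(s$bau$flow)))
  }
  invisible(x)
}

#' @export
summary.slr_scenario <- function(object, d = c(0.5, 1, 3, 6, 9), ...) {
  effects_report(object, d = d)
}

#' @export
plot.slr_scenario <- function(x, d = c(0.5, 1, 3, 6, 9), ...) {
  rep_ <- effects_report(x, d = d)
  s <- rep_$summary
  graphics::matplot(s$slr_m, cbind(s$directly_affected,
                                   s[paste0("indirect_pop_d", d)]),
                    type = "b", pch = 19, lty = 1,
                    xlab = "sea-level rise (m)", ylab = "persons affected",
                    ...)
  graphics::legend("topleft", bty = "n",
                   legend = c("direct", paste0("indirect d=", d, "%")),
                   col = seq_len(length(d) + 1), lty = 1, pch = 19)
  invisible(rep_)
}
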