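#' Generate a seeded synthetic coastal region
#'
#' Builds a self-contained study region with the statistical structure the
#' simulator assumes: zones scattered over a bounded lat/lon box with the
#' coastline along the western edge, log-normal populations, and a flooding
#' exposure profile in which coastal zones lose a population fraction that
#' grows with the sea-level-rise increment and decays with distance from the
#' coast. Each zone is divided into sub-zones (block-group analogues) with
#' heterogeneous vulnerability, so exposure arrives in the same per-sub-zone
#' long form as real data. Inland zones get no exposure records; per
#' sub-zone affected populations are nested (nondecreasing) across
#' increments by construction. Identical seeds give identical tables.
#'
#' The defaults — 200 zones, 30% coastal, log-normal(9, 1) populations —
#' are the reference fixture used throughout the package's tests.
#'
#' @param n_zones number of zones (counties); each zone is its own county.
#' @param seed integer seed.
#' @param frac_coastal fraction of zones designated coastal (the westernmost).
#' @param pop_meanlog,pop_sdlog log-normal population parameters.
#' @param n_subzones sub-zones per zone.
#' @param increments sea-level-rise increments (m) to emit exposure at.
#' @param max_flood_frac population fraction of a shoreline zone flooded at
#'   the highest increment.
#' @param coast_decay_km e-folding distance of flooding inland, km.
#' @param bbox region bounds `c(lat_min, lat_max, lon_min, lon_max)`.
#' @return list with `zones` (a [zone_set()]) and `exposure`
#'   (an [exposure_table()]).
#' @export
synthetic_region <- function(n_zones = 200, seed = 1, frac_coastal = 0.3,
                             pop_meanlog = 9, pop_sdlog = 1, n_subzones = 4,
                             increments = seq(0.3, 1.8, by = 0.3),
                             max_flood_frac = 0.9, coast_decay_km = 60,
                             bbox = c(28, 33, -90, -84)) {
  if (n_zones < 3) stop_slrmig("need at least 3 zones")
  if (pop_sdlog <= 0 || frac_coastal < 0 || frac_coastal > 1 ||
      max_flood_frac <= 0 || max_flood_frac > 1) {
    stop_slrmig("invalid synthetic region parameters")
  }
  with_seed(seed, {
    lat <- stats::runif(n_zones, bbox[1], bbox[2])
    lon <- stats::runif(n_zones, bbox[3], bbox[4])
    pop <- stats::rlnorm(n_zones, pop_meanlog, pop_sdlog)
    ids <- sprintf("z%03d", seq_len(n_zones))
    n_coastal <- round(frac_coastal * n_zones)
    coastal <- rank(lon, ties.method = "first") <= n_coastal
    zones <- zone_set(ids, lat = lat, lon = lon, population = pop,
                      coastal = coastal)
    # distance from the western coastline, km (1 deg lon ~ cos(lat)*111 km)
    coast_km <- (lon - bbox[3]) * 111.32 * cos(lat * pi / 180)

    rows <- list()
    for (i in which(coastal)) {
      shares <- stats::rgamma(n_subzones, 2)
      shares <- shares / sum(shares)
      vuln <- stats::runif(n_subzones, 0.5, 1.5)
      subpop <- pop[i] * shares
      for (x in increments) {
        frac <- max_flood_frac * (x / max(increments)) *
          exp(-coast_km[i] / coast_decay_km)
        rows[[length(rows) + 1L]] <- data.frame(
          subzone_id = sprintf("%s_s%d", ids[i], seq_len(n_subzones)),
          zone_id = ids[i], slr_m = x, population = subpop,
          affected_population = subpop * pmin(1, frac * vuln),
          stringsAsFactors = FALSE)
      }
    }
    exposure <- exposure_table(do.call(rbind, rows), zones = zones)
    list(zones = zones, exposure = exposure)
  })
}

#' Sample a synthetic flow table from a migration model
#'
#' Draws, for each origin, a multinomial sample of size
#' `round(rate * m_i)` over the model's destination-choice row, emulating an
#' annual county-to-county migration table generated by a known process.
#'
#' @param features feature table from [build_feature_table()].
#' @param model the generating `migration_model`.
#' @param rate production rate (fraction of each origin's population that
#'   migrates; default 0.03).
#' @param year year label for the table.
#' @param seed integer seed.
#' @return a flow table (`origin_id`, `dest_id`, `migrants`, `year`), zero
#'   flows dropped.
#' @export
generate_flows <- function(features, model, rate = 0.03, year = 2005,
                           seed = 1) {
  if (rate < 0) stop_slrmig("rate must be nonnegative")
  p <- predict(model, features)
  with_seed(seed, {
    out <- lapply(split(seq_len(nrow(features)), features$origin_id),
                  function(idx) {
      m_i <- features$m_i[idx[1L]]
      size <- round_persons(rate * m_i)
      if (size <= 0) return(NULL)
      counts <- as.numeric(stats::rmultinom(1, size, p[idx]))
      data.frame(origin_id = features$origin_id[idx],
                 dest_id = features$dest_id[idx],
                 migrants = counts, year = year, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) {
      return(data.frame(origin_id = character(0), dest_id = character(0),
                        migrants = numeric(0), year = numeric(0),
                        stringsAsFactors = FALSE))
    }
    out <- out[out$migrants > 0, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate flows from a migration model
#'
#' [simulate()] method for migration models: a thin wrapper over
#' [generate_flows()] returning a list of `nsim` flow tables.
#'
#' @param object a `migration_model`.
#' @param nsim number of tables to draw.
#' @param seed integer seed; table `k` uses `seed + k - 1`.
#' @param features,rate,year forwarded to [generate_flows()].
#' @param ... unused.
#' @export
simulate.migration_model <- function(object, nsim = 1, seed = 1,
                                     features, rate = 0.03, year = 2005,
                                     ...) {
  lapply(seq_len(nsim), function(k)
    generate_flows(features, object, rate = rate, year = year,
                   seed = seed + k - 1))
}

#' Inject a displacement shock into a flow table
#'
#' Emulates the signal a hurricane leaves in migration data: the outgoing
#' totals of the listed counties are scaled by `multiplier`, and the
#' enlarged outflow is redistributed over destinations by a distance-tilted
#' row (destination population times an exponential decay in distance),
#' mimicking forced displacement to nearby habitable zones. Other counties'
#' rows are untouched.
#'
#' @param flows a flow table (`origin_id`, `dest_id`, `migrants`, `year`).
#' @param zones the [zone_set()] the flows live on (for populations and
#'   distances).
#' @param counties county ids to shock.
#' @param multiplier outflow scaling factor, strictly greater than 1.
#' @param seed integer seed for the redistribution draw.
#' @param lambda decay length of the displacement kernel, km.
#' @return the shocked flow table.
#' @export
inject_shock <- function(flows, zones, counties, multiplier, seed = 1,
                         lambda = 200) {
  if (!is.numeric(multiplier) || multiplier <= 1) {
    stop_slrmig("multiplier must be strictly greater than 1")
  }
  unknown <- setdiff(counties, zones$zone_id)
  if (length(unknown) > 0L) {
    stop_slrmig("unknown county(ies): ", paste(unknown, collapse = ", "))
  }
  dist <- zone_distance_matrix(zones)
  kernel <- distance_decay_model(lambda)
  with_seed(seed, {
    for (cty in counties) {
      old <- flows$origin_id == cty
      n_new <- round_persons(multiplier * sum(flows$migrants[old]))
      dests <- zones[zones$zone_id != cty, , drop = FALSE]
      feats <- data.frame(origin_id = cty, dest_id = dests$zone_id,
                          m_i = zones$population[zones$zone_id == cty],
                          m_j = dests$population,
                          d_km = dist[cty, dests$zone_id], s_ij = 0,
                          stringsAsFactors = FALSE)
      p <- predict(kernel, feats)
      counts <- as.numeric(stats::rmultinom(1, n_new, p))
      yr <- if (any(old)) flows$year[old][1L] else flows$year[1L]
      repl <- data.frame(origin_id = cty, dest_id = dests$zone_id,
                         migrants = counts, year = yr,
                         stringsAsFactors = FALSE)
      flows <- rbind(flows[!old, , drop = FALSE],
                     repl[repl$migrants > 0, , drop = FALSE])
    }
    rownames(flows) <- NULL
    flows
  })
}
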