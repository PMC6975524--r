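#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km between points given as
#' (latitude, longitude) in decimal degrees. Vectorised over both arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 180)  # half circumference, ~20015 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop_slrmig("coordinates out of range")
  }
  r <- 6371.0
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Pairwise zone distance matrix
#'
#' Great-circle distances between all zone centroids, in kilometres, as a
#' dense symmetric matrix with zone ids on both dimnames. A precomputed
#' matrix (e.g. planar distances for toy geometries, or road distances) can
#' be passed anywhere a distance matrix is accepted, overriding the centroid
#' haversine.
#'
#' @param zones a [zone_set()] or any data.frame with `zone_id`, `lat`, `lon`.
#' @return an n x n numeric matrix.
#' @export
zone_distance_matrix <- function(zones) {
  n <- nrow(zones)
  d <- matrix(0, n, n, dimnames = list(zones$zone_id, zones$zone_id))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      d[i, j] <- haversine_km(zones$lat[i], zones$lon[i],
                              zones$lat[j], zones$lon[j])
      d[j, i] <- d[i, j]
    }
  }
  d
}

#' Intervening opportunities between an origin and a destination
#'
#' The population living strictly closer to the origin than the destination,
#' excluding both endpoints: the opportunity mass a migrant passes over on
#' the way from `origin_id` to `dest_id`. Third zones exactly on the circle
#' boundary (tied distance) are excluded. Opportunity populations are the
#' habitable (unaffected) populations supplied in `populations`; flooded
#' portions do not count as opportunities.
#'
#' @param zone_ids character vector of zone ids (the opportunity universe).
#' @param populations habitable population of each zone in `zone_ids`.
#' @param dist distance matrix over `zone_ids` (dimnames must match), e.g.
#'   from [zone_distance_matrix()].
#' @param origin_id,dest_id distinct zone ids present in `zone_ids`.
#' @return persons (numeric scalar).
#' @export
intervening_opportunities <- function(zone_ids, populations, dist,
                                      origin_id, dest_id) {
  if (origin_id == dest_id) {
    stop_slrmig("origin and destination must be distinct zones")
  }
  i <- match(origin_id, zone_ids)
  j <- match(dest_id, zone_ids)
  if (is.na(i) || is.na(j)) stop_slrmig("unknown zone id")
  d_i <- dist[i, ]
  inside <- d_i < d_i[j]
  inside[c(i, j)] <- FALSE
  sum(populations[inside])
}

#' Build the migration feature table for origin-destination pairs
#'
#' One row per ordered (origin, allowed destination) pair with the four
#' spatial-interaction features: origin population `m_i`, destination
#' population `m_j`, great-circle distance `d_km`, and intervening
#' opportunities `s_ij`. Origins and destinations are zone *portions*
#' (affected or unaffected halves): populations are taken from whichever half
#' the model being served needs, while distances are always between parent
#' zone centroids.
#'
#' Pairing rules: `self_pairs = "exclude"` drops same-zone pairs (the
#' business-as-usual case); `self_pairs = "intra"` keeps them as intra-zone
#' moves (a flooded portion relocating into its own zone's habitable
#' portion) with distance `intra_km` and `s_ij = 0`. The intra-zone distance
#' is strictly positive so distance-decay models stay finite.
#'
#' @param origins data.frame with `zone_id`, `county_id`, `population` (the
#'   half being routed), `lat`, `lon`.
#' @param dests data.frame with the same columns (habitable halves only).
#' @param universe data.frame `zone_id`, `population`, `lat`, `lon` defining
#'   the opportunity mass for `s_ij`; defaults to `dests`.
#' @param dist optional precomputed distance matrix whose dimnames cover all
#'   parent zone ids involved; defaults to centroid haversine.
#' @param self_pairs `"exclude"` or `"intra"`.
#' @param intra_km intra-zone distance in kilometres (default 1).
#' @return data.frame with columns `origin_id`, `dest_id`, `origin_county`,
#'   `dest_county`, `m_i`, `m_j`, `d_km`, `s_ij`.
#' @export
build_feature_table <- function(origins, dests, universe = dests, dist = NULL,
                                self_pairs = c("exclude", "intra"),
                                intra_km = 1) {
  self_pairs <- match.arg(self_pairs)
  if (nrow(dests) == 0L) {
    stop_slrmig("destination universe is empty (all zones fully flooded?)")
  }
  if (intra_km <= 0) stop_slrmig("intra_km must be strictly positive")
  all_ids <- unique(c(origins$zone_id, dests$zone_id, universe$zone_id))
  if (is.null(dist)) {
    cent <- rbind(origins[c("zone_id", "lat", "lon")],
                  dests[c("zone_id", "lat", "lon")],
                  universe[c("zone_id", "lat", "lon")])
    cent <- cent[!duplicated(cent$zone_id), ]
    dist <- zone_distance_matrix(cent)
  } else {
    missing <- setdiff(all_ids, rownames(dist))
    if (length(missing) > 0L) {
      stop_slrmig("distance matrix lacks zone(s): ",
                  paste(missing, collapse = ", "))
    }
  }
  u_pop <- numeric(length(all_ids))
  names(u_pop) <- all_ids
  u_pop[universe$zone_id] <- universe$population

  n_o <- nrow(origins)
  n_d <- nrow(dests)
  out <- vector("list", n_o)
  for (oi in seq_len(n_o)) {
    o_id <- origins$zone_id[oi]
    keep <- if (self_pairs == "exclude") dests$zone_id != o_id else
      rep(TRUE, n_d)
    d_ids <- dests$zone_id[keep]
    if (length(d_ids) == 0L) next
    d_row <- dist[o_id, all_ids]
    d_ij <- dist[o_id, d_ids]
    intra <- d_ids == o_id
    d_ij[intra] <- intra_km
    # s_ij: habitable population strictly inside the circle of radius d_ij,
    # excluding origin and destination parent zones. The origin parent is
    # always at distance 0, so subtract it back out.
    s_ij <- vapply(seq_along(d_ids), function(k) {
      if (intra[k]) return(0)
      inside <- d_row < d_ij[k]
      sum(u_pop[inside]) - (if (d_row[o_id] < d_ij[k]) u_pop[o_id] else 0) -
        (if (d_row[d_ids[k]] < d_ij[k]) u_pop[d_ids[k]] else 0)
    }, numeric(1))
    out[[oi]] <- data.frame(
      origin_id = o_id, dest_id = d_ids,
      origin_county = origins$county_id[oi],
      dest_county = dests$county_id[keep],
      m_i = origins$population[oi], m_j = dests$population[keep],
      d_km = as.numeric(d_ij), s_ij = pmax(0, s_ij),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) {
    stop_slrmig("no origin-destination pairs to build features for")
  }
  rownames(res) <- NULL
  res
}
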