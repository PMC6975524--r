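# Shared fixtures, built in code.

# Three zones on a line at 0, 100 and 200 km with planar distances supplied
# explicitly (populations A = 100, B = 50, C = 50).
line_toy <- function() {
  zones <- zone_set(c("A", "B", "C"), lat = 0, lon = c(0, 1, 2),
                    population = c(100, 50, 50))
  dist <- matrix(c(0, 100, 200,
                   100, 0, 100,
                   200, 100, 0), 3, 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  list(zones = zones, dist = dist)
}

# Two counties of 1000 people each; county c1 has 200 people flooded at
# 0.3 m, county c2 is untouched. The climate destination-choice row from
# c1's flooded half is stipulated: 0.7 to its own habitable half, 0.3 to c2.
two_county_toy <- function() {
  zones <- zone_set(c("c1", "c2"), lat = c(30, 30.5), lon = c(-90, -89.5),
                    population = c(1000, 1000), coastal = c(TRUE, FALSE))
  exposure <- exposure_table(data.frame(
    subzone_id = "c1_s1", zone_id = "c1", slr_m = 0.3,
    population = 1000, affected_population = 200))
  model_C <- table_model(data.frame(origin_id = "c1",
                                    dest_id = c("c1", "c2"),
                                    p = c(0.7, 0.3)))
  list(zones = zones, exposure = exposure, model_C = model_C,
       model_S = radiation_model())
}

# Business-as-usual feature table over a zone set (no flooding).
bau_features <- function(zones) {
  z <- data.frame(zone_id = zones$zone_id, county_id = zones$county_id,
                  population = zones$population, lat = zones$lat,
                  lon = zones$lon, stringsAsFactors = FALSE)
  build_feature_table(z, z, universe = z, self_pairs = "exclude")
}

# Random feature rows grouped into origins, for probability-contract checks.
random_feature_rows <- function(n_rows, seed) {
  withr::with_seed(seed, {
    n_origin <- max(2L, n_rows %/% 10L)
    data.frame(
      origin_id = sample(sprintf("o%d", seq_len(n_origin)), n_rows,
                         replace = TRUE),
      dest_id = sprintf("d%d", seq_len(n_rows)),
      m_i = stats::rlnorm(n_rows, 9, 1.5),
      m_j = stats::rlnorm(n_rows, 9, 1.5),
      d_km = stats::runif(n_rows, 1, 3000),
      s_ij = stats::rlnorm(n_rows, 10, 2),
      stringsAsFactors = FALSE)
  })
}
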