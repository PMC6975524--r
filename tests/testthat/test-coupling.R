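test_that("climate flows route the whole affected population by the stipulated row", {
  toy <- two_county_toy()
  part <- partition_zones(toy$zones, toy$exposure, 0.3)
  tc <- climate_flows(part, toy$model_C)
  expect_equal(nrow(tc), 2)
  expect_equal(tc$flow[tc$origin_id == "c1" & tc$dest_id == "c1"], 140)
  expect_equal(tc$flow[tc$origin_id == "c1" & tc$dest_id == "c2"], 60)
  expect_equal(sum(tc$flow), 200)  # identity production conserves theta^A
  # an unflooded county contributes no climate rows
  expect_false("c2" %in% tc$origin_id)
})

test_that("business-as-usual flows move 3% of each habitable half", {
  toy <- two_county_toy()
  part <- partition_zones(toy$zones, toy$exposure, 0.3)
  tb <- bau_flows(part, toy$model_S)
  expect_equal(tb$flow[tb$origin_id == "c1"], 24)   # 0.03 * 800
  expect_equal(tb$flow[tb$origin_id == "c2"], 30)   # 0.03 * 1000
  expect_false(any(tb$origin_id == tb$dest_id))
  # zero production rate gives an empty matrix
  expect_equal(nrow(bau_flows(part, toy$model_S, production_function(0))), 0)
})

test_that("aggregation is the entrywise sum with recoverable components", {
  toy <- two_county_toy()
  part <- partition_zones(toy$zones, toy$exposure, 0.3)
  tc <- climate_flows(part, toy$model_C)
  tb <- bau_flows(part, toy$model_S)
  tot <- aggregate_flows(tc, tb)
  expect_equal(sum(tot$flow), 200 + 24 + 30)
  expect_setequal(unique(tot$component), c("climate", "bau"))
  # bau = 0 leaves T = T'
  t_only <- aggregate_flows(tc, bau_flows(part, toy$model_S,
                                          production_function(0)))
  expect_equal(sum(t_only$flow), sum(tc$flow))
  empty <- aggregate_flows(slrmig:::empty_flows("climate"),
                           slrmig:::empty_flows("bau"))
  expect_equal(nrow(empty), 0)
})

test_that("zero exposure reproduces the baseline exactly at every step", {
  reg <- synthetic_region(n_zones = 30, seed = 51)
  sc <- run_scenario(reg$zones, NULL, slr_timeline("medium"),
                     model_C = distance_decay_model(150),
                     model_S = radiation_model())
  for (s in sc$steps) {
    expect_equal(nrow(s$climate), 0)
    key_t <- paste(s$total$origin_id, s$total$dest_id)
    key_b <- paste(s$baseline$origin_id, s$baseline$dest_id)
    expect_setequal(key_t, key_b)
    expect_equal(s$total$flow[match(key_b, key_t)], s$baseline$flow)
  }
})

test_that("production is conserved per origin in both components", {
  reg <- synthetic_region(n_zones = 40, seed = 52)
  sc <- run_scenario(reg$zones, reg$exposure, slr_timeline("medium"),
                     model_C = distance_decay_model(150),
                     model_S = extended_radiation_model(0.5))
  for (s in sc$steps) {
    part <- s$partitions
    out_c <- tapply(s$climate$flow, s$climate$origin_id, sum)
    expected_c <- part$affected[match(names(out_c), part$zone_id)]
    expect_equal(as.numeric(out_c), expected_c, tolerance = 1e-9)
    out_b <- tapply(s$bau$flow, s$bau$origin_id, sum)
    expected_b <- 0.03 * part$unaffected[match(names(out_b), part$zone_id)]
    expect_equal(as.numeric(out_b), expected_b, tolerance = 1e-9)
  }
})

test_that("no flow ever targets a fully-flooded zone", {
  z <- zone_set(c("gone", "safe1", "safe2"), lat = c(29, 30, 31),
                lon = c(-90, -89, -88), population = c(400, 1000, 1000),
                coastal = c(TRUE, FALSE, FALSE))
  ex <- exposure_table(data.frame(
    subzone_id = "g_s1", zone_id = "gone", slr_m = c(0.3, 0.6, 0.9),
    population = 400, affected_population = 400))
  sc <- run_scenario(z, ex, slr_timeline("medium"),
                     model_C = radiation_model(),
                     model_S = radiation_model())
  for (s in sc$steps) {
    expect_false("gone" %in% s$total$dest_id)
    # ... but it still sends its displaced population out
    expect_equal(sum(s$climate$flow[s$climate$origin_id == "gone"]), 400)
  }
})

test_that("baseline flows are independent of the exposure table", {
  reg <- synthetic_region(n_zones = 30, seed = 53)
  tl <- slr_timeline("medium")
  sc1 <- run_scenario(reg$zones, reg$exposure, tl, radiation_model(),
                      radiation_model())
  sc2 <- run_scenario(reg$zones, NULL, tl, radiation_model(),
                      radiation_model())
  for (k in seq_along(sc1$steps)) {
    expect_equal(sc1$steps[[k]]$baseline, sc2$steps[[k]]$baseline)
  }
})

test_that("compounded mode conserves total population and balances flows", {
  reg <- synthetic_region(n_zones = 40, seed = 54)
  total0 <- sum(reg$zones$population)
  sc <- run_scenario(reg$zones, reg$exposure, slr_timeline("high"),
                     model_C = distance_decay_model(150),
                     model_S = extended_radiation_model(0.5),
                     mode = "compounded")
  for (s in sc$steps) {
    part <- s$partitions
    expect_equal(sum(part$affected) + sum(part$unaffected), total0,
                 tolerance = 1e-6)
    inc <- sum(s$total$flow)
    outg <- sum(tapply(s$total$flow, s$total$origin_id, sum))
    expect_equal(inc, outg)
  }
  # nobody is displaced twice: compounded displacement per step sums to at
  # most the exogenous total at the final increment
  displaced <- sum(vapply(sc$steps, function(s) sum(s$partitions$affected),
                          numeric(1)))
  final_exo <- direct_effects(partition_zones(reg$zones, reg$exposure, 1.8))
  expect_lte(displaced, final_exo + 1e-6)
})

test_that("the single-model ablation changes climate flows when models differ", {
  reg <- synthetic_region(n_zones = 40, seed = 55)
  tl <- slr_timeline("medium")
  dual <- run_scenario(reg$zones, reg$exposure, tl,
                       model_C = distance_decay_model(150),
                       model_S = extended_radiation_model(0.5),
                       model_mode = "dual")
  single <- run_scenario(reg$zones, reg$exposure, tl,
                         model_C = distance_decay_model(150),
                         model_S = extended_radiation_model(0.5),
                         model_mode = "single")
  sim <- cpc(dual$steps[[1]]$climate, single$steps[[1]]$climate)
  expect_lt(sim, 1)
  # and the bau component is untouched by the switch
  expect_equal(dual$steps[[1]]$bau, single$steps[[1]]$bau)
})
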