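flows_of <- function(totals, year) {
  # one destination is enough: only origin totals matter to the filter
  data.frame(origin_id = names(totals), dest_id = "elsewhere",
             migrants = as.numeric(totals), year = year)
}

test_that("the shock rule flags coastal surges above both thresholds", {
  prev <- flows_of(c(hit = 900, small = 400, inland = 900, calm = 5000), 2004)
  curr <- flows_of(c(hit = 2000, small = 900, inland = 2000, calm = 5100), 2005)
  coastal <- c(hit = TRUE, small = TRUE, inland = FALSE, calm = TRUE,
               elsewhere = FALSE)
  det <- detect_shocked_origins(prev, curr, coastal)
  flagged <- det$county_id[det$flagged]
  expect_equal(flagged, "hit")                  # 122% rise, 2000 > 1000
  expect_false("small" %in% flagged)            # 125% rise but 900 <= 1000
  expect_false("inland" %in% flagged)           # not coastal
  expect_false("calm" %in% flagged)             # 2% rise
  expect_equal(det$pct_increase[det$county_id == "hit"], 100 * 1100 / 900)
})

test_that("zero previous outflow is an infinite increase, with a warning", {
  prev <- flows_of(c(new = 0, hit = 900), 2004)
  curr <- flows_of(c(new = 1500, hit = 2000), 2005)
  coastal <- c(new = TRUE, hit = TRUE, elsewhere = FALSE)
  expect_warning(det <- detect_shocked_origins(prev, curr, coastal),
                 "infinite")
  expect_true(det$flagged[det$county_id == "new"])
})

test_that("manual exclusions override the rule", {
  prev <- flows_of(c(hit = 900, base_closure = 900), 2005)
  curr <- flows_of(c(hit = 2000, base_closure = 2100), 2006)
  coastal <- c(hit = TRUE, base_closure = TRUE, elsewhere = FALSE)
  det <- detect_shocked_origins(prev, curr, coastal,
                                exclude = "base_closure")
  expect_equal(det$county_id[det$flagged], "hit")
})

test_that("detection is ratio-based except where the absolute floor binds", {
  prev <- flows_of(c(a = 900, b = 90), 2004)
  curr <- flows_of(c(a = 2000, b = 200), 2005)
  coastal <- c(a = TRUE, b = TRUE, elsewhere = FALSE)
  d1 <- detect_shocked_origins(prev, curr, coastal)
  expect_equal(d1$county_id[d1$flagged], "a")   # b fails the floor
  # scale both years by 10: ratios unchanged, b now clears the floor too
  prev10 <- prev; prev10$migrants <- prev10$migrants * 10
  curr10 <- curr; curr10$migrants <- curr10$migrants * 10
  d2 <- detect_shocked_origins(prev10, curr10, coastal)
  expect_setequal(d2$county_id[d2$flagged], c("a", "b"))
  expect_equal(d1$pct_increase, d2$pct_increase)
})

test_that("training split separates shocked origins and drops shocked destinations", {
  ids <- sprintf("c%d", 1:8)
  pairs <- expand.grid(origin_id = ids, dest_id = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$origin_id != pairs$dest_id, ]
  pairs$migrants <- seq_len(nrow(pairs))
  pairs$year <- 2005
  shocked <- c("c1", "c2")
  sp <- split_training_data(pairs, shocked)
  expect_equal(nrow(sp$climate), 2 * 6)
  expect_true(all(sp$climate$origin_id %in% shocked))
  expect_false(any(sp$climate$dest_id %in% shocked))
  expect_false(any(sp$bau$origin_id %in% shocked))
  expect_false(any(sp$bau$dest_id %in% shocked))
  # the two pair sets are disjoint
  key <- function(x) paste(x$origin_id, x$dest_id)
  expect_length(intersect(key(sp$climate), key(sp$bau)), 0)
  expect_warning(sp0 <- split_training_data(pairs, character(0)), "empty")
  expect_equal(nrow(sp0$bau), nrow(pairs))
  expect_error(split_training_data(pairs, "ghost"), "ghost")
})

test_that("an injected shock is recovered exactly by detection and split", {
  reg <- synthetic_region(n_zones = 60, seed = 71)
  feats <- bau_features(reg$zones)
  pre <- generate_flows(feats, extended_radiation_model(0.5), rate = 0.03,
                        year = 2004, seed = 72)
  post <- generate_flows(feats, extended_radiation_model(0.5), rate = 0.03,
                         year = 2005, seed = 73)
  coastal_ids <- reg$zones$zone_id[reg$zones$coastal]
  big <- coastal_ids[order(-reg$zones$population[match(coastal_ids,
                                                       reg$zones$zone_id)])]
  targets <- big[1:3]
  shocked <- inject_shock(post, reg$zones, targets, multiplier = 2.5,
                          seed = 74)
  coastal <- stats::setNames(reg$zones$coastal, reg$zones$zone_id)
  det <- detect_shocked_origins(pre, shocked, coastal)
  expect_setequal(det$county_id[det$flagged], targets)
  sp <- split_training_data(shocked, targets)
  expect_setequal(unique(sp$climate$origin_id), targets)
})
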