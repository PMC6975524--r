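test_that("radiation weights and normalised rows match hand-derived values", {
  feats <- data.frame(origin_id = "A", dest_id = c("B", "C"),
                      m_i = 100, m_j = 50, d_km = c(100, 200),
                      s_ij = c(0, 50))
  # w_AB = 100*50/(100*150) = 1/3, w_AC = 100*50/(150*200) = 1/6
  p <- predict(radiation_model(), feats)
  expect_equal(p, c(2 / 3, 1 / 3))
  # single destination normalises to 1
  expect_equal(predict(radiation_model(), feats[1, ]), 1)
})

test_that("all-zero destination masses fall back to a uniform row with a warning", {
  feats <- data.frame(origin_id = "A", dest_id = c("B", "C"),
                      m_i = 100, m_j = 0, d_km = c(100, 200), s_ij = 0)
  expect_warning(p <- predict(radiation_model(), feats), "uniform")
  expect_equal(p, c(0.5, 0.5))
})

test_that("extended radiation matches its closed form and rejects bad alpha", {
  w <- function(m_i, m_j, s, a) {
    ((m_i + m_j + s)^a - (m_i + s)^a) * (m_i^a + 1) /
      (((m_i + s)^a + 1) * ((m_i + m_j + s)^a + 1))
  }
  feats <- data.frame(origin_id = "A", dest_id = c("B", "C", "D"),
                      m_i = 100, m_j = c(50, 50, 0), d_km = 1,
                      s_ij = c(0, 50, 0))
  raw <- slrmig:::model_weights(extended_radiation_model(1), feats)
  expect_equal(raw[1], 50 * 101 / (101 * 151), tolerance = 1e-12)
  expect_equal(raw[2], 50 * 101 / (151 * 201), tolerance = 1e-12)
  expect_equal(raw[3], 0)
  expect_equal(raw[1:2], w(100, c(50, 50), c(0, 50), 1), tolerance = 1e-15)
  expect_error(extended_radiation_model(0), "positive")
  expect_error(extended_radiation_model(-1), "positive")
})

test_that("extended radiation approaches radiation for large populations", {
  m <- 1e6
  feats <- data.frame(origin_id = "A", dest_id = c("B", "C"),
                      m_i = m, m_j = c(m, m / 2), d_km = 1, s_ij = 0)
  p_ext <- predict(extended_radiation_model(1), feats)
  p_rad <- predict(radiation_model(), feats)
  expect_lt(max(abs(p_ext - p_rad) / p_rad), 1e-4)
})

test_that("model rows are probability distributions over many random features", {
  feats <- random_feature_rows(2000, seed = 21)
  for (model in list(radiation_model(), extended_radiation_model(0.5),
                     distance_decay_model(200))) {
    p <- predict(model, feats)
    expect_true(all(p >= 0))
    sums <- tapply(p, feats$origin_id, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("radiation closed form equals brute-force pairwise evaluation", {
  zones <- withr::with_seed(17, zone_set(
    sprintf("z%02d", 1:50), lat = stats::runif(50, 25, 35),
    lon = stats::runif(50, -95, -80),
    population = stats::rlnorm(50, 9, 1)))
  ft <- bau_features(zones)
  p <- predict(radiation_model(), ft)
  # independent route: evaluate the formula pair by pair, normalise per origin
  w_brute <- vapply(seq_len(nrow(ft)), function(k) {
    m_i <- ft$m_i[k]; m_j <- ft$m_j[k]; s <- ft$s_ij[k]
    m_i * m_j / ((m_i + s) * (m_i + m_j + s))
  }, numeric(1))
  p_brute <- unlist(lapply(split(seq_len(nrow(ft)), ft$origin_id),
                           function(idx) w_brute[idx] / sum(w_brute[idx])))
  idx <- unlist(split(seq_len(nrow(ft)), ft$origin_id))
  expect_lt(max(abs(p[idx] - p_brute)), 1e-12)
})

test_that("production functions are linear with the documented defaults", {
  g_C <- production_function(1)
  g_S <- production_function(0.03)
  expect_equal(g_C(350), 350)
  expect_equal(g_S(1000), 30)
  expect_equal(g_S(0), 0)
  expect_error(g_S(-1), "nonnegative")
  expect_error(production_function(1.5), "\\[0, 1\\]")
  expect_error(production_function(-0.1), "\\[0, 1\\]")
})

test_that("CPC scores flow-matrix overlap as defined", {
  a <- data.frame(origin_id = "A", dest_id = c("B", "C"), flow = c(10, 0))
  b <- data.frame(origin_id = "A", dest_id = c("B", "C"), flow = c(5, 5))
  expect_equal(cpc(a, a), 1)
  expect_equal(cpc(a, b), 0.5)
  disj <- data.frame(origin_id = "A", dest_id = "D", flow = 10)
  expect_equal(cpc(a, disj), 0)
  zero <- data.frame(origin_id = "A", dest_id = "B", flow = 0)
  expect_error(cpc(zero, zero), "all-zero")
})

test_that("table models replay stipulated rows and zero-fill unknown pairs", {
  tm <- table_model(data.frame(origin_id = "A", dest_id = c("B", "C"),
                               p = c(0.7, 0.3)))
  feats <- data.frame(origin_id = "A", dest_id = c("B", "C"),
                      m_i = 1, m_j = 1, d_km = 1, s_ij = 0)
  expect_equal(predict(tm, feats), c(0.7, 0.3))
  # renormalised over the offered subset
  expect_equal(predict(tm, feats[2, ]), 1)
})
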