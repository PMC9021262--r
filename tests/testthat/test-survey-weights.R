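test_that("country population factors equal population-share over sample-share", {
  # 34% of pooled under-5 population but 20% of observations -> factor 1.7
  meta <- data.frame(country = c("A", "B"), pop_u5 = c(34, 66))
  f <- country_population_factors(meta, c(A = 20, B = 80))
  expect_equal(unname(f["A"]), 0.34 / 0.20, tolerance = 1e-12)

  # equal populations, equal samples -> all ones
  meta2 <- data.frame(country = c("A", "B", "C"), pop_u5 = rep(5, 3))
  f2 <- country_population_factors(meta2, c(A = 7, B = 7, C = 7))
  expect_equal(unname(f2), rep(1, 3))

  # pops (3M, 1M), samples (100, 300) -> factors (3, 1/3)
  meta3 <- data.frame(country = c("A", "B"), pop_u5 = c(3e6, 1e6))
  f3 <- country_population_factors(meta3, c(A = 100, B = 300))
  expect_equal(unname(f3), c(3, 1 / 3), tolerance = 1e-12)

  expect_error(
    country_population_factors(
      data.frame(country = "A", pop_u5 = 0), c(A = 10)
    ),
    "A"
  )
})

test_that("round balancing equalizes round totals within country", {
  # the two-round country with sizes 232,761 and 42,615 gets equal totals
  ch <- tiny_children(c("IN", "IN"), c("r2015", "r2005"), c(2328L, 426L))
  f <- round_balance_factors(ch)
  tot <- f$n * f$factor
  expect_equal(tot[1], tot[2], tolerance = 1e-9)

  # single-round country -> factor 1
  f1 <- round_balance_factors(tiny_children("A", "r1", 50L))
  expect_equal(f1$factor, 1)

  # sizes (100, 300) -> factors (2, 2/3), totals both 200
  ch2 <- tiny_children(c("A", "A"), c("r1", "r2"), c(100L, 300L))
  f2 <- round_balance_factors(ch2)
  expect_equal(f2$factor[f2$round_id == "r1"], 2)
  expect_equal(f2$factor[f2$round_id == "r2"], 2 / 3, tolerance = 1e-12)
  expect_equal(f2$n * f2$factor, c(200, 200))
})

test_that("composite weights: identity, product contract, rescale to N", {
  # one country, one round, unit design weights -> all composites 1
  ch <- tiny_children("A", "r1", 40L)
  meta <- data.frame(country = "A", pop_u5 = 1e6)
  ws <- composite_weights(ch, meta)
  expect_equal(ws$composite, rep(1, 40))

  # composite is the product of the three factors times a global constant
  ch2 <- rbind(
    tiny_children(c("A", "A"), c("r1", "r2"), c(10L, 30L), design_weight = 2),
    tiny_children("B", "r1", 20L, design_weight = 0.5)
  )
  meta2 <- data.frame(country = c("A", "B"), pop_u5 = c(2e6, 1e6))
  ws2 <- composite_weights(ch2, meta2)
  raw <- ws2$step1_country_factor * ws2$step2_round_factor * ws2$step3_design_weight
  k <- nrow(ch2) / sum(raw)
  expect_equal(ws2$composite, raw * k, tolerance = 1e-12)
  expect_equal(sum(ws2$composite), nrow(ch2), tolerance = 1e-9)

  expect_error(
    composite_weights(tiny_children("A", "r1", 5L, design_weight = -1), meta),
    "positive"
  )
})

test_that("weighted country shares equal population shares with unit design weights", {
  # two equal-population countries, samples (100, 300)
  ch <- rbind(
    tiny_children("A", "r1", 100L),
    tiny_children(c("B", "B"), c("r1", "r2"), c(120L, 180L))
  )
  meta <- data.frame(country = c("A", "B"), pop_u5 = c(5e6, 5e6))
  chw <- add_composite_weights(ch, meta)
  audit <- weights_audit(chw, meta)
  shareA <- sum(chw$composite_weight[chw$country == "A"]) / sum(chw$composite_weight)
  expect_equal(shareA, 0.5, tolerance = 1e-12)
  expect_equal(audit$country_weight_share, audit$country_pop_share,
    tolerance = 1e-12)
  # round totals equal within B
  totB <- tapply(chw$composite_weight[chw$country == "B"],
    chw$round_id[chw$country == "B"], sum)
  expect_equal(unname(diff(range(totB))), 0, tolerance = 1e-9)
})

test_that("rescaling weights leaves WLS point estimates unchanged", {
  inst <- random_instance(99, n_clusters = 4L, n_per = 10L, k = 3L)
  f1 <- fit_wls(inst$X, inst$y, inst$w, inst$cluster)
  f2 <- fit_wls(inst$X, inst$y, inst$w * 7.3, inst$cluster)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-9)
})
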