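test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(gni_gdp_corr = 1.2), "gni_gdp_corr")
  expect_error(sim_config(gni_gdp_corr = -0.5), "gni_gdp_corr")
  expect_error(sim_config(baseline_prev_range = c(0, 0.2)), "baseline_prev_range")
  expect_error(sim_config(beta_true = Inf), "finite")
  expect_error(sim_config(rounds_per_country = c(3, 2)), "rounds_per_country")
})

test_that("macro generator: no-noise and degenerate-correlation cases", {
  # zero shock sd and zero trend sd: every country's growth equals the
  # (common) trend mean in all years
  cfg <- small_cfg(growth_shock_sd = 0, growth_trend_sd = 0,
    growth_trend_mean = 0.03, gni_gdp_corr = 1)
  macro <- generate_macro(cfg)
  g <- annual_growth(macro, "gdp")
  g <- g[!is.na(g$growth), ]
  expect_equal(g$growth, rep(3, nrow(g)), tolerance = 1e-10)

  # perfect correlation: GNI and GDP growth identical
  cfg2 <- small_cfg(gni_gdp_corr = 1)
  macro2 <- generate_macro(cfg2)
  expect_equal(
    annual_growth(macro2, "gni")$growth,
    annual_growth(macro2, "gdp")$growth,
    tolerance = 1e-9
  )
  expect_true(all(macro2$gni_pc > 0 & macro2$gdp_pc > 0))
})

test_that("pooled GNI-GDP growth correlation is calibrated to the target", {
  # 50 countries x 29 years at the default correlation target of 0.90
  cfg <- sim_config(n_countries = 50L, years = c(1990L, 2018L), seed = 42)
  macro <- generate_macro(cfg)
  gni <- annual_growth(macro, "gni")
  gdp <- annual_growth(macro, "gdp")
  ok <- !is.na(gni$growth) & !is.na(gdp$growth)
  r <- cor(gni$growth[ok], gdp$growth[ok])
  expect_true(abs(r - 0.90) < 0.05)
})

test_that("generator is deterministic and streams are independent", {
  cfg <- small_cfg(seed = 11)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$children, ds2$children)
  expect_identical(ds1$macro, ds2$macro)
  # adding the mechanism stream must not perturb the children stream
  macro <- generate_macro(cfg)
  base <- generate_children(cfg, macro)
  expect_identical(base$children[, setdiff(names(base$children),
    c("diarrhea", "fever_only", "low_maternal_bmi", "min_diet_diversity"))],
    ds1$children[, names(base$children)])
})

test_that("realized prevalence matches planted baselines when structure is off", {
  # flat world: no growth response, no covariate/temporal effects
  cfg <- small_cfg(
    seed = 5, beta_true = 0, growth_shock_sd = 0, growth_trend_sd = 0,
    growth_trend_mean = 0,
    covariate_effects = c(
      asset_some = 0, asset_all = 0, maternal_education_years = 0,
      piped_water = 0, flush_toilet = 0, facility_birth = 0, anc4 = 0,
      fully_vaccinated = 0, teen_birth = 0, parity_4plus = 0, female = 0,
      rural = 0
    ),
    age_effect_amplitude = 0, season_amplitude = 0, trend_step = 0,
    children_per_round = 2000L
  )
  ds <- generate_children(cfg, generate_macro(cfg))
  for (i in seq_len(nrow(ds$meta))) {
    cc <- ds$meta$country[i]
    sel <- ds$children$country == cc
    n <- sum(sel)
    phat <- mean(ds$children$wasting_mod_sev[sel])
    p0 <- ds$meta$base_prev_mod_sev[i]
    # 99.9% binomial CI around the planted baseline
    half <- 3.29 * sqrt(p0 * (1 - p0) / n)
    expect_true(abs(phat - p0) <= half,
      label = sprintf("%s: |%.4f - %.4f| <= %.4f", cc, phat, p0, half))
  }
})

test_that("wasting indicators are strictly nested and asset shares respected", {
  ds <- generate_dataset(small_cfg(seed = 3))
  ch <- ds$children
  expect_true(all(ch$wasting_severe <= ch$wasting_mod_sev))
  expect_true(all(ch$wasting_mod_sev <= ch$wasting_any))
  shares <- prop.table(table(ch$asset_class))[c("none", "some", "all")]
  # multinomial error at n ~ 10^4
  expect_true(all(abs(shares - c(0.34, 0.59, 0.07)) < 0.02))
})

test_that("clamping guard rejects inconsistent configurations", {
  cfg <- small_cfg(
    covariate_effects = c(
      asset_some = -0.2, asset_all = -0.4, maternal_education_years = -0.01,
      piped_water = -0.1, flush_toilet = -0.1, facility_birth = -0.1,
      anc4 = -0.1, fully_vaccinated = -0.1, teen_birth = 0.1,
      parity_4plus = 0.1, female = -0.05, rural = 0.1
    )
  )
  expect_error(generate_children(cfg, generate_macro(cfg)), "clamping")
})

test_that("mechanism outcomes: MDD age window and planted elasticity recovery", {
  ds <- generate_dataset(small_cfg(seed = 9))
  ch <- ds$children
  out_of_window <- ch$age_months < 6 | ch$age_months > 35
  expect_true(all(is.na(ch$min_diet_diversity[out_of_window])))
  expect_true(all(!is.na(ch$min_diet_diversity[!out_of_window])))

  # planted diarrhea elasticity recovered within its clustered 95% CI on a
  # larger run (parameter-recovery oracle)
  cfg <- sim_config(n_countries = 25L, children_per_round = 1500L,
    rounds_per_country = c(3L, 3L), seed = 21)
  big <- generate_dataset(cfg)
  ch2 <- add_composite_weights(big$children, big$meta)
  fit <- estimate_mechanism(ch2, big$meta, big$macro,
    model_spec(outcome = "diarrhea", measure = "gni", lag = 0L))
  planted <- cfg$mech_elasticities[["diarrhea"]]
  expect_true(fit$ci["shock", 1] <= planted && planted <= fit$ci["shock", 2])
})
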