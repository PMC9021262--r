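#' Default region roster
#'
#' Ten geographic groupings used for region-specific temporal effects:
#' three sub-Saharan groupings that separate the high-wasting Sahel & Horn
#' from the rest of the continent, plus the standard macro-regions.
#'
#' @return Character vector of ten region labels.
#' @export
default_regions <- function() {
  c(
    "Sahel & Horn of Africa", "Western & Central Africa",
    "Eastern & Southern Africa", "South Asia", "South-East Asia",
    "Middle East", "North Africa", "Eastern Europe", "Central Asia",
    "Latin America & Caribbean"
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic multi-country
#' survey generator. The generator plants a known wasting-growth elasticity
#' `beta_true` so parameter recovery of the downstream estimator is testable
#' without restricted survey microdata.
#'
#' The planted outcome model for each wasting indicator is
#' `p = clamp(pbar_c * (1 + beta_true * g/10) + age + season + trend + X'gamma)`
#' where `g` is percent income growth in the year before interview and
#' `pbar_c` the country baseline prevalence, so the conditional mean is exactly
#' linear in the regressors of the estimating equation.
#'
#' @param n_countries Number of countries.
#' @param regions Character vector of region labels; countries are assigned
#'   cyclically.
#' @param years Length-2 inclusive calendar span of survey interviews.
#' @param rounds_per_country Length-2 integer range of survey rounds drawn per
#'   country.
#' @param children_per_round Base number of children per round before the
#'   log-uniform size multiplier.
#' @param beta_true Planted elasticity of wasting prevalence per 10% change in
#'   income growth (negative: contractions raise wasting).
#' @param baseline_prev_range Interval from which country baseline
#'   moderate/severe wasting prevalence (a proportion) is drawn.
#' @param severe_ratio,any_ratio Country baseline severe (any) wasting
#'   prevalence as a multiple of the moderate/severe baseline.
#' @param growth_trend_mean,growth_trend_sd Mean and between-country sd of the
#'   long-run annual per-capita growth trend (fractions).
#' @param growth_shock_sd Within-country sd of annual growth deviations
#'   (fraction).
#' @param gni_gdp_corr Target population correlation between GNI and GDP
#'   annual growth; must lie in (0, 1].
#' @param measure Which income measure ("gni" or "gdp") drives the planted
#'   outcome response.
#' @param covariate_effects Named vector of additive probability effects for
#'   the household/maternal controls, on the moderate/severe scale. The
#'   additive shift (covariates plus age/season/trend terms) is scaled per
#'   indicator by its baseline ratio (`severe_ratio` / 1 / `any_ratio`) so
#'   rarer outcomes move less in absolute probability and the linear index
#'   stays inside the clamping band.
#' @param age_effect_amplitude,age_peak_month Gaussian-bump age profile added
#'   to all indicators, peaking at `age_peak_month` months.
#' @param season_amplitude Amplitude of the sinusoidal interview-month effect.
#' @param trend_step Additive probability change per successive 5-year bracket
#'   (scaled by region index to create region-specific trends).
#' @param asset_shares Named shares (none/some/all) of the three-level asset
#'   ownership class.
#' @param round_size_multiplier_range Log-uniform range of the round-size
#'   multiplier (deliberately unequal rounds stress the round-balancing
#'   weights).
#' @param clamp_band Probability clamping band.
#' @param max_clamp_frac Maximum tolerated fraction of clamped children before
#'   the configuration is rejected as internally inconsistent.
#' @param mech_elasticities Named planted contemporaneous-shock elasticities
#'   for the mechanism outcomes (diarrhea, fever_only, low_maternal_bmi,
#'   min_diet_diversity).
#' @param mech_baselines Named global baseline prevalences for the mechanism
#'   outcomes.
#' @param seed Integer global seed; fans out to per-stream sub-seeds.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_countries = 40L,
                       regions = default_regions(),
                       years = c(1990L, 2018L),
                       rounds_per_country = c(2L, 4L),
                       children_per_round = 2000L,
                       beta_true = -0.15,
                       baseline_prev_range = c(0.03, 0.25),
                       severe_ratio = 0.4,
                       any_ratio = 2.2,
                       growth_trend_mean = 0.02,
                       growth_trend_sd = 0.01,
                       growth_shock_sd = 0.05,
                       gni_gdp_corr = 0.90,
                       measure = c("gni", "gdp"),
                       covariate_effects = NULL,
                       age_effect_amplitude = 0.02,
                       age_peak_month = 11,
                       season_amplitude = 0.008,
                       trend_step = -0.001,
                       asset_shares = c(none = 0.34, some = 0.59, all = 0.07),
                       round_size_multiplier_range = c(0.25, 4),
                       clamp_band = c(0.001, 0.999),
                       max_clamp_frac = 0.01,
                       mech_elasticities = c(
                         diarrhea = -0.12, fever_only = -0.18,
                         low_maternal_bmi = -0.14, min_diet_diversity = 0.19
                       ),
                       mech_baselines = c(
                         diarrhea = 0.15, fever_only = 0.12,
                         low_maternal_bmi = 0.12, min_diet_diversity = 0.30
                       ),
                       seed = 1L) {
  measure <- match.arg(measure)
  if (is.null(covariate_effects)) {
    covariate_effects <- c(
      asset_some = -0.006, asset_all = -0.012,
      maternal_education_years = -0.0005,
      piped_water = -0.002, flush_toilet = -0.002,
      facility_birth = -0.002, anc4 = -0.002, fully_vaccinated = -0.002,
      teen_birth = 0.003, parity_4plus = 0.003,
      female = -0.001, rural = 0.004
    )
  }
  cfg <- list(
    n_countries = as.integer(n_countries), regions = as.character(regions),
    years = as.integer(years), rounds_per_country = as.integer(rounds_per_country),
    children_per_round = as.integer(children_per_round),
    beta_true = beta_true, baseline_prev_range = baseline_prev_range,
    severe_ratio = severe_ratio, any_ratio = any_ratio,
    growth_trend_mean = growth_trend_mean, growth_trend_sd = growth_trend_sd,
    growth_shock_sd = growth_shock_sd, gni_gdp_corr = gni_gdp_corr,
    measure = measure, covariate_effects = covariate_effects,
    age_effect_amplitude = age_effect_amplitude, age_peak_month = age_peak_month,
    season_amplitude = season_amplitude, trend_step = trend_step,
    asset_shares = asset_shares,
    round_size_multiplier_range = round_size_multiplier_range,
    clamp_band = clamp_band, max_clamp_frac = max_clamp_frac,
    mech_elasticities = mech_elasticities, mech_baselines = mech_baselines,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_countries < 1L) stop2("n_countries must be >= 1")
  if (length(cfg$years) != 2L || cfg$years[2] < cfg$years[1]) {
    stop2("years must be an inclusive span c(first, last)")
  }
  if (length(cfg$rounds_per_country) != 2L ||
      any(cfg$rounds_per_country < 1L) ||
      cfg$rounds_per_country[2] < cfg$rounds_per_country[1]) {
    stop2("rounds_per_country must be a non-degenerate positive range")
  }
  if (cfg$children_per_round < 1L) stop2("children_per_round must be positive")
  if (!is.finite(cfg$beta_true)) stop2("beta_true must be finite")
  bp <- cfg$baseline_prev_range
  if (length(bp) != 2L || bp[1] <= 0 || bp[2] >= 1 || bp[2] < bp[1]) {
    stop2("baseline_prev_range must lie strictly inside (0, 1)")
  }
  if (abs(cfg$gni_gdp_corr) > 1) {
    stop2("gni_gdp_corr must lie in [-1, 1]")
  }
  if (cfg$gni_gdp_corr <= 0) {
    stop2(
      "gni_gdp_corr must be positive: the generator adds independent noise ",
      "to GDP growth and cannot target a non-positive correlation"
    )
  }
  sh <- cfg$asset_shares
  if (!all(c("none", "some", "all") %in% names(sh)) || abs(sum(sh) - 1) > 1e-8) {
    stop2("asset_shares must be named (none/some/all) and sum to 1")
  }
  mr <- cfg$round_size_multiplier_range
  if (any(mr <= 0) || mr[2] < mr[1]) stop2("round_size_multiplier_range invalid")
  if (cfg$growth_shock_sd < 0 || cfg$growth_trend_sd < 0) {
    stop2("growth sds must be non-negative")
  }
  invisible(cfg)
}

#' Generate the country-year macroeconomic series
#'
#' Simulates per-capita GDP levels as a random-walk-with-drift in growth
#' rates, `level_t = level_{t-1} * (1 + mu_c + eps_{c,t})`, with a
#' country-specific long-run trend `mu_c` and annual deviations `eps`.
#' GNI growth equals GDP growth plus independent Gaussian noise whose
#' variance `sigma^2 * (1/rho^2 - 1)` (with `sigma^2` the pooled GDP growth
#' variance) calibrates the population correlation of the two growth series
#' to `gni_gdp_corr`. Levels start two years before the survey span so that
#' lagged annual growth exists for every interview year.
#'
#' @param cfg A [sim_config()].
#' @return A `data.frame` with columns `country`, `year`, `gni_pc`, `gdp_pc`
#'   (strictly positive levels).
#' @export
generate_macro <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(sub_seed(cfg$seed, 1L))
  countries <- sprintf("C%02d", seq_len(cfg$n_countries))
  yrs <- (cfg$years[1] - 2L):cfg$years[2]
  n_yr <- length(yrs)

  mu <- stats::rnorm(cfg$n_countries, cfg$growth_trend_mean, cfg$growth_trend_sd)
  init <- exp(stats::rnorm(cfg$n_countries, log(2000), 0.8))

  pooled_var <- cfg$growth_trend_sd^2 + cfg$growth_shock_sd^2
  rho <- cfg$gni_gdp_corr
  eta_sd <- sqrt(pooled_var * (1 / rho^2 - 1))

  out <- vector("list", cfg$n_countries)
  for (i in seq_len(cfg$n_countries)) {
    eps <- stats::rnorm(n_yr - 1L, 0, cfg$growth_shock_sd)
    g_gdp <- mu[i] + eps
    g_gni <- g_gdp + stats::rnorm(n_yr - 1L, 0, eta_sd)
    # growth floored just above -100% so levels stay strictly positive
    g_gdp <- pmax(g_gdp, -0.99)
    g_gni <- pmax(g_gni, -0.99)
    gdp <- init[i] * cumprod(c(1, 1 + g_gdp))
    gni <- init[i] * cumprod(c(1, 1 + g_gni))
    out[[i]] <- data.frame(
      country = countries[i], year = yrs, gni_pc = gni, gdp_pc = gdp,
      stringsAsFactors = FALSE
    )
  }
  macro <- do.call(rbind, out)
  rownames(macro) <- NULL
  attr(macro, "mu") <- stats::setNames(mu, countries)
  macro
}

# Additive structural effects shared by all wasting indicators; each term is a
# function of a single design-matrix block so the conditional mean stays
# linear in the estimating equation's regressors.
sim_structural_effects <- function(cfg, age, month, region_idx, year) {
  age_eff <- cfg$age_effect_amplitude *
    exp(-(age - cfg$age_peak_month)^2 / (2 * 8^2))
  month_eff <- cfg$season_amplitude * sin(2 * pi * (month - 1) / 12)
  bracket_idx <- floor((year - 1990) / 5)
  trend_eff <- cfg$trend_step * bracket_idx * (1 + 0.1 * (region_idx - 1))
  age_eff + month_eff + trend_eff
}

#' Generate the child-level survey data
#'
#' Draws survey rounds of deliberately unequal size per country (log-uniform
#' multiplier) and, for each child, covariates, a DHS-style design weight and
#' three nested wasting indicators. The three indicators are thresholded on a
#' single latent uniform draw so severe implies moderate/severe implies any
#' wasting by construction while each retains its marginal probability.
#'
#' @param cfg A [sim_config()].
#' @param macro Output of [generate_macro()] covering every interview year
#'   minus one.
#' @return An object of class `wasting_sim`: a list with elements `children`,
#'   `macro`, `meta` (country metadata with planted baselines) and `truth`
#'   (planted parameters).
#' @export
generate_children <- function(cfg, macro) {
  validate_sim_config(cfg)
  assert_cols(macro, c("country", "year", "gni_pc", "gdp_pc"), "macro")
  set.seed(sub_seed(cfg$seed, 2L))

  countries <- unique(macro$country)
  n_c <- length(countries)
  region_idx <- ((seq_len(n_c) - 1L) %% length(cfg$regions)) + 1L
  regions <- cfg$regions[region_idx]

  pop_u5 <- round(exp(stats::rnorm(n_c, log(2e6), 1.2)))
  p_ms <- stats::runif(n_c, cfg$baseline_prev_range[1], cfg$baseline_prev_range[2])
  p_sev <- cfg$severe_ratio * p_ms
  p_any <- pmin(cfg$any_ratio * p_ms, 0.6)

  meta <- data.frame(
    country = countries, region = regions, pop_u5 = pop_u5,
    base_prev_any = p_any, base_prev_mod_sev = p_ms, base_prev_severe = p_sev,
    stringsAsFactors = FALSE
  )

  growth <- annual_growth(macro, cfg$measure) # percent

  rounds <- list()
  for (i in seq_len(n_c)) {
    n_r <- sample(seq(cfg$rounds_per_country[1], cfg$rounds_per_country[2]), 1L)
    yr_pool <- seq(cfg$years[1], cfg$years[2])
    yr <- sort(sample(yr_pool, n_r))
    mult <- exp(stats::runif(
      n_r,
      log(cfg$round_size_multiplier_range[1]),
      log(cfg$round_size_multiplier_range[2])
    ))
    size <- pmax(1L, as.integer(round(cfg$children_per_round * mult)))
    rounds[[i]] <- data.frame(
      country = countries[i], round_id = sprintf("%s_r%d", countries[i], seq_len(n_r)),
      interview_year = yr, n = size, stringsAsFactors = FALSE
    )
  }
  rounds <- do.call(rbind, rounds)

  idx <- rep(seq_len(nrow(rounds)), rounds$n)
  n <- length(idx)
  ci <- match(rounds$country[idx], countries)

  ch <- data.frame(
    country = rounds$country[idx],
    region = regions[ci],
    round_id = rounds$round_id[idx],
    interview_year = rounds$interview_year[idx],
    interview_month = sample.int(12L, n, replace = TRUE),
    age_months = sample(0:59, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  ch$asset_class <- sample(
    c("none", "some", "all"), n,
    replace = TRUE,
    prob = cfg$asset_shares[c("none", "some", "all")]
  )
  ch$maternal_education_years <- pmin(stats::rpois(n, 3.5), 18L)
  bern <- function(p) stats::rbinom(n, 1L, p)
  ch$piped_water <- bern(0.40)
  ch$flush_toilet <- bern(0.25)
  ch$facility_birth <- bern(0.50)
  ch$anc4 <- bern(0.45)
  ch$fully_vaccinated <- bern(0.55)
  ch$teen_birth <- bern(0.20)
  ch$parity_4plus <- bern(0.35)
  ch$female <- bern(0.49)
  ch$rural <- bern(0.65)
  ch$design_weight <- stats::rgamma(n, shape = 4, rate = 4)

  g_lag <- growth$growth[match(
    paste(ch$country, ch$interview_year - 1L),
    paste(growth$country, growth$year)
  )]
  if (anyNA(g_lag)) stop2("macro series does not cover all interview years minus one")

  gam <- cfg$covariate_effects
  xb <- gam["asset_some"] * (ch$asset_class == "some") +
    gam["asset_all"] * (ch$asset_class == "all") +
    gam["maternal_education_years"] * ch$maternal_education_years +
    gam["piped_water"] * ch$piped_water +
    gam["flush_toilet"] * ch$flush_toilet +
    gam["facility_birth"] * ch$facility_birth +
    gam["anc4"] * ch$anc4 +
    gam["fully_vaccinated"] * ch$fully_vaccinated +
    gam["teen_birth"] * ch$teen_birth +
    gam["parity_4plus"] * ch$parity_4plus +
    gam["female"] * ch$female +
    gam["rural"] * ch$rural

  struct <- sim_structural_effects(
    cfg, ch$age_months, ch$interview_month, region_idx[ci], ch$interview_year
  )

  # The additive structural/covariate shift is scaled per indicator in
  # proportion to the indicator's baseline ratio (rarer outcomes move less
  # in absolute probability), keeping each linear index inside (0, 1).
  shift <- xb + struct
  raw_for <- function(base, ratio) {
    base[ci] * (1 + cfg$beta_true * g_lag / 10) + ratio * shift
  }
  raw_any <- raw_for(p_any, cfg$any_ratio)
  raw_ms <- raw_for(p_ms, 1)
  raw_sev <- raw_for(p_sev, cfg$severe_ratio)
  outside <- function(p) p < cfg$clamp_band[1] | p > cfg$clamp_band[2]
  frac_clamped <- (sum(outside(raw_any)) + sum(outside(raw_ms)) +
    sum(outside(raw_sev))) / (3 * n)
  if (frac_clamped > cfg$max_clamp_frac) {
    stop2(
      sprintf(
        "probability clamping affected %.2f%% of children (limit %.2f%%): ",
        100 * frac_clamped, 100 * cfg$max_clamp_frac
      ),
      "the configuration is internally inconsistent"
    )
  }
  pr_any <- clamp(raw_any, cfg$clamp_band[1], cfg$clamp_band[2])
  pr_ms <- clamp(raw_ms, cfg$clamp_band[1], cfg$clamp_band[2])
  pr_sev <- clamp(raw_sev, cfg$clamp_band[1], cfg$clamp_band[2])
  # enforce probability ordering so thresholding one latent uniform always
  # yields strictly nested indicators (binds with negligible probability)
  pr_ms <- pmax(pr_ms, pr_sev)
  pr_any <- pmax(pr_any, pr_ms)

  u <- stats::runif(n)
  ch$wasting_any <- as.integer(u < pr_any)
  ch$wasting_mod_sev <- as.integer(u < pr_ms)
  ch$wasting_severe <- as.integer(u < pr_sev)
  ch$whz <- NA_real_

  truth <- list(
    beta_true = cfg$beta_true, measure = cfg$measure,
    baseline_prevalence = meta[, c(
      "country", "base_prev_any", "base_prev_mod_sev", "base_prev_severe"
    )],
    covariate_effects = as.list(cfg$covariate_effects),
    seed = cfg$seed
  )

  structure(
    list(children = ch, macro = macro, meta = meta, truth = truth,
         config = cfg,
         probs = data.frame(any = pr_any, mod_sev = pr_ms, severe = pr_sev)),
    class = "wasting_sim"
  )
}

#' Add mechanism outcomes to a synthetic dataset
#'
#' Appends binary diarrhea, fever-only, low maternal BMI and minimum
#' dietary diversity (MDD) columns, each responding to *contemporaneous*
#' income growth through its own planted elasticity:
#' `p = pbar_mc * (1 + e_m * g_t/10)`. MDD is defined only for children
#' 6-35 months old and is missing (NA) otherwise.
#'
#' @param cfg A [sim_config()].
#' @param ds A `wasting_sim` from [generate_children()].
#' @return The dataset with mechanism columns added and planted mechanism
#'   parameters appended to `truth`.
#' @export
generate_mechanism_outcomes <- function(cfg, ds) {
  validate_sim_config(cfg)
  stopifnot(inherits(ds, "wasting_sim"), nrow(ds$children) > 0)
  set.seed(sub_seed(cfg$seed, 3L))

  ch <- ds$children
  countries <- ds$meta$country
  ci <- match(ch$country, countries)
  growth <- annual_growth(ds$macro, cfg$measure)
  g0 <- growth$growth[match(
    paste(ch$country, ch$interview_year),
    paste(growth$country, growth$year)
  )]
  if (anyNA(g0)) stop2("macro series does not cover all interview years")

  base_c <- list()
  outcomes <- c("diarrhea", "fever_only", "low_maternal_bmi", "min_diet_diversity")
  for (m in outcomes) {
    base <- cfg$mech_baselines[[m]] * stats::runif(length(countries), 0.7, 1.3)
    base_c[[m]] <- stats::setNames(base, countries)
    p <- clamp(base[ci] * (1 + cfg$mech_elasticities[[m]] * g0 / 10),
      cfg$clamp_band[1], cfg$clamp_band[2]
    )
    y <- stats::rbinom(nrow(ch), 1L, p)
    if (m == "min_diet_diversity") {
      y[ch$age_months < 6L | ch$age_months > 35L] <- NA_integer_
    }
    ch[[m]] <- y
  }

  ds$children <- ch
  ds$truth$mech_elasticities <- as.list(cfg$mech_elasticities)
  ds$truth$mech_baselines <- base_c
  ds
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_macro()], [generate_children()] and
#' [generate_mechanism_outcomes()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return A `wasting_sim` list (children, macro, meta, truth).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  macro <- generate_macro(cfg)
  ds <- generate_children(cfg, macro)
  generate_mechanism_outcomes(cfg, ds)
}

#' @export
print.wasting_sim <- function(x, ...) {
  cat("<wasting_sim> synthetic multi-country survey dataset\n")
  cat(sprintf(
    "  %d children, %d countries, %d rounds, years %d-%d\n",
    nrow(x$children), nrow(x$meta), length(unique(x$children$round_id)),
    min(x$children$interview_year), max(x$children$interview_year)
  ))
  cat(sprintf(
    "  planted elasticity beta_true = %.3f (%s growth)\n",
    x$truth$beta_true, toupper(x$truth$measure)
  ))
  invisible(x)
}
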