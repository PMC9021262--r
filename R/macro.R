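#' Annual per-capita growth from income levels
#'
#' Computes simple percent change of per-capita income levels,
#' `g_t = 100 * (Y_t - Y_{t-1}) / Y_{t-1}`. Growth is missing (not zero)
#' wherever the prior-year level is absent. If the series already carries
#' growth columns (`gni_growth` / `gdp_growth`) they are returned as-is.
#'
#' @param macro `data.frame` with `country`, `year` and either levels
#'   (`gni_pc`, `gdp_pc`) or precomputed growth columns.
#' @param measure `"gni"` or `"gdp"`.
#' @return `data.frame` with `country`, `year`, `growth` (percent per annum).
#' @export
annual_growth <- function(macro, measure = c("gni", "gdp")) {
  measure <- match.arg(measure)
  assert_cols(macro, c("country", "year"), "macro")
  gcol <- paste0(measure, "_growth")
  if (gcol %in% names(macro)) {
    out <- data.frame(
      country = macro$country, year = macro$year, growth = macro[[gcol]],
      stringsAsFactors = FALSE
    )
    return(out[order(out$country, out$year), ])
  }
  lcol <- paste0(measure, "_pc")
  assert_cols(macro, lcol, "macro")
  lv <- macro[[lcol]]
  if (any(lv <= 0, na.rm = TRUE)) stop2("income levels must be strictly positive")
  macro <- macro[order(macro$country, macro$year), ]
  lv <- macro[[lcol]]
  prev_key <- paste(macro$country, macro$year - 1L)
  prev <- lv[match(prev_key, paste(macro$country, macro$year))]
  data.frame(
    country = macro$country, year = macro$year,
    growth = 100 * (lv - prev) / prev,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Long-run mean wasting prevalence per country
#'
#' Survey-weighted prevalence is computed per round (using the children's
#' design weights), then averaged *unweighted* across a country's rounds, so
#' every round contributes equally to the country mean regardless of its
#' sample size.
#'
#' @param children Child-level `data.frame` with `country`, `round_id`,
#'   the indicator column and `design_weight`.
#' @param indicator Name of a binary outcome column.
#' @return `data.frame` with `country` and `mean_prev` (percent).
#' @export
long_run_mean_prevalence <- function(children, indicator) {
  assert_cols(children, c("country", "round_id", indicator, "design_weight"),
    "children")
  ok <- !is.na(children[[indicator]])
  ch <- children[ok, ]
  if (nrow(ch) == 0L) stop2("no non-missing observations for ", indicator)
  w <- ch$design_weight
  y <- ch[[indicator]]
  key <- interaction(ch$country, ch$round_id, drop = TRUE)
  prev_r <- 100 * tapply(w * y, key, sum) / tapply(w, key, sum)
  country_r <- tapply(ch$country, key, `[`, 1L)
  mp <- tapply(prev_r, country_r, mean)
  data.frame(
    country = names(mp), mean_prev = as.numeric(mp),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Shock-by-prevalence interaction regressor
#'
#' Builds the per-child regressor whose coefficient is the growth elasticity:
#' `mean_prev_c (as a proportion) * g_{c, t - lag} / 10`, where `g` is percent
#' annual growth. Dividing by 10 makes the coefficient read "per 10% change
#' in income"; entering the long-run prevalence as a proportion makes the
#' coefficient an elasticity of prevalence exactly, since the outcome is 0/1.
#'
#' @param children Child-level `data.frame` (`country`, `interview_year`).
#' @param macro Income series accepted by [annual_growth()].
#' @param mean_prev `data.frame` with `country`, `mean_prev` (percent), e.g.
#'   from [long_run_mean_prevalence()].
#' @param measure `"gni"` or `"gdp"`.
#' @param lag Years of lag; 1 for the main model (growth in the calendar year
#'   before interview), 0 for mechanism regressions.
#' @return Numeric vector aligned with `children` rows; NA where growth for
#'   the lagged year is unavailable (the count of such children is reported
#'   via a message).
#' @export
shock_regressor <- function(children, macro, mean_prev,
                            measure = c("gni", "gdp"), lag = 1L) {
  measure <- match.arg(measure)
  assert_cols(children, c("country", "interview_year"), "children")
  assert_cols(mean_prev, c("country", "mean_prev"), "mean_prev")
  growth <- annual_growth(macro, measure)
  g <- growth$growth[match(
    paste(children$country, children$interview_year - lag),
    paste(growth$country, growth$year)
  )]
  mp <- mean_prev$mean_prev[match(children$country, mean_prev$country)]
  if (anyNA(mp)) {
    stop2(
      "missing long-run mean prevalence for country(ies): ",
      paste(unique(children$country[is.na(mp)]), collapse = ", ")
    )
  }
  n_miss <- sum(is.na(g))
  if (n_miss > 0L) {
    message(n_miss, " children lack growth for interview_year - ", lag,
      "; they will be excluded from estimation")
  }
  (mp / 100) * g / 10
}
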