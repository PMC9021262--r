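#' Growth shock relative to the decade trend
#'
#' The projection's shock is the difference between a year's growth estimate
#' and the country's mean annual growth over the preceding decade:
#' `shock = g_year - g_decade_mean` (both percent; simple means).
#'
#' @param g_year Percent growth in the shock year (e.g. 2020), vectorised.
#' @param g_decade_mean Percent mean annual growth over the reference decade
#'   (e.g. 2010-2019).
#' @return Percent shock (negative = contraction relative to trend).
#' @export
compute_shock <- function(g_year, g_decade_mean) {
  stopifnot(all(is.finite(g_year)), all(is.finite(g_decade_mean)))
  g_year - g_decade_mean
}

#' Project wasting prevalence under a growth shock
#'
#' Applies the elasticity to the pre-shock prevalence:
#' `prev_out = prev_in * (1 + elasticity * shock / 10)`, clamped to
#' \[0, 100\] (clamping is reported via a message). With the default
#' elasticity -0.178 (moderate/severe wasting per 10% GDP growth change),
#' a -14.9% shock applied to 20.8% prevalence yields 26.3%.
#'
#' @param prev Pre-shock prevalence in percent, vectorised.
#' @param shock Percent growth shock (see [compute_shock()]).
#' @param elasticity Elasticity per 10% growth change (default -0.178).
#' @return Projected prevalence in percent (full precision; round only for
#'   display).
#' @export
project_prevalence <- function(prev, shock, elasticity = -0.178) {
  stopifnot(all(is.finite(prev)), all(is.finite(shock)), is.finite(elasticity))
  out <- prev * (1 + elasticity * shock / 10)
  n_cl <- sum(out < 0 | out > 100)
  if (n_cl > 0L) message(n_cl, " projected prevalence value(s) clamped to [0, 100]")
  clamp(out, 0, 100)
}

#' Aggregate projection rows
#'
#' Sums wasted-child counts by a grouping column (plus a `Total` row) and
#' reports aggregate prevalence as the under-5-population-weighted mean,
#' i.e. total wasted children divided by total under-5 population.
#'
#' @param rows `data.frame` with `grouping`, `pop_u5`, `wasted_2019`,
#'   `wasted_2021`, `change` (and optionally `shock`, count columns from
#'   CI-band runs).
#' @param total_label Label for the all-rows aggregate (default "Total").
#' @return `data.frame` of per-group aggregates plus the total row.
#' @export
aggregate_projection <- function(rows, total_label = "Total") {
  assert_cols(rows, c("grouping", "pop_u5", "wasted_2019", "wasted_2021", "change"),
    "rows")
  agg_one <- function(df, label) {
    out <- data.frame(
      grouping = label, n_countries = nrow(df),
      pop_u5 = sum(df$pop_u5),
      prev_2019 = 100 * sum(df$wasted_2019) / sum(df$pop_u5),
      prev_2021 = 100 * sum(df$wasted_2021) / sum(df$pop_u5),
      wasted_2019 = sum(df$wasted_2019),
      wasted_2021 = sum(df$wasted_2021),
      change = sum(df$change),
      stringsAsFactors = FALSE
    )
    for (suff in c("_lo", "_hi")) {
      wc <- paste0("wasted_2021", suff)
      if (wc %in% names(df)) {
        out[[wc]] <- sum(df[[wc]])
        out[[paste0("change", suff)]] <- sum(df[[paste0("change", suff)]])
      }
    }
    out
  }
  groups <- unique(rows$grouping)
  per_group <- do.call(rbind, lapply(groups, function(g) {
    agg_one(rows[rows$grouping == g, ], g)
  }))
  rbind(per_group, agg_one(rows, total_label))
}

#' Project wasted-child counts for a set of countries
#'
#' The burden calculator: for each country, computes the growth shock (from
#' `g2020` and `g_decade_mean`, or uses a supplied `shock` column), projects
#' prevalence through the elasticity, converts prevalences to wasted-child
#' counts using the under-5 population, and aggregates by region grouping
#' and in total. All arithmetic is carried at full float precision; rounding
#' to whole children/one decimal belongs to display.
#'
#' @param rows `data.frame` with columns `country`, `grouping`, `prev_2019`
#'   (percent), `pop_u5`, and either `shock` or both `g2020` and
#'   `g_decade_mean` (percent).
#' @param elasticity Elasticity per 10% growth change (default -0.178).
#' @param elasticity_ci Optional length-2 vector of elasticity bounds; adds
#'   `prev_2021_lo/hi`, `wasted_2021_lo/hi`, `change_lo/hi` band columns.
#' @return List with `countries` (per-country rows) and `aggregates`
#'   (per-grouping plus total; see [aggregate_projection()]).
#' @export
project_counts <- function(rows, elasticity = -0.178, elasticity_ci = NULL) {
  assert_cols(rows, c("country", "grouping", "prev_2019", "pop_u5"), "rows")
  if (nrow(rows) == 0L) stop2("projection input is empty")
  if (anyDuplicated(rows$country)) {
    stop2("duplicate country rows: ",
      paste(unique(rows$country[duplicated(rows$country)]), collapse = ", "))
  }
  if (any(rows$pop_u5 <= 0)) stop2("pop_u5 must be positive")
  if (any(rows$prev_2019 < 0 | rows$prev_2019 > 100)) {
    stop2("prev_2019 must lie in [0, 100]")
  }
  if (!"shock" %in% names(rows)) {
    assert_cols(rows, c("g2020", "g_decade_mean"), "rows")
    rows$shock <- compute_shock(rows$g2020, rows$g_decade_mean)
  }
  grouping <- rows$grouping
  grouping[is.na(grouping) | grouping == ""] <- "all"
  out <- data.frame(
    country = rows$country, grouping = grouping,
    shock = rows$shock, prev_2019 = rows$prev_2019, pop_u5 = rows$pop_u5,
    stringsAsFactors = FALSE
  )
  out$prev_2021 <- project_prevalence(out$prev_2019, out$shock, elasticity)
  out$wasted_2019 <- out$prev_2019 / 100 * out$pop_u5
  out$wasted_2021 <- out$prev_2021 / 100 * out$pop_u5
  out$change <- out$wasted_2021 - out$wasted_2019

  if (!is.null(elasticity_ci)) {
    stopifnot(length(elasticity_ci) == 2L)
    lo <- min(elasticity_ci); hi <- max(elasticity_ci)
    out$prev_2021_lo <- project_prevalence(out$prev_2019, out$shock, lo)
    out$prev_2021_hi <- project_prevalence(out$prev_2019, out$shock, hi)
    out$wasted_2021_lo <- out$prev_2021_lo / 100 * out$pop_u5
    out$wasted_2021_hi <- out$prev_2021_hi / 100 * out$pop_u5
    out$change_lo <- out$wasted_2021_lo - out$wasted_2019
    out$change_hi <- out$wasted_2021_hi - out$wasted_2019
  }
  list(countries = out, aggregates = aggregate_projection(out))
}

#' Display-round a projection table
#'
#' Rounds prevalences to one decimal and counts to whole children, mirroring
#' the conventional published layout. Use only at output: aggregates are
#' computed from full-precision country rows.
#'
#' @param df A countries or aggregates table from [project_counts()].
#' @return Rounded copy.
#' @export
round_projection <- function(df) {
  for (cc in names(df)) {
    if (startsWith(cc, "prev_")) df[[cc]] <- round(df[[cc]], 1)
    if (startsWith(cc, "wasted_") || startsWith(cc, "change")) {
      df[[cc]] <- round(df[[cc]])
    }
  }
  df
}
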