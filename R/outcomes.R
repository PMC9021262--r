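#' Classify wasting from weight-for-height z-scores
#'
#' Applies the standard strict cutoffs: any wasting (WHZ < -1),
#' moderate/severe wasting (WHZ < -2), severe wasting (WHZ < -3), so the
#' indicators are nested (severe implies moderate/severe implies any).
#' Records failing the plausibility filter (non-finite or |WHZ| above
#' `flag_limit`, the conventional WHO flagging band) get NA indicators; their
#' count is attached as attribute `n_excluded` and reported via a message.
#'
#' @param whz Numeric vector of weight-for-height z-scores.
#' @param flag_limit Plausibility bound on |WHZ| (default 5).
#' @return `data.frame` with integer columns `wasting_any`,
#'   `wasting_mod_sev`, `wasting_severe`; attribute `n_excluded`.
#' @export
classify_wasting <- function(whz, flag_limit = 5) {
  ok <- is.finite(whz) & abs(whz) <= flag_limit
  out <- data.frame(
    wasting_any = ifelse(ok, as.integer(whz < -1), NA_integer_),
    wasting_mod_sev = ifelse(ok, as.integer(whz < -2), NA_integer_),
    wasting_severe = ifelse(ok, as.integer(whz < -3), NA_integer_)
  )
  n_excl <- sum(!ok)
  if (n_excl > 0L) {
    message(n_excl, " record(s) excluded by the WHZ plausibility filter (|WHZ| <= ",
      flag_limit, " and finite)")
  }
  attr(out, "n_excluded") <- n_excl
  out
}

#' Weighted prevalence of a binary indicator
#'
#' @param children Child-level `data.frame`.
#' @param indicator Name of a binary column.
#' @param weights Optional numeric weights (default: `composite_weight`
#'   column if present, else `design_weight`).
#' @return Prevalence in percent.
#' @export
weighted_prevalence <- function(children, indicator, weights = NULL) {
  assert_cols(children, indicator, "children")
  if (is.null(weights)) {
    weights <- children$composite_weight %||% children$design_weight
    if (is.null(weights)) stop2("no weights supplied and no weight column found")
  }
  y <- children[[indicator]]
  keep <- !is.na(y)
  y <- y[keep]
  w <- weights[keep]
  if (length(y) == 0L) {
    stop2("empty selection: no non-missing values of ", indicator)
  }
  if (any(w <= 0)) stop2("weights must be positive")
  100 * sum(w * y) / sum(w)
}

#' Prevalence band label
#'
#' Classifies a wasting prevalence into the established national-threshold
#' bands: low/very low (< 5%), medium (5-10%), high (10-15%), very high
#' (>= 15%). Bands are half-open (`[0,5) [5,10) [10,15) [15,100]`) so they
#' partition 0-100 with no overlap.
#'
#' @param prev Prevalence in percent (0-100), vectorised.
#' @return Character vector of band labels.
#' @export
prevalence_band <- function(prev) {
  if (any(!is.finite(prev) | prev < 0 | prev > 100)) {
    stop2("prevalence must lie in [0, 100]")
  }
  cut(prev,
    breaks = c(0, 5, 10, 15, 100.000001), right = FALSE,
    labels = c("low/very low", "medium", "high", "very high")
  ) |> as.character()
}

#' Smoothed wasting-age profile by region
#'
#' Computes, for each region and integer age 0-59 months, a triangular-kernel
#' moving average of the per-age weighted prevalence (bandwidth in months;
#' bandwidth 0 returns the raw per-age weighted prevalences). A simplified
#' stand-in for local-polynomial age curves; no confidence bands.
#'
#' @param children Child-level `data.frame` with `region`, `age_months`.
#' @param indicator Binary outcome column name.
#' @param bandwidth Kernel half-width in months (default 3).
#' @param weights Optional weights (defaults as in [weighted_prevalence()]).
#' @return `data.frame` with `region`, `age_months`, `prevalence` (percent),
#'   `n` (children at that exact age).
#' @export
age_profile <- function(children, indicator, bandwidth = 3, weights = NULL) {
  assert_cols(children, c("region", "age_months", indicator), "children")
  if (is.null(weights)) {
    weights <- children$composite_weight %||% children$design_weight
    if (is.null(weights)) stop2("no weights supplied and no weight column found")
  }
  keep <- !is.na(children[[indicator]])
  ch <- children[keep, ]
  w <- weights[keep]
  regions <- unique(ch$region)
  ages <- 0:59
  out <- list()
  for (r in regions) {
    sel <- ch$region == r
    if (!any(sel)) {
      warning("region ", r, " has no observations; omitted")
      next
    }
    wy <- tapply(w[sel] * ch[[indicator]][sel], factor(ch$age_months[sel], levels = ages), sum)
    ww <- tapply(w[sel], factor(ch$age_months[sel], levels = ages), sum)
    nn <- tapply(rep(1L, sum(sel)), factor(ch$age_months[sel], levels = ages), sum)
    wy[is.na(wy)] <- 0; ww[is.na(ww)] <- 0; nn[is.na(nn)] <- 0L
    p_raw <- ifelse(ww > 0, wy / ww, NA_real_)
    sm <- numeric(length(ages))
    for (i in seq_along(ages)) {
      d <- abs(ages - ages[i])
      k <- pmax(0, 1 - d / (bandwidth + 1))
      num <- sum(k * wy)
      den <- sum(k * ww)
      sm[i] <- if (den > 0) num / den else NA_real_
    }
    out[[r]] <- data.frame(
      region = r, age_months = ages, prevalence = 100 * sm,
      n = as.integer(nn), stringsAsFactors = FALSE
    )
  }
  if (!length(out)) stop2("no regions with observations")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Prevalence summary table
#'
#' Weighted prevalence, band and counts for one indicator, grouped by a
#' grouping column (country or region).
#'
#' @param children Children table (needs a weight column or `weights`).
#' @param indicator Binary outcome column name.
#' @param by Grouping column name (default `"country"`).
#' @param weights Optional weights.
#' @return `data.frame`: group, indicator, prevalence, band, n, weighted n.
#' @export
prevalence_table <- function(children, indicator, by = "country", weights = NULL) {
  assert_cols(children, c(by, indicator), "children")
  if (is.null(weights)) {
    weights <- children$composite_weight %||% children$design_weight
    if (is.null(weights)) stop2("no weights supplied and no weight column found")
  }
  groups <- unique(children[[by]])
  rows <- lapply(groups, function(g) {
    sel <- children[[by]] == g
    prev <- weighted_prevalence(children[sel, ], indicator, weights[sel])
    data.frame(
      group = g, indicator = indicator, prevalence = prev,
      band = prevalence_band(prev), n = sum(sel),
      weighted_n = sum(weights[sel]), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- by
  out
}
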