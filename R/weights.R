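#' Country population weighting factors (step 1)
#'
#' Rescales each country so its share of total weight equals its share of the
#' pooled under-5 population rather than its (arbitrary) share of
#' observations: `factor_c = (pop_c / sum(pop)) / (n_c / sum(n))`.
#'
#' @param meta `data.frame` with `country` and `pop_u5`.
#' @param sample_sizes Named vector (or `data.frame` with `country`, `n`) of
#'   per-country child counts.
#' @return Named numeric vector of per-country factors.
#' @export
country_population_factors <- function(meta, sample_sizes) {
  assert_cols(meta, c("country", "pop_u5"), "meta")
  if (is.data.frame(sample_sizes)) {
    assert_cols(sample_sizes, c("country", "n"), "sample_sizes")
    sample_sizes <- stats::setNames(sample_sizes$n, sample_sizes$country)
  }
  bad <- meta$country[meta$pop_u5 <= 0]
  if (length(bad)) stop2("non-positive under-5 population for: ",
    paste(bad, collapse = ", "))
  cn <- names(sample_sizes)
  miss <- setdiff(cn, meta$country)
  if (length(miss)) stop2("countries missing from meta: ",
    paste(miss, collapse = ", "))
  if (any(sample_sizes <= 0)) {
    stop2("non-positive sample size for: ",
      paste(cn[sample_sizes <= 0], collapse = ", "))
  }
  pop <- meta$pop_u5[match(cn, meta$country)]
  pop_share <- pop / sum(pop)
  n_share <- sample_sizes / sum(sample_sizes)
  stats::setNames(as.numeric(pop_share / n_share), cn)
}

#' Round balancing factors (step 2)
#'
#' Within each country, survey rounds can have very different sample sizes;
#' this factor gives every round of a country equal total weight:
#' `factor_r = mean(round sizes in country) / size_r`.
#'
#' @param children `data.frame` with `country` and `round_id`.
#' @return `data.frame` with `country`, `round_id`, `n`, `factor`.
#' @export
round_balance_factors <- function(children) {
  assert_cols(children, c("country", "round_id"), "children")
  if (nrow(children) == 0L) stop2("children is empty")
  key <- paste(children$country, children$round_id, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  out <- data.frame(
    country = parts[, 1], round_id = parts[, 2], n = as.integer(tab),
    stringsAsFactors = FALSE
  )
  mean_n <- tapply(out$n, out$country, mean)
  out$factor <- as.numeric(mean_n[out$country]) / out$n
  rownames(out) <- NULL
  out
}

#' Composite three-step survey weights
#'
#' Combines (1) country under-5 population factors, (2) within-country round
#' balancing factors and (3) the survey design weights into one per-child
#' composite, globally rescaled so the composite weights sum to the number of
#' child records (a convention only: weighted-least-squares estimates are
#' invariant to any positive rescaling).
#'
#' @param children Child-level `data.frame` with `country`, `round_id` and
#'   `design_weight`.
#' @param meta `data.frame` with `country`, `pop_u5`.
#' @return `data.frame` aligned with `children` rows: `step1_country_factor`,
#'   `step2_round_factor`, `step3_design_weight`, `composite`.
#' @export
composite_weights <- function(children, meta) {
  assert_cols(children, c("country", "round_id", "design_weight"), "children")
  if (any(!is.finite(children$design_weight) | children$design_weight <= 0)) {
    stop2("all design weights must be positive and finite")
  }
  sizes <- table(children$country)
  f1 <- country_population_factors(meta, stats::setNames(as.integer(sizes), names(sizes)))
  f2 <- round_balance_factors(children)
  s1 <- f1[children$country]
  s2 <- f2$factor[match(
    paste(children$country, children$round_id),
    paste(f2$country, f2$round_id)
  )]
  s3 <- children$design_weight
  raw <- s1 * s2 * s3
  k <- nrow(children) / sum(raw)
  data.frame(
    step1_country_factor = as.numeric(s1),
    step2_round_factor = s2,
    step3_design_weight = s3,
    composite = as.numeric(raw * k),
    stringsAsFactors = FALSE
  )
}

#' Attach composite weights to a children table
#'
#' @param children Child-level `data.frame`.
#' @param meta Country metadata with `pop_u5`.
#' @return `children` with a `composite_weight` column appended.
#' @export
add_composite_weights <- function(children, meta) {
  ws <- composite_weights(children, meta)
  children$composite_weight <- ws$composite
  children
}

#' Audit table of weighted country/round shares
#'
#' @param children Children table with a `composite_weight` column.
#' @param meta Country metadata.
#' @return `data.frame` of per-(country, round) weight totals, country weight
#'   shares and population shares.
#' @export
weights_audit <- function(children, meta) {
  assert_cols(children, c("country", "round_id", "composite_weight"), "children")
  key <- interaction(children$country, children$round_id, drop = TRUE)
  tot <- tapply(children$composite_weight, key, sum)
  country <- tapply(children$country, key, `[`, 1L)
  round_id <- tapply(children$round_id, key, `[`, 1L)
  out <- data.frame(
    country = as.character(country), round_id = as.character(round_id),
    n = as.integer(table(key)), weight_total = as.numeric(tot),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ctot <- tapply(out$weight_total, out$country, sum)
  out$country_weight_share <- as.numeric(ctot[out$country]) / sum(out$weight_total)
  pop <- meta$pop_u5[match(out$country, meta$country)]
  pop_all <- sum(meta$pop_u5[meta$country %in% out$country])
  out$country_pop_share <- pop / pop_all
  out[order(out$country, out$round_id), ]
}
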