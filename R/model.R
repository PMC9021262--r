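#' Model specification for the wasting elasticity regressions
#'
#' Describes one weighted linear probability model: outcome, income measure,
#' growth lag, control blocks, optional subgroup interactions, extra
#' country-year controls and optional growth trimming.
#'
#' @param outcome Outcome column: one of `wasting_any`, `wasting_mod_sev`,
#'   `wasting_severe` or a mechanism column (`diarrhea`, `fever_only`,
#'   `low_maternal_bmi`, `min_diet_diversity`).
#' @param measure Income growth measure, `"gni"` or `"gdp"`.
#' @param lag Growth lag in years (1 for the main model, 0 for mechanisms).
#' @param dhs_controls Include the household/maternal control block (asset
#'   class with "no assets" reference, maternal education years, piped water,
#'   flush toilet, facility birth, antenatal care, full vaccination, teen
#'   birth, parity 4+, female, rural)?
#' @param country_fe Country fixed effects?
#' @param region_age,region_month,region_bracket Region-specific temporal
#'   effect blocks: age-in-months dummies, interview-month dummies and
#'   5-year-bracket dummies, each interacted with region.
#' @param subgroup_interactions Subset of `c("urban", "girl")`: adds
#'   shock-by-subgroup interaction columns.
#' @param extra_controls Names of extra country-year control columns already
#'   present in the children table (e.g. lagged rainfall, temperature,
#'   battle deaths).
#' @param growth_trim Optional length-2 vector of percentile bounds (e.g.
#'   `c(0.01, 0.99)`); country-years with lagged growth outside these pooled
#'   quantiles are excluded before fitting.
#' @param small_sample Clustered-variance flavour: `"CR3"` (cluster
#'   jackknife, the default — calibrated even when fixed-effect blocks
#'   absorb most of the cluster-level variation), `"CR1"` (the conventional
#'   `G/(G-1) * (N-1)/(N-k)` sandwich factor, matching the usual published
#'   convention but downward-biased in heavily absorbed designs) or
#'   `"none"` (plain sandwich).
#' @param conf_level Confidence level for reported intervals.
#' @param df_method `"t"` for t(G-1) critical values (G = number of
#'   clusters), `"normal"` for Gaussian quantiles.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome = "wasting_mod_sev",
                       measure = c("gni", "gdp"),
                       lag = 1L,
                       dhs_controls = TRUE,
                       country_fe = TRUE,
                       region_age = TRUE,
                       region_month = TRUE,
                       region_bracket = TRUE,
                       subgroup_interactions = character(0),
                       extra_controls = character(0),
                       growth_trim = NULL,
                       small_sample = c("CR3", "CR1", "none"),
                       conf_level = 0.95,
                       df_method = c("t", "normal")) {
  measure <- match.arg(measure)
  small_sample <- match.arg(small_sample)
  df_method <- match.arg(df_method)
  stopifnot(length(outcome) == 1L, lag >= 0L)
  if (length(subgroup_interactions) &&
      !all(subgroup_interactions %in% c("urban", "girl"))) {
    stop2("subgroup_interactions must be a subset of c('urban', 'girl')")
  }
  if (!is.null(growth_trim)) {
    stopifnot(length(growth_trim) == 2L, growth_trim[1] < growth_trim[2],
      growth_trim[1] >= 0, growth_trim[2] <= 1)
  }
  structure(
    list(
      outcome = outcome, measure = measure, lag = as.integer(lag),
      dhs_controls = dhs_controls, country_fe = country_fe,
      region_age = region_age, region_month = region_month,
      region_bracket = region_bracket,
      subgroup_interactions = subgroup_interactions,
      extra_controls = extra_controls, growth_trim = growth_trim,
      small_sample = small_sample, conf_level = conf_level,
      df_method = df_method
    ),
    class = "model_spec"
  )
}

dhs_control_cols <- c(
  "maternal_education_years", "piped_water", "flush_toilet", "facility_birth",
  "anc4", "fully_vaccinated", "teen_birth", "parity_4plus", "female", "rural"
)

# Column-bind a list of dense/sparse blocks into one CsparseMatrix through a
# single triplet assembly (much faster than repeated Matrix cbind).
assemble_sparse <- function(blocks, n) {
  is <- list(); js <- list(); xs <- list(); nms <- character(0)
  off <- 0L
  for (b in blocks) {
    if (is.null(b)) next
    if (inherits(b, "Matrix")) {
      tr <- Matrix::summary(methods::as(b, "CsparseMatrix"))
      is[[length(is) + 1L]] <- tr$i
      js[[length(js) + 1L]] <- tr$j + off
      xs[[length(xs) + 1L]] <- tr$x
    } else {
      b <- as.matrix(b)
      nz <- which(b != 0, arr.ind = TRUE)
      is[[length(is) + 1L]] <- nz[, 1]
      js[[length(js) + 1L]] <- nz[, 2] + off
      xs[[length(xs) + 1L]] <- b[nz]
    }
    nms <- c(nms, colnames(b))
    off <- off + ncol(b)
  }
  Matrix::sparseMatrix(
    i = unlist(is), j = unlist(js), x = unlist(xs),
    dims = c(n, off), dimnames = list(NULL, nms)
  )
}

# Treatment-coded sparse dummies for a factor, first level as reference.
sparse_dummies <- function(f, prefix) {
  f <- droplevels(as.factor(f))
  lev <- levels(f)
  if (length(lev) <= 1L) {
    return(list(mat = NULL, ref = lev[1] %||% NA_character_))
  }
  code <- as.integer(f)
  keep <- code > 1L
  m <- Matrix::sparseMatrix(
    i = which(keep), j = code[keep] - 1L, x = 1,
    dims = c(length(f), length(lev) - 1L),
    dimnames = list(NULL, paste0(prefix, lev[-1]))
  )
  list(mat = m, ref = lev[1])
}

#' Build the regression design for one model specification
#'
#' Assembles the sparse design matrix (intercept, shock-by-prevalence
#' interaction, optional subgroup interactions, DHS controls, country fixed
#' effects, region-by-age, region-by-month and region-by-5-year-bracket
#' dummies with one reference level each), the outcome vector, the composite
#' weights and the country cluster ids. Rows with any missing required field
#' are dropped and counted per column; children whose lagged growth is
#' unavailable are excluded.
#'
#' @param children Child-level table; a `composite_weight` column is used if
#'   present, otherwise computed from `meta` via [add_composite_weights()].
#' @param meta Country metadata (`country`, `region`, `pop_u5`).
#' @param macro Income series accepted by [annual_growth()].
#' @param spec A [model_spec()].
#' @param mean_prev Optional `data.frame(country, mean_prev)` (percent)
#'   overriding the estimated long-run mean prevalence — e.g. planted truth
#'   in simulation studies. Default: computed from the data with
#'   [long_run_mean_prevalence()] for the spec's outcome.
#' @return A list: `X` (sparse design), `y`, `w`, `cluster`, `reference_levels`,
#'   `missing_report`, `n_dropped`, `mean_prev`.
#' @export
build_design <- function(children, meta, macro, spec, mean_prev = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  assert_cols(children, c("country", "region", "round_id", "interview_year",
    "interview_month", "age_months", spec$outcome), "children")

  if (is.null(children$composite_weight)) {
    children <- add_composite_weights(children, meta)
  }
  if (is.null(mean_prev)) {
    mean_prev <- long_run_mean_prevalence(children, spec$outcome)
  }

  # MDD is only defined for 6-35 month olds; restrict the sample accordingly
  if (spec$outcome == "min_diet_diversity") {
    children <- children[children$age_months >= 6L & children$age_months <= 35L, ]
  }

  shock <- shock_regressor(children, macro, mean_prev, spec$measure, spec$lag)

  if (!is.null(spec$growth_trim)) {
    growth <- annual_growth(macro, spec$measure)
    g <- growth$growth[match(
      paste(children$country, children$interview_year - spec$lag),
      paste(growth$country, growth$year)
    )]
    cy <- unique(data.frame(g = g)[!is.na(g), , drop = FALSE]$g)
    qs <- stats::quantile(cy, spec$growth_trim, na.rm = TRUE, names = FALSE)
    inside <- !is.na(g) & g >= qs[1] & g <= qs[2]
    children <- children[inside, ]
    shock <- shock[inside]
  }

  req <- c(spec$outcome, "interview_year", "interview_month", "age_months")
  if (spec$dhs_controls) req <- c(req, "asset_class", dhs_control_cols)
  if (length(spec$extra_controls)) req <- c(req, spec$extra_controls)
  assert_cols(children, req, "children")

  miss_by_col <- vapply(req, function(cc) sum(is.na(children[[cc]])), 0L)
  ok <- !is.na(shock)
  for (cc in req) ok <- ok & !is.na(children[[cc]])
  n_dropped <- sum(!ok)
  ch <- children[ok, ]
  shock <- shock[ok]
  if (nrow(ch) == 0L) stop2("no rows remain after listwise deletion")

  blocks <- list()
  refs <- list()
  n <- nrow(ch)
  blocks$base <- cbind(`(Intercept)` = rep(1, n), shock = shock)

  if (length(spec$subgroup_interactions)) {
    sg <- NULL
    if ("urban" %in% spec$subgroup_interactions) {
      urban <- 1 - ch$rural
      if (length(unique(urban)) < 2L) {
        warning("subgroup 'urban' is constant in the sample; interaction dropped")
      } else {
        sg <- cbind(sg, shock_x_urban = shock * urban, urban = urban)
      }
    }
    if ("girl" %in% spec$subgroup_interactions) {
      if (length(unique(ch$female)) < 2L) {
        warning("subgroup 'girl' is constant in the sample; interaction dropped")
      } else {
        sg <- cbind(sg, shock_x_girl = shock * ch$female)
      }
    }
    if (!is.null(sg)) blocks$subgroup <- sg
  }

  if (spec$dhs_controls) {
    ctrl <- cbind(
      asset_some = as.numeric(ch$asset_class == "some"),
      asset_all = as.numeric(ch$asset_class == "all")
    )
    refs$asset_class <- "none"
    for (cc in dhs_control_cols) ctrl <- cbind(ctrl, as.numeric(ch[[cc]]))
    colnames(ctrl) <- c("asset_some", "asset_all", dhs_control_cols)
    blocks$controls <- ctrl
  }

  if (length(spec$extra_controls)) {
    ex <- as.matrix(ch[, spec$extra_controls, drop = FALSE])
    storage.mode(ex) <- "double"
    blocks$extra <- ex
  }

  if (spec$country_fe) {
    d <- sparse_dummies(ch$country, "country:")
    refs$country <- d$ref
    if (!is.null(d$mat)) blocks$country <- d$mat
  }
  if (spec$region_age) {
    d <- sparse_dummies(
      interaction(ch$region, ch$age_months, sep = ":", lex.order = TRUE),
      "region_age:"
    )
    refs$region_age <- d$ref
    if (!is.null(d$mat)) blocks$region_age <- d$mat
  }
  if (spec$region_month) {
    d <- sparse_dummies(
      interaction(ch$region, ch$interview_month, sep = ":", lex.order = TRUE),
      "region_month:"
    )
    refs$region_month <- d$ref
    if (!is.null(d$mat)) blocks$region_month <- d$mat
  }
  if (spec$region_bracket) {
    d <- sparse_dummies(
      interaction(ch$region, year_bracket(ch$interview_year),
        sep = ":", lex.order = TRUE),
      "region_bracket:"
    )
    refs$region_bracket <- d$ref
    if (!is.null(d$mat)) blocks$region_bracket <- d$mat
  }

  X <- assemble_sparse(blocks, n)
  list(
    X = X,
    y = as.numeric(ch[[spec$outcome]]),
    w = ch$composite_weight,
    cluster = ch$country,
    reference_levels = refs,
    missing_report = miss_by_col,
    n_dropped = n_dropped,
    mean_prev = mean_prev
  )
}

#' Weighted least squares with cluster-robust (sandwich) inference
#'
#' Fits a weighted linear probability model by weighted least squares and
#' computes a cluster-robust covariance. The default `"CR3"` is the cluster
#' jackknife: the model is refit leaving out one cluster at a time (via
#' downdated normal equations) and the covariance is
#' `(G-1)/G * sum_g (b_(-g) - b_bar)(b_(-g) - b_bar)'`. The `"CR1"` option is
#' the conventional sandwich `(X'WX)^{-1} (sum_g s_g s_g') (X'WX)^{-1}` with
#' cluster score sums `s_g = X_g' W_g e_g` scaled by
#' `G/(G-1) * (N-1)/(N-k)`; it is the convention of most published tables in
#' this literature but is severely downward-biased when fixed-effect blocks
#' absorb most of the within-cluster variation of the regressor of interest
#' (verified against the exact conditional variance in simulation), which is
#' why CR3 is the default. Confidence intervals use t(G-1) critical values
#' by default. Perfectly collinear columns are detected by pivoted Cholesky
#' of the (scaled) normal equations and dropped with their names recorded.
#'
#' @param X Design matrix (dense or `Matrix` sparse) with column names.
#' @param y Numeric outcome vector.
#' @param w Positive weights.
#' @param cluster Cluster ids (e.g. country codes), one per row.
#' @param small_sample `"CR3"` (jackknife, default), `"CR1"` or `"none"`.
#' @param conf_level Confidence level (default 0.95).
#' @param df_method `"t"` (t with G-1 df) or `"normal"`.
#' @return Object of class `wasting_fit`: coefficients, `vcov` (clustered),
#'   `se`, `ci` (matrix), `r2`, `n_obs`, `n_clusters`, `dropped_columns`,
#'   `reference_levels` (if attached later), `df_method`, `small_sample`.
#' @export
fit_wls <- function(X, y, w, cluster,
                    small_sample = c("CR3", "CR1", "none"),
                    conf_level = 0.95,
                    df_method = c("t", "normal")) {
  small_sample <- match.arg(small_sample)
  df_method <- match.arg(df_method)
  n <- length(y)
  stopifnot(nrow(X) == n, length(w) == n, length(cluster) == n)
  if (any(w <= 0)) stop2("weights must be strictly positive")
  G <- length(unique(cluster))
  if (G < 2L) stop2("cluster-robust inference requires at least 2 clusters")
  if (n <= ncol(X)) stop2("more columns than observations")

  X <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  cn <- colnames(X)
  Xw <- Matrix::Diagonal(x = sqrt(w)) %*% X
  A <- as.matrix(Matrix::crossprod(Xw))

  # rank-revealing pivoted Cholesky on the correlation-scaled normal matrix;
  # the shock column is held out of the pruning pass and checked against the
  # retained basis, so collinearity involving the shock is always fatal
  # rather than silently resolved by dropping some other column
  d <- sqrt(diag(A))
  d[d == 0] <- 1
  An <- A / tcrossprod(d)
  s_idx <- which(cn == "shock")
  prune_set <- setdiff(seq_along(cn), s_idx)
  ch <- suppressWarnings(chol(An[prune_set, prune_set, drop = FALSE],
    pivot = TRUE, tol = 1e-9))
  rank <- attr(ch, "rank")
  piv <- attr(ch, "pivot")
  keep <- sort(prune_set[piv[seq_len(rank)]])
  if (length(s_idx)) {
    # Schur complement of the shock column given the retained columns:
    # ~0 means the shock lies in their span and the elasticity is not
    # identified
    Aoo <- A[keep, keep, drop = FALSE]
    Aos <- A[keep, s_idx]
    schur <- A[s_idx, s_idx] - sum(Aos * solve(Aoo, Aos))
    if (!is.finite(schur) || schur <= 1e-8 * A[s_idx, s_idx]) {
      stop2("the shock interaction column is collinear with the remaining ",
        "design; the elasticity is not identified")
    }
    keep <- sort(c(keep, s_idx))
  }
  dropped <- cn[setdiff(seq_along(cn), keep)]
  if (length(dropped)) {
    X <- X[, keep, drop = FALSE]
    A <- A[keep, keep, drop = FALSE]
    cn <- cn[keep]
  }
  k <- ncol(X)

  b <- solve(A, as.numeric(Matrix::crossprod(X, w * y)))
  names(b) <- cn
  e <- y - as.numeric(X %*% b)

  # cluster score sums s_g = X_g' W_g e_g, assembled through a sparse
  # cluster-indicator matrix
  cl <- as.integer(factor(cluster))
  if (small_sample == "CR3") {
    # cluster jackknife: refit leaving each cluster out, using downdated
    # normal equations. Columns supported only by the omitted cluster (its
    # own fixed-effect dummy, single-cluster region cells) are dropped for
    # that refit; their jackknife variance is undefined and reported NA.
    Xy <- as.numeric(Matrix::crossprod(X, w * y))
    B <- matrix(NA_real_, k, G)
    dA <- diag(A)
    for (g in seq_len(G)) {
      idx <- which(cl == g)
      Xg <- X[idx, , drop = FALSE]
      wg <- w[idx]
      Ag <- as.matrix(Matrix::crossprod(Xg * sqrt(wg)))
      As <- A - Ag
      rhs <- Xy - as.numeric(Matrix::crossprod(Xg, wg * y[idx]))
      present <- which(diag(As) > 1e-10 * pmax(dA, .Machine$double.eps))
      # correlation-scaled pivoted Cholesky on the downdated system: prunes
      # columns that became collinear without the omitted cluster, and the
      # scaled triangular solve keeps the refit well conditioned
      Ms <- As[present, present, drop = FALSE]
      dm <- sqrt(diag(Ms))
      Mn <- Ms / tcrossprod(dm)
      chg <- suppressWarnings(chol(Mn, pivot = TRUE, tol = 1e-9))
      rk <- attr(chg, "rank")
      piv <- attr(chg, "pivot")[seq_len(rk)]
      R <- chg[seq_len(rk), seq_len(rk), drop = FALSE]
      rhs_n <- (rhs[present] / dm)[piv]
      sol_n <- backsolve(R, backsolve(R, rhs_n, transpose = TRUE))
      keep_g <- present[piv]
      B[keep_g, g] <- sol_n / dm[piv]
    }
    complete <- rowSums(is.na(B)) == 0L
    V <- matrix(NA_real_, k, k)
    if (any(complete)) {
      Bc <- B[complete, , drop = FALSE]
      Bc <- Bc - rowMeans(Bc)
      V[complete, complete] <- ((G - 1) / G) * tcrossprod(Bc)
    }
    dimnames(V) <- list(cn, cn)
    se <- sqrt(pmax(diag(V), 0))
  } else {
    Smat <- Matrix::sparseMatrix(i = seq_len(n), j = cl, x = w * e,
      dims = c(n, G))
    S <- as.matrix(Matrix::crossprod(X, Smat)) # k x G
    meat <- tcrossprod(S)
    Ainv <- solve(A)
    V <- Ainv %*% meat %*% Ainv
    if (small_sample == "CR1") {
      V <- V * (G / (G - 1)) * ((n - 1) / (n - k))
    }
    V <- (V + t(V)) / 2
    dimnames(V) <- list(cn, cn)
    se <- sqrt(pmax(diag(V), 0))
  }

  crit <- if (df_method == "t") {
    stats::qt(1 - (1 - conf_level) / 2, df = G - 1)
  } else {
    stats::qnorm(1 - (1 - conf_level) / 2)
  }
  ci <- cbind(lower = b - crit * se, upper = b + crit * se)

  wbar <- sum(w * y) / sum(w)
  sst <- sum(w * (y - wbar)^2)
  r2 <- if (sst > 0) 1 - sum(w * e^2) / sst else 0

  structure(
    list(
      coefficients = b, vcov = V, se = se, ci = ci,
      conf_level = conf_level, r2 = r2, n_obs = n, n_clusters = G,
      dropped_columns = dropped, df_method = df_method,
      small_sample = small_sample, residual_df = n - k
    ),
    class = "wasting_fit"
  )
}

#' @export
print.wasting_fit <- function(x, ...) {
  cat("<wasting_fit> weighted linear probability model\n")
  cat(sprintf("  N = %d, clusters = %d, R2 = %.4f\n",
    x$n_obs, x$n_clusters, x$r2))
  if (!is.null(x$elasticity_term) && x$elasticity_term %in% names(x$coefficients)) {
    tm <- x$elasticity_term
    cat(sprintf(
      "  elasticity (%s): %.4f  [%.4f, %.4f]  (%.0f%% CI, clustered SE %.4f)\n",
      tm, x$coefficients[tm], x$ci[tm, 1], x$ci[tm, 2],
      100 * x$conf_level, x$se[tm]
    ))
  }
  if (length(x$dropped_columns)) {
    cat("  dropped collinear columns:", length(x$dropped_columns), "\n")
  }
  invisible(x)
}

#' Tidy coefficient table from a fit
#'
#' @param fit A `wasting_fit`.
#' @return `data.frame` with term, estimate, clustered SE and CI bounds.
#' @export
tidy_fit <- function(fit) {
  stopifnot(inherits(fit, "wasting_fit"))
  data.frame(
    term = names(fit$coefficients),
    estimate = as.numeric(fit$coefficients),
    se_clustered = as.numeric(fit$se),
    ci_lo = as.numeric(fit$ci[, 1]),
    ci_hi = as.numeric(fit$ci[, 2]),
    stringsAsFactors = FALSE
  )
}

#' Estimate the wasting-growth elasticity
#'
#' End-to-end composition: composite weights, long-run mean prevalence,
#' shock regressor, design matrix, weighted least squares with
#' country-clustered inference. The coefficient on the shock interaction is
#' the elasticity: percent change in wasting prevalence per 10% change in
#' income growth.
#'
#' @inheritParams build_design
#' @return A `wasting_fit` with `elasticity_term = "shock"` and the design
#'   bookkeeping (`reference_levels`, `missing_report`, `n_dropped`)
#'   attached.
#' @export
estimate_elasticity <- function(children, meta, macro, spec = model_spec(),
                                mean_prev = NULL) {
  des <- build_design(children, meta, macro, spec, mean_prev)
  fit <- fit_wls(des$X, des$y, des$w, des$cluster,
    small_sample = spec$small_sample, conf_level = spec$conf_level,
    df_method = spec$df_method)
  fit$elasticity_term <- "shock"
  fit$spec <- spec
  fit$reference_levels <- des$reference_levels
  fit$missing_report <- des$missing_report
  fit$n_dropped <- des$n_dropped
  fit
}

#' Estimate a mechanism regression
#'
#' Same machinery as [estimate_elasticity()] but with a mechanism outcome
#' (diarrhea, fever-only, low maternal BMI or minimum dietary diversity),
#' contemporaneous growth (lag 0) and the interaction built from the
#' mechanism outcome's own country mean rather than mean wasting. The MDD
#' sample is restricted to children 6-35 months.
#'
#' @inheritParams build_design
#' @param spec A [model_spec()] whose `outcome` is a mechanism column;
#'   `lag` defaults to 0 in [model_spec()] calls for mechanisms.
#' @return A `wasting_fit`.
#' @export
estimate_mechanism <- function(children, meta, macro,
                               spec = model_spec(outcome = "diarrhea", lag = 0L),
                               mean_prev = NULL) {
  if (spec$lag != 0L) {
    warning("mechanism regressions conventionally use contemporaneous growth (lag = 0)")
  }
  estimate_elasticity(children, meta, macro, spec, mean_prev)
}

#' Estimate subgroup-interaction models
#'
#' Adds shock-by-urban and/or shock-by-girl interaction columns to the main
#' specification and reports base and interaction coefficients with
#' clustered confidence intervals.
#'
#' @inheritParams build_design
#' @param subgroups Subset of `c("urban", "girl")`.
#' @return A `wasting_fit`.
#' @export
estimate_subgroup <- function(children, meta, macro, spec = model_spec(),
                              subgroups = c("urban", "girl"),
                              mean_prev = NULL) {
  spec$subgroup_interactions <- subgroups
  estimate_elasticity(children, meta, macro, spec, mean_prev)
}
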