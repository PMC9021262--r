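# Shared fixtures and independent oracles for the test suite.

# Small, fast simulation configuration for routine tests.
small_cfg <- function(seed = 1L, ...) {
  defaults <- list(
    n_countries = 6L, children_per_round = 300L,
    rounds_per_country = c(2L, 3L), years = c(1995L, 2014L), seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Minimal hand-built children table: one row per child, deterministic.
tiny_children <- function(country, round_id, n_per_round,
                          design_weight = 1, y = 0L) {
  idx <- rep(seq_along(round_id), n_per_round)
  n <- length(idx)
  data.frame(
    country = country[idx], region = "R1", round_id = round_id[idx],
    interview_year = 2010L, interview_month = 6L,
    age_months = rep_len(0:59, n),
    design_weight = rep_len(design_weight, n),
    wasting_mod_sev = rep_len(y, n),
    stringsAsFactors = FALSE
  )
}

# Independently coded brute-force cluster-robust sandwich for WLS:
# dense algebra, explicit per-cluster outer products.
bf_cluster_fit <- function(X, y, w, cluster, cr1 = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  A <- t(X * w) %*% X
  b <- solve(A, t(X) %*% (w * y))
  e <- as.numeric(y - X %*% b)
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    sel <- cluster == g
    sg <- t(X[sel, , drop = FALSE]) %*% (w[sel] * e[sel])
    meat <- meat + sg %*% t(sg)
  }
  Ainv <- solve(A)
  V <- Ainv %*% meat %*% Ainv
  G <- length(unique(cluster))
  if (cr1) V <- V * (G / (G - 1)) * ((n - 1) / (n - k))
  list(coef = as.numeric(b), vcov = V)
}

# Random small full-rank regression instance with clustered rows.
random_instance <- function(seed, n_clusters = 5L, n_per = 8L, k = 3L) {
  set.seed(seed)
  n <- n_clusters * n_per
  X <- cbind(1, matrix(rnorm(n * (k - 1)), n, k - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(k - 1)))
  list(
    X = X, y = rnorm(n), w = rgamma(n, 3, 3),
    cluster = rep(seq_len(n_clusters), each = n_per)
  )
}
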