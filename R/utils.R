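# Internal helpers shared across modules.

# Deterministic per-stream sub-seed derived from one global seed, so adding a
# generation stream never perturbs the draws of another. Kept below 2^31 - 1.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) * 48271 + stream * 9973) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop2(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

# 5-year calendar brackets anchored at 1990 (1990-94, 1995-99, ...).
year_bracket <- function(year, anchor = 1990L) {
  lo <- anchor + 5L * floor((year - anchor) / 5)
  sprintf("%d-%d", lo, lo + 4L)
}
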