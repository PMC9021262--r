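#' Pipeline configuration
#'
#' Builds (or reads from a JSON file) the configuration driving the
#' [run_simulate()], [run_fit()] and [run_project()] subcommands. A complete
#' default template ships at
#' `system.file("extdata", "config_template.json", package = "wastingshocks")`.
#'
#' @param path Optional path to a JSON config; values there override the
#'   defaults, and `...` overrides both.
#' @param ... Named overrides: `out_dir`, `seed`, file paths
#'   (`children_csv`, `macro_csv`, `countries_csv`, `projection_csv`),
#'   `outcomes`, `measures`, `lag`, `elasticity`, `mechanisms` (logical),
#'   `sim` (list passed to [sim_config()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    out_dir = ".",
    seed = 1L,
    children_csv = NULL, macro_csv = NULL, countries_csv = NULL,
    projection_csv = NULL,
    outcomes = c("wasting_any", "wasting_mod_sev", "wasting_severe"),
    measures = c("gni", "gdp"),
    lag = 1L,
    mechanisms = FALSE,
    elasticity = -0.178,
    elasticity_ci = NULL,
    sim = list(),
    verbose = TRUE
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop2("config file not found: ", path)
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

say <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

#' Write a synthetic dataset to CSV files
#'
#' Emits `children.csv`, `macro.csv`, `countries.csv` and a `truth.json`
#' sidecar of planted parameters (snake_case headers, UTF-8, "." decimal,
#' empty string for missing).
#'
#' @param ds A `wasting_sim` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "wasting_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    children = file.path(dir, "children.csv"),
    macro = file.path(dir, "macro.csv"),
    countries = file.path(dir, "countries.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(ds$children, paths["children"], row.names = FALSE, na = "")
  utils::write.csv(ds$macro, paths["macro"], row.names = FALSE, na = "")
  utils::write.csv(ds$meta, paths["countries"], row.names = FALSE, na = "")
  truth <- ds$truth
  truth$baseline_prevalence <- as.list(truth$baseline_prevalence)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(paths)
}

#' Read a dataset from CSV files
#'
#' @param children_csv,macro_csv,countries_csv Paths to the three tables.
#' @return A list with `children`, `macro`, `meta`.
#' @export
read_dataset <- function(children_csv, macro_csv, countries_csv) {
  for (p in c(children_csv, macro_csv, countries_csv)) {
    if (!file.exists(p)) stop2("input file not found: ", p)
  }
  children <- utils::read.csv(children_csv, stringsAsFactors = FALSE)
  macro <- utils::read.csv(macro_csv, stringsAsFactors = FALSE)
  meta <- utils::read.csv(countries_csv, stringsAsFactors = FALSE)
  assert_cols(children, c("country", "region", "round_id", "interview_year",
    "interview_month", "age_months", "design_weight"), "children.csv")
  assert_cols(macro, c("country", "year"), "macro.csv")
  assert_cols(meta, c("country", "region", "pop_u5"), "countries.csv")
  list(children = children, macro = macro, meta = meta)
}

#' Subcommand: simulate
#'
#' Generates a synthetic dataset under the config's `sim` settings and seed,
#' and writes the CSV files plus the planted-truth sidecar to
#' `out_dir/`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the generated `wasting_sim`.
#' @export
run_simulate <- function(config = pipeline_config()) {
  sim_args <- config$sim
  sim_args$seed <- sim_args$seed %||% config$seed
  cfg <- do.call(sim_config, sim_args)
  say(config, "simulating with seed ", cfg$seed)
  ds <- generate_dataset(cfg)
  paths <- write_dataset(ds, config$out_dir)
  say(config, "wrote ", paste(basename(paths), collapse = ", "),
    " to ", config$out_dir)
  invisible(ds)
}

#' Subcommand: fit
#'
#' Runs the elasticity regressions for each requested outcome-by-measure
#' pair (the main mode mirrors a three-outcomes-by-two-measures table;
#' `mechanisms = TRUE` mirrors a four-mechanisms-by-two-measures table with
#' contemporaneous growth). Each regression is written as a tidy CSV
#' (`fit_<outcome>_<measure>.csv`) plus a run-metadata text file.
#'
#' @param config A [pipeline_config()]; either CSV paths or a `dataset`
#'   element (a list with children/macro/meta) must be supplied.
#' @param dataset Optional in-memory dataset, overriding the CSV paths.
#' @return Invisibly, a named list of `wasting_fit` objects.
#' @export
run_fit <- function(config = pipeline_config(), dataset = NULL) {
  if (is.null(dataset)) {
    if (is.null(config$children_csv)) {
      stop2("run_fit: no dataset supplied and no children_csv configured")
    }
    dataset <- read_dataset(config$children_csv, config$macro_csv,
      config$countries_csv)
  }
  children <- add_composite_weights(dataset$children, dataset$meta)
  outcomes <- if (isTRUE(config$mechanisms)) {
    c("diarrhea", "fever_only", "low_maternal_bmi", "min_diet_diversity")
  } else {
    config$outcomes
  }
  lag <- if (isTRUE(config$mechanisms)) 0L else config$lag
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  fits <- list()
  for (oc in outcomes) {
    for (ms in config$measures) {
      key <- paste(oc, ms, sep = "_")
      say(config, "fitting ", oc, " ~ ", toupper(ms), " shock (lag ", lag, ")")
      spec <- model_spec(outcome = oc, measure = ms, lag = lag)
      fit <- tryCatch(
        estimate_elasticity(children, dataset$meta, dataset$macro, spec),
        error = function(e) stop2("estimation failed for ", key, ": ",
          conditionMessage(e))
      )
      fits[[key]] <- fit
      td <- tidy_fit(fit)
      td$block <- ifelse(td$term == "shock", "elasticity",
        ifelse(grepl("^(country|region_)", td$term), "fixed_effects", "controls"))
      utils::write.csv(td, file.path(config$out_dir, paste0("fit_", key, ".csv")),
        row.names = FALSE)
      meta_lines <- c(
        paste0("outcome: ", oc), paste0("measure: ", ms),
        paste0("lag: ", lag),
        paste0("n_obs: ", fit$n_obs), paste0("n_clusters: ", fit$n_clusters),
        paste0("r2: ", format(fit$r2)),
        paste0("rows_dropped_missing: ", fit$n_dropped),
        paste0("dropped_columns: ", paste(fit$dropped_columns, collapse = "; ")),
        paste0("missingness: ", paste(names(fit$missing_report),
          fit$missing_report, sep = "=", collapse = "; "))
      )
      writeLines(meta_lines, file.path(config$out_dir, paste0("fit_", key, "_meta.txt")))
    }
  }
  invisible(fits)
}

#' Subcommand: project
#'
#' Reads the projection input CSV (`country, grouping, prev_2019, pop_u5`
#' plus `shock` or `g2020`/`g_decade_mean`), runs the burden calculator and
#' writes per-country and aggregate outputs.
#'
#' @param config A [pipeline_config()] with `projection_csv` set (or
#'   `rows` supplied directly).
#' @param rows Optional in-memory projection input, overriding the CSV.
#' @return Invisibly, the [project_counts()] result.
#' @export
run_project <- function(config = pipeline_config(), rows = NULL) {
  if (is.null(rows)) {
    if (is.null(config$projection_csv)) {
      stop2("run_project: no projection input supplied")
    }
    if (!file.exists(config$projection_csv)) {
      stop2("projection input file not found: ", config$projection_csv)
    }
    rows <- utils::read.csv(config$projection_csv, stringsAsFactors = FALSE)
  }
  res <- project_counts(rows, elasticity = config$elasticity,
    elasticity_ci = config$elasticity_ci)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(round_projection(res$countries),
    file.path(config$out_dir, "projection_countries.csv"), row.names = FALSE)
  utils::write.csv(round_projection(res$aggregates),
    file.path(config$out_dir, "projection_aggregates.csv"), row.names = FALSE)
  say(config, "total projected change in wasted children: ",
    format(round(sum(res$countries$change)), big.mark = ","))
  invisible(res)
}
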