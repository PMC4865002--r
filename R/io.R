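#' Read a population/exposure table
#'
#' CSV with header `sex,age_lower,age_upper,population,prevalence_exposed`.
#' Validation (range checks with row numbers, band overlap/contiguity per
#' sex) is applied on read.
#'
#' @param path CSV file path.
#' @return validated population data frame.
#' @export
read_population <- function(path) {
  validate_population(read_csv_checked(path,
    c("sex", "age_lower", "age_upper", "population", "prevalence_exposed")))
}

#' Read an age-specific rate schedule
#'
#' CSV with header `age,rate` and optional `scale` (1 or 100000) and `sex`
#' columns. Rates are normalised to per person-year.
#'
#' @param path CSV file path.
#' @param what label for error messages.
#' @return validated schedule data frame.
#' @export
read_schedule <- function(path, what = "rate") {
  as_rate_schedule(read_csv_checked(path, c("age", "rate")), what)
}

#' Read a historical rate series
#'
#' CSV with header `year,age_band,rate` and optional `scale`, `sex`.
#'
#' @param path CSV file path.
#' @return history data frame.
#' @export
read_rate_history <- function(path) {
  read_csv_checked(path, c("year", "age_band", "rate"))
}

read_csv_checked <- function(path, needed) {
  if (!file.exists(path)) {
    fef_stop(sprintf("file not found: %s", path), "fef_io_error")
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    fef_stop(sprintf("%s: missing column%s %s", path,
                     if (length(missing) > 1L) "s" else "",
                     paste(missing, collapse = ", ")), "fef_validation_error")
  }
  x
}

#' Read a run configuration
#'
#' YAML key tree with the run geometry (`index_year`, `interval_length`,
#' `horizon` or `horizon_end`, `max_age`), the method choices (`projector`,
#' `decrement`), `rr`, optional `seed`, and a `files` map of input CSV paths
#' (resolved relative to the config file).
#'
#' @param path YAML file path.
#' @return a `fef_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    fef_stop(sprintf("config not found: %s", path), "fef_io_error")
  }
  cfg <- yaml::read_yaml(path)
  cfg$interval_length <- cfg$interval_length %||% 5L
  cfg$max_age <- cfg$max_age %||% 100L
  cfg$projector <- cfg$projector %||% "constant"
  cfg$decrement <- cfg$decrement %||% "double"
  if (is.null(cfg$index_year)) {
    fef_stop("config must set index_year", "fef_validation_error")
  }
  if (is.null(cfg$rr)) {
    fef_stop("config must set rr", "fef_validation_error")
  }
  if (is.null(cfg$files$population) || is.null(cfg$files$mortality) ||
      is.null(cfg$files$incidence)) {
    fef_stop("config must list files: population, mortality, incidence",
             "fef_validation_error")
  }
  cfg$dir <- dirname(normalizePath(path))
  class(cfg) <- "fef_config"
  cfg
}

#' Load and cross-validate a configured input bundle
#'
#' Reads every file the config names, applies per-file validation, then the
#' cross-file checks: schedules must cover every age from the youngest
#' baseline band to `max_age - 1` for every sex in the population table.
#'
#' @param config a `fef_config` from [read_run_config()], or a path to one.
#' @return list with `population`, `mortality`, `incidence`, `history`
#'   (or `NULL`) and `config`.
#' @export
load_inputs <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "fef_config"))
  resolve <- function(f) if (is.null(f)) NULL else file.path(config$dir, f)
  population <- read_population(resolve(config$files$population))
  mortality <- read_schedule(resolve(config$files$mortality), "mortality")
  incidence <- read_schedule(resolve(config$files$incidence), "incidence")
  history <- if (!is.null(config$files$history)) {
    read_rate_history(resolve(config$files$history))
  }
  ages_needed <- min(population$age_lower):(config$max_age - 1L)
  for (g in unique(population$sex)) {
    schedule_rates(filter_sex(mortality, g), ages_needed, "mortality")
    schedule_rates(filter_sex(incidence, g), ages_needed, "incidence")
  }
  list(population = population, mortality = mortality,
       incidence = incidence, history = history, config = config)
}

#' Run the pipeline from a configuration file
#'
#' @param config a `fef_config` or path to one.
#' @return a fitted `"fef"` object.
#' @export
fef_run <- function(config) {
  bundle <- load_inputs(config)
  cfg <- bundle$config
  fef(bundle$population, bundle$mortality, bundle$incidence, rr = cfg$rr,
      history = bundle$history, projector = cfg$projector,
      decrement = cfg$decrement, index_year = cfg$index_year,
      interval_length = cfg$interval_length,
      horizon = cfg$horizon, horizon_end = cfg$horizon_end,
      max_age = cfg$max_age)
}

#' Write model results to disk
#'
#' Writes `results.csv` and `by_band.csv` at full precision (round-trippable
#' with [utils::read.csv()]) and a human-readable `results.txt` mirroring the
#' printed table, with display rounding confined to the text report
#' (fractions to 3 decimals, risks to 2 significant figures in percent,
#' counts to integers).
#'
#' @param object a fitted `"fef"` object.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_report <- function(object, dir) {
  stopifnot(inherits(object, "fef"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(results = file.path(dir, "results.csv"),
             report = file.path(dir, "results.txt"))
  utils::write.csv(format(rbind(object$results, object$total), digits = 17,
                          scientific = FALSE, trim = TRUE),
                   paths[["results"]], row.names = FALSE, quote = FALSE)
  if (!is.null(object$by_band)) {
    paths[["by_band"]] <- file.path(dir, "by_band.csv")
    utils::write.csv(format(object$by_band, digits = 17,
                            scientific = FALSE, trim = TRUE),
                     paths[["by_band"]], row.names = FALSE, quote = FALSE)
  }
  con <- file(paths[["report"]], "w")
  on.exit(close(con))
  sink(con)
  print(object)
  sink()
  invisible(paths)
}
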