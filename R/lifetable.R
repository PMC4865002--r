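#' Single-decrement survival table
#'
#' Builds the probability of being alive (and hence still contributing
#' person-years) at each integer age, given age-specific all-cause mortality
#' rates. Rates are treated as constant hazards within each single year of
#' age, so the annual survival factor is `exp(-h)`. The table starts at the
#' youngest age in the schedule with `p_at_risk = 1` and runs to `max_age`,
#' the administrative censoring age.
#'
#' @param mortality schedule with columns `age`, `rate` (all-cause death rate
#'   per person-year; `scale` column of 100000 accepted).
#' @param max_age administrative censoring age (default 100). The schedule
#'   must cover every age from its youngest up to `max_age - 1`.
#' @return a `survival_table`: data frame with `age`, `hazard` (total exit
#'   hazard used between this age and the next; `NA` at `max_age`) and
#'   `p_at_risk`, with attribute `decrement_mode = "single"`.
#' @seealso [build_double_decrement()], [compute_pyar()]
#' @export
build_single_decrement <- function(mortality, max_age = 100L) {
  mortality <- as_rate_schedule(mortality, "mortality")
  check_number(max_age, "max_age", min = 1)
  a0 <- min(mortality$age)
  ages <- a0:(max_age - 1L)
  h <- schedule_rates(mortality, ages, "mortality")
  new_survival_table(a0, max_age, h, "single")
}

#' Double-decrement survival table
#'
#' As [build_single_decrement()], but exit from the at-risk state occurs on
#' the first of death or first diagnosis of the disease of interest, the
#' disease being treated as an absorbing state (no return transition). Under
#' the constant-within-year hazard convention the two hazards add, so the
#' annual retention factor is `exp(-(h_death + h_disease))` and the
#' double-decrement `p_at_risk` can never exceed the single-decrement value.
#'
#' @inheritParams build_single_decrement
#' @param incidence schedule of first-diagnosis incidence rates per
#'   person-year, same age coverage contract as `mortality`.
#' @return a `survival_table` with `decrement_mode = "double"`.
#' @export
build_double_decrement <- function(mortality, incidence, max_age = 100L) {
  mortality <- as_rate_schedule(mortality, "mortality")
  incidence <- as_rate_schedule(incidence, "incidence")
  check_number(max_age, "max_age", min = 1)
  a0 <- max(min(mortality$age), min(incidence$age))
  ages <- a0:(max_age - 1L)
  h <- schedule_rates(mortality, ages, "mortality") +
    schedule_rates(incidence, ages, "incidence")
  new_survival_table(a0, max_age, h, "double")
}

new_survival_table <- function(a0, max_age, hazard, mode) {
  p <- c(1, exp(-cumsum(hazard)))
  out <- data.frame(
    age = a0:max_age,
    hazard = c(hazard, NA_real_),
    p_at_risk = p
  )
  attr(out, "decrement_mode") <- mode
  attr(out, "max_age") <- as.integer(max_age)
  class(out) <- c("survival_table", "data.frame")
  out
}

survival_lookup <- function(survival, ages, column = "p_at_risk") {
  idx <- match(ages, survival$age)
  if (anyNA(idx)) {
    fef_stop(sprintf("survival table does not cover age%s %s",
                     if (sum(is.na(idx)) > 1L) "s" else "",
                     paste(utils::head(ages[is.na(idx)], 5L), collapse = ", ")),
             "fef_coverage_error")
  }
  survival[[column]][idx]
}

#' Person-years at risk by baseline age band and future interval
#'
#' Converts a baseline population, enumerated by closed integer age bands at
#' the index year, into expected person-years at risk over future estimation
#' intervals, using a survival table. Cohorts advance internally along
#' single-year ages (the Lexis diagonal): a person aged `a` at the index year
#' who is still at risk at the start of future year `t` (probability
#' `p_at_risk(a + t) / p_at_risk(a)`) contributes `(1 - exp(-h)) / h`
#' person-years during that year, where `h` is the exit hazard at attained
#' age `a + t` (a full year when `h = 0`). Counts within a band are spread
#' uniformly over its single-year ages. Everyone is censored on reaching
#' `max_age` (the survival table's upper bound) or the end of the horizon,
#' whichever comes first. Person-years are attributed to the *baseline* band,
#' while downstream rate lookups use the attained age.
#'
#' @param strata data frame with columns `age_lower`, `age_upper` (closed
#'   integer bands) and `population` (baseline counts at the index year).
#' @param survival a `survival_table` covering every baseline age.
#' @param interval_length length of each future estimation interval in years.
#' @param horizon total number of future years (the final interval is
#'   truncated if `interval_length` does not divide it).
#' @return a `pyar_matrix`: list with `pyar` (band x interval matrix),
#'   `detail` (baseline single-year age x future year matrix, the Lexis
#'   decomposition used for attained-age rate lookups), band and interval
#'   descriptors, and totals.
#' @export
compute_pyar <- function(strata, survival, interval_length, horizon) {
  if (!is.data.frame(strata) ||
      !all(c("age_lower", "age_upper", "population") %in% names(strata))) {
    fef_stop("strata must have columns age_lower, age_upper, population",
             "fef_validation_error")
  }
  check_number(interval_length, "interval_length", min = 1)
  check_number(horizon, "horizon", min = 1)
  interval_length <- as.integer(interval_length)
  horizon <- as.integer(horizon)
  if (any(strata$population < 0)) {
    fef_stop("negative population count in strata", "fef_validation_error")
  }
  if (any(strata$age_upper < strata$age_lower)) {
    fef_stop("age_upper < age_lower in strata", "fef_validation_error")
  }
  max_age <- attr(survival, "max_age")

  baseline_ages <- min(strata$age_lower):max(strata$age_upper)
  # every baseline age must be inside the survival table
  survival_lookup(survival, baseline_ages)

  # uniform spread of band counts over single-year ages; band index per age
  weight <- numeric(length(baseline_ages))
  band_of_age <- integer(length(baseline_ages))
  for (i in seq_len(nrow(strata))) {
    ages_i <- strata$age_lower[i]:strata$age_upper[i]
    idx <- match(ages_i, baseline_ages)
    if (any(band_of_age[idx] != 0L)) {
      fef_stop("overlapping age bands in strata", "fef_validation_error")
    }
    band_of_age[idx] <- i
    weight[idx] <- weight[idx] + strata$population[i] / length(ages_i)
  }
  keep <- band_of_age != 0L
  baseline_ages <- baseline_ages[keep]
  weight <- weight[keep]
  band_of_age <- band_of_age[keep]

  n_int <- as.integer(ceiling(horizon / interval_length))
  interval_of_t <- rep(seq_len(n_int), each = interval_length)[seq_len(horizon)]

  detail <- matrix(0, nrow = length(baseline_ages), ncol = horizon,
                   dimnames = list(baseline_ages, seq_len(horizon) - 1L))
  p_base <- survival_lookup(survival, baseline_ages)
  for (k in seq_along(baseline_ages)) {
    a <- baseline_ages[k]
    t_max <- min(horizon, max_age - a)
    if (t_max <= 0L || weight[k] == 0) next
    t <- 0:(t_max - 1L)
    x <- a + t
    p_start <- survival_lookup(survival, x) / p_base[k]
    h <- survival_lookup(survival, x, "hazard")
    frac <- ifelse(h > 0, (1 - exp(-h)) / h, 1)
    detail[k, t + 1L] <- weight[k] * p_start * frac
  }

  labels <- band_label(strata$age_lower, strata$age_upper)
  pyar <- rowsum(detail, group = labels[band_of_age], reorder = FALSE)
  pyar <- pyar[labels, , drop = FALSE]
  pyar <- t(rowsum(t(pyar), group = interval_of_t, reorder = FALSE))
  colnames(pyar) <- paste0("interval_", seq_len(n_int))

  t_start <- (seq_len(n_int) - 1L) * interval_length
  t_end <- pmin(seq_len(n_int) * interval_length, horizon)
  structure(list(
    pyar = pyar,
    detail = detail,
    baseline_ages = baseline_ages,
    weight = weight,
    band_of_age = band_of_age,
    age_bands = data.frame(label = labels,
                           lower = strata$age_lower,
                           upper = strata$age_upper,
                           population = strata$population),
    intervals = data.frame(interval = seq_len(n_int),
                           t_start = t_start, t_end = t_end,
                           midpoint_offset = (t_start + t_end) / 2),
    interval_of_t = interval_of_t,
    interval_length = interval_length,
    horizon = horizon,
    max_age = max_age,
    total_population = sum(strata$population)
  ), class = "pyar_matrix")
}

#' Cumulative risk of disease up to an upper age limit
#'
#' The registry-style cumulative risk: the sum of age-specific incidence
#' rates over single years of age from the schedule's youngest age up to (but
#' not including) `upper_age`. Competing mortality is ignored by
#' construction, so this typically over-states the true lifetime risk. Both
#' the raw cumulative rate and its exponential transform
#' `1 - exp(-cumulative rate)` are returned; the conventional "1 in n"
#' expression uses the raw cumulative rate.
#'
#' @param incidence incidence schedule (columns `age`, `rate`).
#' @param upper_age upper age limit (risk accumulates over ages
#'   `min(age) .. upper_age - 1`).
#' @return list with `cumulative_rate`, `risk` (`1 - exp(-cumulative_rate)`)
#'   and `one_in_n` (`Inf` when the cumulative rate is zero).
#' @export
cumulative_risk <- function(incidence, upper_age) {
  incidence <- as_rate_schedule(incidence, "incidence")
  check_number(upper_age, "upper_age")
  ages <- min(incidence$age):(upper_age - 1L)
  cum <- sum(schedule_rates(incidence, ages, "incidence"))
  list(
    cumulative_rate = cum,
    risk = 1 - exp(-cum),
    one_in_n = if (cum > 0) 1 / cum else Inf
  )
}
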