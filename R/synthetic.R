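#' Generate a synthetic burden-of-disease scenario
#'
#' Builds a fully specified, seed-reproducible scenario emulating the kind
#' of inputs the method consumes in practice: a working-age population
#' pyramid by sex (an initial two-year band then five-year bands), a
#' Gompertz all-cause mortality schedule `a * exp(b * age)`, a power-law
#' age-increasing disease incidence schedule `c * (age / ref)^k` for the
#' never-exposed, a uniform index-year exposure prevalence per sex, and a
#' known relative risk. The *observed* (population-level) incidence schedule
#' handed to the pipeline is the exposure-mixed rate
#' `h_u(age) * (1 + p(RR - 1))`, which is what a registry would record for
#' the index year. Optionally a historical rate series with a known
#' log-linear drift is generated for the projection module.
#'
#' Defaults mirror an Australia-2012-like setting: ages 18-64 enumerated in
#' bands 18-19, 20-24, ..., 60-64; male exposure prevalence 0.0347 and
#' female 0.0004; index year 2012, 5-year estimation intervals, follow-up to
#' 2094 (83 years), administrative censoring at age 100. The default RR of
#' 14 and the incidence scales are calibrated so the default scenario's
#' lifetime risks and excess fractions sit in the range reported for
#' occupational asbestos and mesothelioma (lifetime risk of a few per
#' 10,000; a male excess fraction of roughly a third at 3.5 % prevalence).
#'
#' @param seed integer seed; the scenario is deterministic given it.
#' @param sexes group labels.
#' @param band_breaks lower bounds of the baseline age bands plus the
#'   exclusive upper end (default `c(18, 20, 25, ..., 65)`).
#' @param pop_per_age mean population per single year of age, per sex.
#' @param pop_noise_sd lognormal noise (sd of log) on band populations.
#' @param prevalence named vector of index-year exposure prevalences per sex.
#' @param rr relative risk for the exposed.
#' @param gompertz_a,gompertz_b mortality hazard `a * exp(b * age)` per sex
#'   (`a` named per sex).
#' @param incidence_scale,incidence_power,incidence_ref_age never-exposed
#'   incidence hazard `scale * (age / ref_age)^power` (`scale` named per sex).
#' @param index_year,interval_length,horizon,max_age run geometry.
#' @param history_years number of historical years of banded rates to emit
#'   (0 for none).
#' @param drift log-linear annual drift used to generate the history.
#' @param history_noise_sd lognormal noise on historical rates.
#' @return a `fef_scenario` list with `population`, `mortality`,
#'   `incidence` (observed), `incidence_unexposed`, `history` (or `NULL`),
#'   `rr`, and the run geometry fields.
#' @seealso [microsimulate()], [write_scenario()], [fef_from_scenario()]
#' @export
generate_scenario <- function(seed,
                              sexes = c("male", "female"),
                              band_breaks = c(18L, 20L, seq(25L, 65L, by = 5L)),
                              pop_per_age = c(male = 155000, female = 150000),
                              pop_noise_sd = 0.05,
                              prevalence = c(male = 0.0347, female = 0.0004),
                              rr = 14,
                              gompertz_a = c(male = 3e-5, female = 1.8e-5),
                              gompertz_b = 0.09,
                              incidence_scale = c(male = 6e-5, female = 3.4e-5),
                              incidence_power = 3,
                              incidence_ref_age = 70,
                              index_year = 2012L,
                              interval_length = 5L,
                              horizon = 83L,
                              max_age = 100L,
                              history_years = 0L,
                              drift = 0,
                              history_noise_sd = 0) {
  check_number(seed, "seed")
  check_number(rr, "rr", min = 1)
  check_number(pop_noise_sd, "pop_noise_sd", min = 0)
  check_number(history_noise_sd, "history_noise_sd", min = 0)
  if (any(prevalence[sexes] < 0) || any(prevalence[sexes] > 1) ||
      anyNA(prevalence[sexes])) {
    fef_stop("prevalence must be named per sex and lie in [0, 1]",
             "fef_validation_error")
  }
  if (any(gompertz_a[sexes] < 0) || any(incidence_scale[sexes] < 0) ||
      anyNA(gompertz_a[sexes]) || anyNA(incidence_scale[sexes])) {
    fef_stop("hazard coefficients must be named per sex and non-negative",
             "fef_validation_error")
  }
  set.seed(seed)

  lower <- band_breaks[-length(band_breaks)]
  upper <- band_breaks[-1L] - 1L
  width <- upper - lower + 1L
  ages <- min(lower):max_age

  population <- do.call(rbind, lapply(sexes, function(g) {
    noise <- stats::rlnorm(length(lower), -pop_noise_sd^2 / 2, pop_noise_sd)
    data.frame(sex = g, age_lower = lower, age_upper = upper,
               population = round(pop_per_age[[g]] * width * noise),
               prevalence_exposed = prevalence[[g]],
               stringsAsFactors = FALSE)
  }))

  mortality <- do.call(rbind, lapply(sexes, function(g) {
    data.frame(sex = g, age = ages,
               rate = gompertz_a[[g]] * exp(gompertz_b * ages),
               stringsAsFactors = FALSE)
  }))

  inc_u <- do.call(rbind, lapply(sexes, function(g) {
    data.frame(sex = g, age = ages,
               rate = incidence_scale[[g]] * (ages / incidence_ref_age)^incidence_power,
               stringsAsFactors = FALSE)
  }))
  incidence <- inc_u
  mix <- 1 + prevalence[incidence$sex] * (rr - 1)
  incidence$rate <- incidence$rate * as.numeric(mix)

  history <- NULL
  if (history_years > 0L) {
    h_lower <- c(lower, seq(max(upper) + 1L, max_age - 1L, by = 5L))
    h_upper <- c(upper, pmin(seq(max(upper) + 5L, max_age + 3L, by = 5L), max_age - 1L))
    mid <- (h_lower + h_upper) / 2
    yrs <- (index_year - history_years):(index_year - 1L)
    history <- do.call(rbind, lapply(sexes, function(g) {
      base <- incidence_scale[[g]] * (mid / incidence_ref_age)^incidence_power *
        (1 + prevalence[[g]] * (rr - 1))
      do.call(rbind, lapply(yrs, function(y) {
        noise <- if (history_noise_sd > 0) {
          stats::rlnorm(length(mid), -history_noise_sd^2 / 2, history_noise_sd)
        } else 1
        data.frame(sex = g, year = y,
                   age_band = band_label(h_lower, h_upper),
                   rate = base * exp(drift * (y - index_year)) * noise,
                   stringsAsFactors = FALSE)
      }))
    }))
  }

  structure(list(
    seed = as.integer(seed),
    population = population,
    mortality = mortality,
    incidence = incidence,
    incidence_unexposed = inc_u,
    history = history,
    rr = rr,
    prevalence = prevalence[sexes],
    index_year = as.integer(index_year),
    interval_length = as.integer(interval_length),
    horizon = as.integer(horizon),
    max_age = as.integer(max_age)
  ), class = "fef_scenario")
}

#' Fit the model to a synthetic scenario
#'
#' Convenience wrapper running [fef()] on a scenario's observed inputs.
#'
#' @param scenario a `fef_scenario`.
#' @param ... overrides passed on to [fef()] (e.g. `projector`).
#' @return a fitted `"fef"` object.
#' @export
fef_from_scenario <- function(scenario, ...) {
  stopifnot(inherits(scenario, "fef_scenario"))
  args <- list(population = scenario$population,
               mortality = scenario$mortality,
               incidence = scenario$incidence,
               rr = scenario$rr,
               history = scenario$history,
               index_year = scenario$index_year,
               interval_length = scenario$interval_length,
               horizon = scenario$horizon,
               max_age = scenario$max_age)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(fef, args)
}

#' Individual-level microsimulation oracle
#'
#' Simulates individual lifetimes under the scenario's hazards and tallies
#' person-years, survival and case counts by exposure group. Individuals are
#' drawn iid: sex and baseline age proportional to the scenario population
#' (uniform within band), exposure Bernoulli with the stratum prevalence.
#' Each person faces the never-exposed mortality and incidence hazards at
#' their attained age, the incidence hazard multiplied by RR for life if
#' exposed in the index year; death and first diagnosis compete, diagnosis
#' is absorbing. Exit times are drawn exactly from the piecewise-exponential
#' distribution on annual hazard pieces — the same constant-within-year
#' convention as the life tables, so discretisation cancels in comparisons.
#' Follow-up is censored at the scenario horizon or at `max_age`.
#'
#' @param scenario a `fef_scenario`.
#' @param n total number of simulated individuals.
#' @param seed simulation seed (independent of the scenario seed).
#' @return list with `individuals` (data frame: `sex`, `age0`, `exposed`,
#'   `py`, `exit` in death/case/censored, `exit_time`), `summary` (per sex
#'   and exposure group: `n`, `py_mean`, `py_sd`, `cases`, `risk`,
#'   `risk_se`), `n` and `seed`.
#' @export
microsimulate <- function(scenario, n = 100000L, seed = 1L) {
  stopifnot(inherits(scenario, "fef_scenario"))
  check_number(n, "n", min = 1)
  check_number(seed, "seed")
  set.seed(seed)
  pop <- scenario$population
  horizon <- scenario$horizon
  max_age <- scenario$max_age

  # sample strata, single-year ages and exposure
  stratum <- sample.int(nrow(pop), n, replace = TRUE, prob = pop$population)
  width <- pop$age_upper - pop$age_lower + 1L
  age0 <- pop$age_lower[stratum] +
    floor(stats::runif(n) * width[stratum])
  sex <- pop$sex[stratum]
  exposed <- stats::rbinom(n, 1L, pop$prevalence_exposed[stratum])

  py <- numeric(n)
  exit <- rep("censored", n)
  exit_time <- numeric(n)
  E <- stats::rexp(n)

  idx_by_key <- split(seq_len(n), paste(sex, age0, exposed))
  for (idx in idx_by_key) {
    g <- sex[idx[1L]]
    a <- age0[idx[1L]]
    ex <- exposed[idx[1L]]
    t_max <- min(horizon, max_age - a)
    if (t_max <= 0L) next
    x <- a + 0:(t_max - 1L)
    mort <- filter_sex(scenario$mortality, g)
    incu <- filter_sex(scenario$incidence_unexposed, g)
    h_d <- schedule_rates(mort, x, "mortality")
    h_i <- schedule_rates(incu, x, "incidence") * if (ex) scenario$rr else 1
    h <- h_d + h_i
    cumh <- c(0, cumsum(h))
    e <- E[idx]
    yr <- findInterval(e, cumh, left.open = TRUE)  # exit year index (1-based)
    out <- yr > t_max
    yr_in <- pmin(yr, t_max)
    within <- ifelse(out | h[yr_in] == 0, 0,
                     (e - cumh[yr_in]) / h[yr_in])
    py[idx] <- ifelse(out, t_max, (yr_in - 1L) + within)
    exit_time[idx] <- py[idx]
    if (any(!out)) {
      j <- idx[!out]
      yrj <- yr[!out]
      p_case <- ifelse(h[yrj] > 0, h_i[yrj] / h[yrj], 0)
      is_case <- stats::runif(length(j)) < p_case
      exit[j] <- ifelse(is_case, "case", "death")
    }
  }

  individuals <- data.frame(sex = sex, age0 = age0, exposed = exposed,
                            py = py, exit = exit, exit_time = exit_time,
                            stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(individuals,
                                     list(individuals$sex, individuals$exposed),
                                     drop = TRUE), function(d) {
    risk <- mean(d$exit == "case")
    data.frame(sex = d$sex[1L], exposed = d$exposed[1L], n = nrow(d),
               py_mean = mean(d$py), py_sd = stats::sd(d$py),
               cases = sum(d$exit == "case"), risk = risk,
               risk_se = sqrt(risk * (1 - risk) / nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(individuals = individuals, summary = agg, n = as.integer(n),
       seed = as.integer(seed))
}

#' Write a scenario to the CSV/YAML dialects the pipeline reads
#'
#' Emits `population.csv`, `mortality.csv`, `incidence.csv`, optionally
#' `history.csv`, and a `config.yaml` pointing at them, so that
#' [load_inputs()] / [fef_run()] can consume the bundle.
#'
#' @param scenario a `fef_scenario`.
#' @param dir output directory (created if needed).
#' @return the config file path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "fef_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(scenario$population, file.path(dir, "population.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$mortality, file.path(dir, "mortality.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$incidence, file.path(dir, "incidence.csv"),
                   row.names = FALSE)
  config <- list(
    index_year = scenario$index_year,
    interval_length = scenario$interval_length,
    horizon = scenario$horizon,
    max_age = scenario$max_age,
    projector = "constant",
    decrement = "double",
    rr = scenario$rr,
    seed = scenario$seed,
    files = list(population = "population.csv",
                 mortality = "mortality.csv",
                 incidence = "incidence.csv")
  )
  if (!is.null(scenario$history)) {
    utils::write.csv(scenario$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
    config$files$history <- "history.csv"
    config$projector <- "loglinear"
  }
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}
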