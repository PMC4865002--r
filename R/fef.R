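#' Fit the future excess fraction model
#'
#' Runs the full future-excess-fraction pipeline for a population
#' cross-classified by sex and age band at an index year: builds a (single-
#' or double-decrement) survival table per sex, converts the baseline
#' population into a person-years-at-risk matrix, projects age-specific
#' disease rates over the horizon, multiplies the two into expected cases
#' `D_ij` and their total `FN_p`, and derives the lifetime risk `LR_p`, the
#' baseline and excess lifetime risks `LR_u` and `LR_x`, the future excess
#' number `FEN = LR_x * N_e` and the future excess fraction
#' `FEF = FEN / FN_p` per sex. Only exposure in the index year counts as
#' exposed; people exposed in the past but not in the index year are
#' unexposed. No latency period is applied: the lifetime-risk formulation
#' counts cases whenever they occur over the cohort's remaining lifetime.
#'
#' @param population data frame with columns `sex`, `age_lower`, `age_upper`
#'   (closed integer bands, non-overlapping and contiguous within sex),
#'   `population` (counts at the index year) and `prevalence_exposed`
#'   (proportion exposed in the index year, in `[0, 1]`).
#' @param mortality all-cause mortality schedule (`age`, `rate`, optional
#'   `scale` and `sex` columns) covering every age from the youngest band to
#'   `max_age - 1`.
#' @param incidence index-year disease incidence schedule, same format and
#'   coverage. Used for the second decrement (when `decrement = "double"`)
#'   and as the baseline for the constant projector.
#' @param rr relative risk for the exposed versus never-exposed (a single
#'   number `>= 1`), or a data frame with columns `prevalence` and `rr` (and
#'   optionally `level`) describing multiple exposure levels; level
#'   prevalences are applied uniformly to each sex's population and then
#'   override `prevalence_exposed`.
#' @param history optional historical rate series (`year`, `age_band`,
#'   `rate`, optional `scale`, `sex`) for the log-linear projector.
#' @param projector `"constant"` (index-year rates carried forward) or
#'   `"loglinear"` (shared-drift log-linear fit to `history`).
#' @param decrement `"double"` (exit on death or first diagnosis; the
#'   disease is treated as absorbing) or `"single"` (death only).
#' @param index_year calendar year at which the cohort is enumerated (t = 0).
#' @param interval_length estimation-interval length in years (default 5).
#' @param horizon number of future years to follow the cohort; alternatively
#'   give `horizon_end`, the last calendar year, so that
#'   `horizon = horizon_end - index_year + 1`. Defaults to following everyone
#'   to `max_age`.
#' @param horizon_end last calendar year of follow-up (see `horizon`).
#' @param max_age administrative censoring age (default 100).
#' @return an object of class `"fef"`: list with `results` (one row per sex
#'   plus a pooled `total` row), `by_band` (per-band transparency table),
#'   `groups` (per-sex survival table, PYAR, projected rates, cases),
#'   `config`, and the validated `inputs`. See [print.fef()],
#'   [summary.fef()], [coef.fef()], [plot.fef()], [af_comparison()],
#'   [fef_sensitivity()].
#' @examples
#' sc <- generate_scenario(seed = 1)
#' fit <- fef(sc$population, sc$mortality, sc$incidence, rr = sc$rr,
#'            index_year = sc$index_year, interval_length = sc$interval_length,
#'            horizon = sc$horizon, max_age = sc$max_age)
#' fit
#' @export
fef <- function(population, mortality, incidence, rr,
                history = NULL,
                projector = c("constant", "loglinear"),
                decrement = c("double", "single"),
                index_year = 2012L,
                interval_length = 5L,
                horizon = NULL,
                horizon_end = NULL,
                max_age = 100L) {
  projector <- match.arg(projector)
  decrement <- match.arg(decrement)
  check_number(index_year, "index_year")
  check_number(interval_length, "interval_length", min = 1)
  check_number(max_age, "max_age", min = 1)
  population <- validate_population(population)
  if (projector == "loglinear" && is.null(history)) {
    fef_stop("the loglinear projector requires a rate history", "fef_validation_error")
  }
  if (is.null(horizon)) {
    horizon <- if (!is.null(horizon_end)) {
      as.integer(horizon_end) - as.integer(index_year) + 1L
    } else {
      as.integer(max_age) - min(population$age_lower)
    }
  }
  check_number(horizon, "horizon", min = 1)

  levels_df <- NULL
  if (is.data.frame(rr)) {
    if (!all(c("prevalence", "rr") %in% names(rr))) {
      fef_stop("multi-level exposure must have columns prevalence, rr",
               "fef_validation_error")
    }
    if (sum(rr$prevalence) > 1) {
      fef_stop("exposure-level prevalences sum to more than 1", "fef_validation_error")
    }
    levels_df <- rr
  } else {
    check_number(rr, "rr", min = 0)
  }

  groups <- unique(population$sex)
  group_fits <- list()
  res <- list()
  bandres <- list()
  for (g in groups) {
    pop_g <- population[population$sex == g, , drop = FALSE]
    mort_g <- filter_sex(mortality, g)
    inc_g <- filter_sex(incidence, g)
    hist_g <- filter_sex(history, g)

    survival <- switch(decrement,
      double = build_double_decrement(mort_g, inc_g, max_age),
      single = build_single_decrement(mort_g, max_age))
    strata <- pop_g[c("age_lower", "age_upper", "population")]
    pyar <- compute_pyar(strata, survival, interval_length, horizon)
    rates <- switch(projector,
      constant = project_constant(inc_g, pyar),
      loglinear = project_loglinear(hist_g, pyar, index_year))
    cases <- expected_cases(pyar, rates)

    n_p <- sum(pop_g$population)
    if (is.null(levels_df)) {
      n_e <- sum(pop_g$population * pop_g$prevalence_exposed)
      rr_vec <- rr
    } else {
      n_e <- n_p * levels_df$prevalence
      rr_vec <- levels_df$rr
    }
    lr_p <- lifetime_risk(cases, n_p)
    ler <- lifetime_excess_risk(lr_p, n_p, n_e, rr_vec)
    fen <- future_excess_number(ler$LR_x, n_e)
    fef_val <- future_excess_fraction(fen, cases$FN_p)

    res[[g]] <- data.frame(
      group = g, N_p = n_p, N_e = sum(n_e),
      prevalence = sum(n_e) / n_p,
      LR_p = lr_p, FN_p = cases$FN_p,
      LR_u = ler$LR_u,
      LR_x = if (sum(n_e) > 0) fen / sum(n_e) else 0,
      FEN = fen, FEF = fef_val,
      stringsAsFactors = FALSE
    )

    # per-band transparency table: the band-level run of the same arithmetic
    n_p_b <- pop_g$population
    n_e_b <- if (is.null(levels_df)) pop_g$population * pop_g$prevalence_exposed
             else NULL
    lr_p_b <- ifelse(n_p_b > 0, cases$by_band / n_p_b, 0)
    if (is.null(levels_df)) {
      lr_x_b <- fen_b <- numeric(length(n_p_b))
      for (i in seq_along(n_p_b)) {
        if (n_p_b[i] > 0) {
          l <- lifetime_excess_risk(min(lr_p_b[i], 1), n_p_b[i], n_e_b[i], rr)
          lr_x_b[i] <- l$LR_x
          fen_b[i] <- future_excess_number(l$LR_x, n_e_b[i])
        }
      }
      bandres[[g]] <- data.frame(
        group = g, band = pyar$age_bands$label,
        N_p = n_p_b, N_e = n_e_b, LR_p = lr_p_b,
        FN_p = as.numeric(cases$by_band), LR_x = lr_x_b, FEN = fen_b,
        stringsAsFactors = FALSE
      )
    }

    group_fits[[g]] <- list(survival = survival, pyar = pyar,
                            rates = rates, cases = cases,
                            n_p = n_p, n_e = n_e, rr = rr_vec)
  }

  results <- do.call(rbind, res)
  rownames(results) <- NULL
  total <- data.frame(
    group = "total",
    N_p = sum(results$N_p), N_e = sum(results$N_e),
    prevalence = sum(results$N_e) / sum(results$N_p),
    LR_p = sum(results$FN_p) / sum(results$N_p),
    FN_p = sum(results$FN_p),
    LR_u = NA_real_,
    LR_x = if (sum(results$N_e) > 0) sum(results$FEN) / sum(results$N_e) else 0,
    FEN = sum(results$FEN),
    FEF = sum(results$FEN) / sum(results$FN_p),
    stringsAsFactors = FALSE
  )

  structure(list(
    results = results,
    total = total,
    by_band = if (length(bandres)) do.call(rbind, c(bandres, list(make.row.names = FALSE))) else NULL,
    groups = group_fits,
    config = list(index_year = as.integer(index_year),
                  interval_length = as.integer(interval_length),
                  horizon = as.integer(horizon),
                  max_age = as.integer(max_age),
                  projector = projector, decrement = decrement),
    inputs = list(population = population, mortality = mortality,
                  incidence = incidence, history = history, rr = rr),
    call = match.call()
  ), class = "fef")
}

validate_population <- function(population) {
  needed <- c("sex", "age_lower", "age_upper", "population", "prevalence_exposed")
  if (!is.data.frame(population) || !all(needed %in% names(population))) {
    fef_stop(paste("population must have columns",
                   paste(needed, collapse = ", ")), "fef_validation_error")
  }
  population <- as.data.frame(population)
  bad <- which(!is.finite(population$prevalence_exposed) |
                 population$prevalence_exposed < 0 |
                 population$prevalence_exposed > 1)
  if (length(bad)) {
    fef_stop(sprintf("prevalence_exposed out of [0, 1] at row %d (value %s)",
                     bad[1L], population$prevalence_exposed[bad[1L]]),
             "fef_validation_error")
  }
  bad <- which(!is.finite(population$population) | population$population < 0)
  if (length(bad)) {
    fef_stop(sprintf("negative or non-finite population at row %d", bad[1L]),
             "fef_validation_error")
  }
  for (g in unique(population$sex)) {
    p <- population[population$sex == g, ]
    p <- p[order(p$age_lower), ]
    if (any(p$age_upper < p$age_lower)) {
      fef_stop(sprintf("band with age_upper < age_lower for sex '%s'", g),
               "fef_validation_error")
    }
    if (nrow(p) > 1L) {
      overlap <- which(p$age_lower[-1L] <= p$age_upper[-nrow(p)])
      if (length(overlap)) {
        i <- overlap[1L]
        fef_stop(sprintf("overlapping age bands %s and %s for sex '%s'",
                         band_label(p$age_lower[i], p$age_upper[i]),
                         band_label(p$age_lower[i + 1L], p$age_upper[i + 1L]), g),
                 "fef_validation_error")
      }
      gap <- which(p$age_lower[-1L] != p$age_upper[-nrow(p)] + 1L)
      if (length(gap)) {
        i <- gap[1L]
        fef_stop(sprintf("age bands %s and %s are not contiguous for sex '%s'",
                         band_label(p$age_lower[i], p$age_upper[i]),
                         band_label(p$age_lower[i + 1L], p$age_upper[i + 1L]), g),
                 "fef_validation_error")
      }
    }
  }
  population
}
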