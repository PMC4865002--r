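#' Constant-rate projection
#'
#' Carries the index-year age-specific incidence rates unchanged into every
#' future estimation interval. This is the simplest defensible projector for
#' diseases without usable historical rate series: each interval's rate for a
#' given attained age equals the baseline rate at that age.
#'
#' @param baseline incidence schedule at the index year (columns `age`,
#'   `rate`), covering every attained age the PYAR grid can reach
#'   (youngest baseline age up to `max_age - 1`).
#' @param grid a `pyar_matrix` from [compute_pyar()].
#' @return a `projected_rates` object: matrix of rates per person-year with
#'   one row per attained age and one column per estimation interval.
#' @export
project_constant <- function(baseline, grid) {
  stopifnot(inherits(grid, "pyar_matrix"))
  baseline <- as_rate_schedule(baseline, "incidence")
  ages <- min(grid$baseline_ages):(grid$max_age - 1L)
  r <- schedule_rates(baseline, ages, "incidence")
  m <- matrix(r, nrow = length(ages), ncol = nrow(grid$intervals),
              dimnames = list(ages, paste0("interval_", grid$intervals$interval)))
  new_projected_rates(m, ages, grid, method = "constant",
                      schedule = baseline)
}

#' Log-linear drift projection
#'
#' Fits `log(rate) = alpha_band + beta * year` to a historical series of
#' banded incidence rates (band-specific intercepts, one shared annual drift
#' `beta`) by ordinary least squares, then evaluates the fit at the calendar
#' midpoint of each future estimation interval. Zero rates are replaced, for
#' fitting only, by half the smallest positive rate observed anywhere in the
#' series (a continuity offset for the log transform); a band whose rates
#' are all zero cannot be fitted and raises an error. Fewer than three
#' distinct years of history triggers a warning and a fall back to the
#' constant projector using the most recent year's rates.
#'
#' @param history data frame with columns `year`, `age_band` (labels like
#'   `"40-44"` or `"85+"`), `rate` and optionally `scale`. Bands must cover
#'   every attained age the PYAR grid can reach.
#' @param grid a `pyar_matrix`.
#' @param index_year calendar year of the baseline population (t = 0), used
#'   to convert interval offsets into calendar years.
#' @return a `projected_rates` object (rates floored at zero, although the
#'   exponential fit is positive by construction).
#' @export
project_loglinear <- function(history, grid, index_year) {
  stopifnot(inherits(grid, "pyar_matrix"))
  check_number(index_year, "index_year")
  if (!is.data.frame(history) ||
      !all(c("year", "age_band", "rate") %in% names(history))) {
    fef_stop("history must have columns year, age_band, rate",
             "fef_validation_error")
  }
  history <- as.data.frame(history)
  if ("scale" %in% names(history)) {
    history$rate <- history$rate / history$scale
    history$scale <- NULL
  }
  if (any(!is.finite(history$rate) | history$rate < 0)) {
    fef_stop("history rates must be finite and non-negative",
             "fef_validation_error")
  }
  if (anyDuplicated(history[c("year", "age_band")])) {
    fef_stop("duplicate (year, age_band) pair in history", "fef_validation_error")
  }

  ages <- min(grid$baseline_ages):(grid$max_age - 1L)
  bands <- unique(history$age_band)
  band_ranges <- vapply(bands, parse_band, numeric(2L))
  age_band <- rep(NA_character_, length(ages))
  for (b in seq_along(bands)) {
    inside <- ages >= band_ranges[1L, b] & ages <= band_ranges[2L, b]
    age_band[inside] <- bands[b]
  }
  if (anyNA(age_band)) {
    fef_stop(sprintf("history bands do not cover attained age %s",
                     ages[which(is.na(age_band))[1L]]), "fef_coverage_error")
  }

  years <- sort(unique(history$year))
  if (length(years) < 3L) {
    warning("fewer than 3 distinct years of history; falling back to the constant projector",
            call. = FALSE)
    last <- history[history$year == max(years), ]
    rate_of_band <- last$rate[match(age_band, last$age_band)]
    if (anyNA(rate_of_band)) {
      fef_stop("latest history year does not cover every band", "fef_coverage_error")
    }
    baseline <- data.frame(age = ages, rate = rate_of_band)
    return(project_constant(baseline, grid))
  }

  all_zero <- tapply(history$rate, history$age_band, function(r) all(r == 0))
  if (any(all_zero)) {
    fef_stop(sprintf("history for band %s is identically zero; cannot fit a log-linear drift",
                     names(all_zero)[all_zero][1L]), "fef_fit_error")
  }
  pos <- history$rate[history$rate > 0]
  offset <- min(pos) * 0.5
  y <- log(ifelse(history$rate > 0, history$rate, offset))
  fit <- stats::lm(y ~ 0 + factor(age_band, levels = bands) +
                     I(year - index_year), data = history)
  cf <- stats::coef(fit)
  drift <- cf[["I(year - index_year)"]]
  intercepts <- cf[seq_along(bands)]
  names(intercepts) <- bands

  mid_years <- index_year + grid$intervals$midpoint_offset
  m <- exp(outer(intercepts[age_band], drift * (mid_years - index_year), `+`))
  m <- pmax(m, 0)
  dimnames(m) <- list(ages, paste0("interval_", grid$intervals$interval))
  new_projected_rates(m, ages, grid, method = "loglinear",
                      intercepts = intercepts, drift = drift,
                      band_of_age = age_band, ref_year = index_year)
}

new_projected_rates <- function(m, ages, grid, method, ...) {
  structure(m, ages = ages, method = method,
            midpoint_offsets = grid$intervals$midpoint_offset,
            extra = list(...),
            class = c("projected_rates", "matrix", "array"))
}

# Evaluate the fitted projector at an exact calendar-year offset (used by the
# attributable-fraction comparator's single-year case count).
projected_rate_at <- function(rates, ages, year_offset, index_year) {
  extra <- attr(rates, "extra")
  if (attr(rates, "method") == "constant") {
    schedule_rates(extra$schedule, ages, "incidence")
  } else {
    band <- extra$band_of_age[match(ages, attr(rates, "ages"))]
    if (anyNA(band)) {
      fef_stop("projected rates do not cover the requested ages", "fef_coverage_error")
    }
    unname(exp(extra$intercepts[band] + extra$drift * year_offset))
  }
}
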