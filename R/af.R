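#' Levin's attributable fraction
#'
#' `AF = p(RR - 1) / (1 + p(RR - 1))` where `p` is the exposure prevalence.
#' This is the comparator method: the fraction of cases in a single year
#' attributable to exposure, computed from a point prevalence and a relative
#' risk. Strictly increasing in both arguments; `RR < 1` is rejected for
#' consistency with the excess-risk formula.
#'
#' @param prevalence exposure prevalence, in `[0, 1]` (vectorised).
#' @param rr relative risk, `>= 1` (vectorised).
#' @return the attributable fraction, in `[0, 1)`.
#' @export
levin_af <- function(prevalence, rr) {
  if (any(!is.finite(prevalence) | prevalence < 0 | prevalence > 1)) {
    fef_stop("prevalence must lie in [0, 1]", "fef_validation_error")
  }
  if (any(!is.finite(rr) | rr < 1)) {
    fef_stop(paste("relative risk below 1 is not supported: the",
                   "attributable-fraction comparison assumes RR >= 1"),
             "fef_rr_error")
  }
  prevalence * (rr - 1) / (1 + prevalence * (rr - 1))
}

#' Attributable number of cases
#'
#' The attributable fraction multiplied by the expected case count in the
#' target year.
#'
#' @param af attributable fraction, in `[0, 1]`.
#' @param cases_in_year expected case count in the target year.
#' @return the attributable number.
#' @export
attributable_number <- function(af, cases_in_year) {
  if (any(!is.finite(af) | af < 0 | af > 1)) {
    fef_stop("af must lie in [0, 1]", "fef_validation_error")
  }
  if (any(!is.finite(cases_in_year) | cases_in_year < 0)) {
    fef_stop("cases_in_year must be non-negative", "fef_validation_error")
  }
  af * cases_in_year
}

#' Attributable-fraction comparison for a fitted model
#'
#' Applies the comparator attributable-fraction method to a fitted future
#' excess fraction model: per sex, Levin's AF from the index-year point
#' prevalence and the model's relative risk, multiplied by the expected
#' number of cases occurring in a single target calendar year. The
#' single-year case count reuses the fitted person-years machinery restricted
#' to an interval of length one (the Lexis column for that year, with the
#' projector evaluated at the exact year).
#'
#' @param object a fitted `"fef"` object with a single-level (scalar) RR.
#' @param year target calendar year, within the fitted horizon.
#' @return a data frame of class `"fef_af"` with one row per sex: prevalence,
#'   RR, `af`, `cases_in_year`, `attributable_number`, and the model's `FEF`
#'   for side-by-side comparison.
#' @export
af_comparison <- function(object, year) {
  stopifnot(inherits(object, "fef"))
  check_number(year, "year")
  if (is.data.frame(object$inputs$rr)) {
    fef_stop("af_comparison supports a single exposure level", "fef_validation_error")
  }
  cfg <- object$config
  t <- as.integer(year) - cfg$index_year
  if (t < 0L || t >= cfg$horizon) {
    fef_stop(sprintf("year %d is outside the fitted horizon (%d-%d)",
                     year, cfg$index_year, cfg$index_year + cfg$horizon - 1L),
             "fef_coverage_error")
  }
  rows <- lapply(names(object$groups), function(g) {
    gf <- object$groups[[g]]
    pyar <- gf$pyar
    py_t <- pyar$detail[, t + 1L]
    x <- pyar$baseline_ages + t
    keep <- py_t > 0
    rate <- numeric(length(x))
    if (any(keep)) {
      rate[keep] <- projected_rate_at(gf$rates, x[keep], t, cfg$index_year)
    }
    cases_y <- sum(py_t * rate)
    prev <- gf$n_e / gf$n_p
    af <- levin_af(prev, gf$rr)
    data.frame(group = g, year = as.integer(year), prevalence = prev,
               rr = gf$rr, af = af, cases_in_year = cases_y,
               attributable_number = attributable_number(af, cases_y),
               FEF = object$results$FEF[object$results$group == g],
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("fef_af", "data.frame"))
}

#' @export
print.fef_af <- function(x, ...) {
  cat("Attributable-fraction comparison (single-year cases vs lifetime FEF)\n\n")
  y <- x
  y$af <- format_fraction(y$af)
  y$FEF <- format_fraction(y$FEF)
  y$cases_in_year <- format_count(y$cases_in_year)
  y$attributable_number <- format_count(y$attributable_number)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
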