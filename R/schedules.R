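#' Validate an age-specific rate schedule
#'
#' A schedule is a data frame with integer `age` (single years, strictly
#' increasing and contiguous) and non-negative `rate` per person-year. An
#' optional `scale` column (1 or 100000) declares the denominator of `rate`;
#' rates are normalised to per person-year. An optional `sex` column allows
#' one file to carry schedules for several groups (validated per group).
#'
#' @param x data frame with columns `age`, `rate` and optionally `scale`, `sex`.
#' @param what label used in error messages ("mortality", "incidence", ...).
#' @return the normalised schedule (rates per person-year, `scale` dropped).
#' @export
as_rate_schedule <- function(x, what = "rate") {
  if (!is.data.frame(x) || !all(c("age", "rate") %in% names(x))) {
    fef_stop(sprintf("%s schedule must be a data frame with columns age, rate", what),
             "fef_validation_error")
  }
  x <- as.data.frame(x)
  if ("scale" %in% names(x)) {
    bad <- which(!x$scale %in% c(1, 1e5))
    if (length(bad)) {
      fef_stop(sprintf("%s schedule: unsupported scale %s at row %d (use 1 or 100000)",
                       what, x$scale[bad[1L]], bad[1L]), "fef_validation_error")
    }
    x$rate <- x$rate / x$scale
    x$scale <- NULL
  }
  neg <- which(!is.finite(x$rate) | x$rate < 0)
  if (length(neg)) {
    fef_stop(sprintf("%s schedule: negative or non-finite rate at row %d (age %s)",
                     what, neg[1L], x$age[neg[1L]]), "fef_validation_error")
  }
  groups <- if ("sex" %in% names(x)) split(x, x$sex) else list(x)
  for (g in groups) {
    age <- g$age
    if (anyDuplicated(age) || any(age != round(age))) {
      fef_stop(sprintf("%s schedule: ages must be unique integers", what),
               "fef_validation_error")
    }
    age <- sort(age)
    if (length(age) > 1L && any(diff(age) != 1L)) {
      fef_stop(sprintf("%s schedule: ages must be contiguous single years", what),
               "fef_coverage_error")
    }
  }
  x
}

# Hazard lookup for a single-group schedule; errors if any age is uncovered.
schedule_rates <- function(schedule, ages, what = "rate") {
  idx <- match(ages, schedule$age)
  if (anyNA(idx)) {
    miss <- ages[is.na(idx)]
    fef_stop(sprintf("%s schedule does not cover age%s %s",
                     what, if (length(miss) > 1L) "s" else "",
                     paste(utils::head(miss, 5L), collapse = ", ")),
             "fef_coverage_error")
  }
  schedule$rate[idx]
}
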