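#' One-at-a-time sensitivity analysis
#'
#' Reruns a fitted future excess fraction model with one of its five primary
#' inputs multiplied by each of a set of factors, holding everything else
#' fixed, and tabulates the resulting `LR_p`, `LR_x`, `FEN` and `FEF`
#' alongside their relative changes from baseline.
#'
#' Perturbation semantics per parameter:
#' \describe{
#'   \item{`numbers_exposed`}{scales `prevalence_exposed` (so `N_e`), with
#'     `N_p` fixed and `N_u` adjusting.}
#'   \item{`population`}{scales the cohort denominators `N_p` (and `N_u`)
#'     used in the lifetime-risk and excess-risk steps while the number
#'     exposed and the projected case numbers stay at baseline — the
#'     "future population" input enters the model only through those
#'     denominators once expected cases are taken as data.}
#'   \item{`incidence`}{scales the projected future rates (and hence the
#'     expected cases linearly); the decrement table is untouched.}
#'   \item{`mortality`}{scales the all-cause mortality schedule and rebuilds
#'     the life tables and person-years.}
#'   \item{`rr`}{scales the relative risk (the result must stay `>= 1`).}
#' }
#'
#' @param object a fitted `"fef"` object with a scalar RR.
#' @param parameter one of `"numbers_exposed"`, `"population"`,
#'   `"incidence"`, `"mortality"`, `"rr"`.
#' @param multipliers positive factors; a baseline row (multiplier 1) is
#'   always included.
#' @return a data frame of class `"fef_sensitivity"`: one row per group and
#'   multiplier with the four outputs and `rel_*` columns (relative change
#'   from the multiplier-1 row).
#' @export
fef_sensitivity <- function(object,
                            parameter = c("numbers_exposed", "population",
                                          "incidence", "mortality", "rr"),
                            multipliers = c(0.5, 0.9, 1, 1.1, 2)) {
  stopifnot(inherits(object, "fef"))
  parameter <- match.arg(parameter)
  if (any(!is.finite(multipliers) | multipliers <= 0)) {
    fef_stop("multipliers must be positive", "fef_validation_error")
  }
  if (is.data.frame(object$inputs$rr)) {
    fef_stop("sensitivity analysis supports a single exposure level",
             "fef_validation_error")
  }
  multipliers <- sort(unique(c(1, multipliers)))
  rows <- lapply(multipliers, function(m) {
    r <- perturbed_results(object, parameter, m)
    cbind(parameter = parameter, multiplier = m, r)
  })
  out <- do.call(rbind, rows)
  base <- out[out$multiplier == 1, ]
  idx <- match(out$group, base$group)
  for (col in c("LR_p", "LR_x", "FEN", "FEF")) {
    out[[paste0("rel_", col)]] <-
      ifelse(base[[col]][idx] != 0, out[[col]] / base[[col]][idx] - 1, 0)
  }
  rownames(out) <- NULL
  structure(out, class = c("fef_sensitivity", "data.frame"))
}

# Rerun (or re-derive, for arithmetic-only perturbations) the pipeline with
# one input scaled; returns the group-level results columns.
perturbed_results <- function(object, parameter, m) {
  inp <- object$inputs
  cfg <- object$config
  refit <- function(population = inp$population, mortality = inp$mortality,
                    rr = inp$rr) {
    fef(population, mortality, inp$incidence, rr = rr,
        history = inp$history, projector = cfg$projector,
        decrement = cfg$decrement, index_year = cfg$index_year,
        interval_length = cfg$interval_length, horizon = cfg$horizon,
        max_age = cfg$max_age)$results
  }
  cols <- c("group", "LR_p", "LR_x", "FEN", "FEF")

  if (parameter == "numbers_exposed") {
    pop <- inp$population
    pop$prevalence_exposed <- pop$prevalence_exposed * m
    if (any(pop$prevalence_exposed > 1)) {
      fef_stop("multiplier drives an exposure prevalence above 1",
               "fef_validation_error")
    }
    return(refit(population = pop)[cols])
  }
  if (parameter == "mortality") {
    mort <- as_rate_schedule(inp$mortality, "mortality")
    mort$rate <- mort$rate * m
    return(refit(mortality = mort)[cols])
  }
  if (parameter == "rr") {
    return(refit(rr = inp$rr * m)[cols])
  }
  if (parameter == "incidence") {
    # scale projected rates; recompute cases and downstream steps per group
    rows <- lapply(names(object$groups), function(g) {
      gf <- object$groups[[g]]
      rates <- gf$rates
      rates[] <- unclass(rates) * m
      cases <- expected_cases(gf$pyar, rates)
      lr_p <- lifetime_risk(cases, gf$n_p)
      ler <- lifetime_excess_risk(lr_p, gf$n_p, gf$n_e, gf$rr)
      fen <- future_excess_number(ler$LR_x, gf$n_e)
      data.frame(group = g, LR_p = lr_p,
                 LR_x = if (gf$n_e > 0) fen / gf$n_e else 0,
                 FEN = fen,
                 FEF = future_excess_fraction(fen, cases$FN_p))
    })
    return(do.call(rbind, rows))
  }
  # population: scale cohort denominators, expected cases stay at baseline
  rows <- lapply(names(object$groups), function(g) {
    gf <- object$groups[[g]]
    n_p <- gf$n_p * m
    if (gf$n_e > n_p) {
      fef_stop("multiplier drives the population below the number exposed",
               "fef_validation_error")
    }
    fn_p <- gf$cases$FN_p
    lr_p <- lifetime_risk(fn_p, n_p)
    ler <- lifetime_excess_risk(min(lr_p, 1), n_p, gf$n_e, gf$rr)
    fen <- future_excess_number(ler$LR_x, gf$n_e)
    data.frame(group = g, LR_p = lr_p,
               LR_x = if (gf$n_e > 0) fen / gf$n_e else 0,
               FEN = fen,
               FEF = future_excess_fraction(fen, fn_p))
  })
  do.call(rbind, rows)
}

#' @export
print.fef_sensitivity <- function(x, ...) {
  cat(sprintf("One-at-a-time sensitivity: %s\n\n", x$parameter[1L]))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
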