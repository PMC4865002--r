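#' Expected disease cases per age band and estimation interval
#'
#' Multiplies person-years at risk by the projected age-specific rate in each
#' cell and sums. With a `projected_rates` object the multiplication runs on
#' the Lexis detail: the person-years a baseline-age-`a` cohort spends in
#' future year `t` meet the rate at attained age `a + t` in the interval
#' containing `t`, and the product is attributed to the baseline band. A
#' plain band-by-interval matrix of rates (conforming to `pyar$pyar`) is
#' also accepted, in which case cases are the elementwise product.
#'
#' @param pyar a `pyar_matrix` from [compute_pyar()].
#' @param rates a `projected_rates` object or a conforming numeric matrix of
#'   rates per person-year.
#' @return a `case_matrix`: list with `D` (band x interval expected cases),
#'   `FN_p` (grand total), `by_interval` and `by_band` margins.
#' @export
expected_cases <- function(pyar, rates) {
  stopifnot(inherits(pyar, "pyar_matrix"))
  if (inherits(rates, "projected_rates")) {
    ages_att <- attr(rates, "ages")
    if (ncol(rates) != nrow(pyar$intervals)) {
      fef_stop("projected rates and PYAR grid have different interval counts",
               "fef_grid_error")
    }
    detail <- pyar$detail
    Dd <- matrix(0, nrow(detail), ncol(detail))
    for (ti in seq_len(ncol(detail))) {
      x <- pyar$baseline_ages + (ti - 1L)
      idx <- match(x, ages_att)
      live <- detail[, ti] > 0
      if (any(live & is.na(idx))) {
        fef_stop(sprintf("projected rates do not cover attained age %s",
                         x[which(live & is.na(idx))[1L]]), "fef_coverage_error")
      }
      r <- ifelse(is.na(idx), 0, rates[idx, pyar$interval_of_t[ti]])
      Dd[, ti] <- detail[, ti] * r
    }
    labels <- pyar$age_bands$label
    D <- rowsum(Dd, group = labels[pyar$band_of_age], reorder = FALSE)
    D <- D[labels, , drop = FALSE]
    D <- t(rowsum(t(D), group = pyar$interval_of_t, reorder = FALSE))
    colnames(D) <- colnames(pyar$pyar)
  } else if (is.matrix(rates)) {
    if (!all(dim(rates) == dim(pyar$pyar))) {
      fef_stop("rate matrix does not conform to the PYAR grid", "fef_grid_error")
    }
    if (any(rates < 0)) {
      fef_stop("negative rate in rate matrix", "fef_validation_error")
    }
    D <- pyar$pyar * rates
  } else {
    fef_stop("rates must be a projected_rates object or a conforming matrix",
             "fef_grid_error")
  }
  structure(list(
    D = D,
    FN_p = sum(D),
    by_interval = colSums(D),
    by_band = rowSums(D),
    intervals = pyar$intervals
  ), class = "case_matrix")
}

#' Lifetime risk in the population
#'
#' The expected number of future cases over the cohort's lifetime divided by
#' the cohort size at the index year (the person-years model of lifetime
#' risk): `LR_p = FN_p / N_p(t=0)`.
#'
#' @param cases a `case_matrix` from [expected_cases()], or the total
#'   expected case count `FN_p` as a single number.
#' @param n_p_total baseline population count (must be positive).
#' @return the lifetime risk, a proportion.
#' @export
lifetime_risk <- function(cases, n_p_total) {
  fn_p <- if (inherits(cases, "case_matrix")) cases$FN_p else
    check_number(cases, "cases", min = 0)
  if (!is.numeric(n_p_total) || length(n_p_total) != 1L ||
      !is.finite(n_p_total) || n_p_total <= 0) {
    fef_stop("lifetime risk is undefined for a non-positive population count",
             "fef_undefined_error")
  }
  fn_p / n_p_total
}

#' Baseline and excess lifetime risk for the exposed
#'
#' Back-solves the baseline lifetime risk in the never-exposed, `LR_u`, from
#' the whole-population lifetime risk and the exposed/unexposed split, then
#' applies the excess-risk relation `LR_x = LR_u * (RR - 1)`:
#' \deqn{LR_u = \frac{LR_p N_p}{N_u + \sum_l N_{e,l} RR_l}, \qquad
#'       LR_{x,l} = LR_u (RR_l - 1).}
#' With a single exposure level this is the modified excess-risk equation
#' `LR_x = LR_p N_p (RR - 1) / (N_u + N_e RR)`. The relation assumes
#' `RR >= 1`; a protective exposure (RR < 1) is rejected because the
#' excess-risk formula only holds for RR greater than 1.0. Vectors `n_e`
#' and `rr` describe multiple exposure levels sharing one unexposed group.
#'
#' @param lr_p lifetime risk in the whole population.
#' @param n_p baseline population count.
#' @param n_e numbers exposed at the index year (scalar, or one per level).
#' @param rr relative risk(s) for the exposed versus never-exposed.
#' @return list with `LR_u` (scalar) and `LR_x` (one value per level).
#' @export
lifetime_excess_risk <- function(lr_p, n_p, n_e, rr) {
  check_number(lr_p, "lr_p", min = 0, max = 1)
  check_number(n_p, "n_p", min = 0)
  if (length(n_e) != length(rr)) {
    fef_stop("n_e and rr must have the same length (one per exposure level)",
             "fef_validation_error")
  }
  if (any(!is.finite(n_e) | n_e < 0)) {
    fef_stop("n_e must be non-negative", "fef_validation_error")
  }
  if (any(!is.finite(rr) | rr < 1)) {
    fef_stop(paste("relative risk below 1 is not supported: the excess-risk",
                   "equation only holds under the assumption that RR is",
                   "greater than 1.0"), "fef_rr_error")
  }
  if (sum(n_e) > n_p * (1 + 1e-9)) {
    fef_stop("numbers exposed exceed the population count", "fef_validation_error")
  }
  n_u <- n_p - sum(n_e)
  lr_u <- lr_p * n_p / (n_u + sum(n_e * rr))
  list(LR_u = lr_u, LR_x = lr_u * (rr - 1))
}

#' Future excess number of cases
#'
#' `FEN = sum_l LR_x,l * N_e,l`: the expected number of future cases among
#' those exposed at the index year that are due to that exposure.
#'
#' @param lr_x excess lifetime risk(s) per exposed person (one per level).
#' @param n_e numbers exposed (one per level).
#' @return the future excess number (a single expected count).
#' @export
future_excess_number <- function(lr_x, n_e) {
  if (length(lr_x) != length(n_e)) {
    fef_stop("lr_x and n_e must have the same length", "fef_validation_error")
  }
  if (any(!is.finite(lr_x) | lr_x < 0) || any(!is.finite(n_e) | n_e < 0)) {
    fef_stop("lr_x and n_e must be non-negative", "fef_validation_error")
  }
  sum(lr_x * n_e)
}

#' Future excess fraction
#'
#' `FEF = FEN / FN_p`: the fraction of all expected future cases in the
#' cohort that occur in the exposed subgroup because of their exposure
#' (equivalently `FEN / (LR_p * N_p)`).
#'
#' @param fen future excess number.
#' @param fn_p total expected future cases in the cohort (must be positive).
#' @return the future excess fraction, in `[0, 1)` for valid inputs.
#' @export
future_excess_fraction <- function(fen, fn_p) {
  check_number(fen, "fen", min = 0)
  if (!is.numeric(fn_p) || length(fn_p) != 1L || !is.finite(fn_p) || fn_p <= 0) {
    fef_stop("future excess fraction is undefined when no cases are expected",
             "fef_undefined_error")
  }
  fen / fn_p
}

#' Combine fractions for multiple exposures: product of complements
#'
#' For several exposures acting on one outcome, the combined fraction is
#' `1 - prod(1 - f_k)`. Order-independent, and never smaller than the
#' largest input.
#'
#' @param fractions numeric vector of fractions, each in `[0, 1]`.
#' @return the combined fraction.
#' @export
combine_fractions <- function(fractions) {
  if (length(fractions) == 0L) {
    fef_stop("at least one fraction is required", "fef_validation_error")
  }
  if (any(!is.finite(fractions) | fractions < 0 | fractions > 1)) {
    fef_stop("fractions must lie in [0, 1]", "fef_validation_error")
  }
  1 - prod(1 - fractions)
}
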