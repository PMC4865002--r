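# Display rounding policy (shared with write_report): fractions to 3
# decimals, risks to 2 significant figures in percent, counts to integers.
format_fraction <- function(x) formatC(round(x, 3), format = "f", digits = 3)
format_risk_pct <- function(x) paste0(formatC(signif(100 * x, 2),
                                              format = "fg"), "%")
format_count <- function(x) formatC(round(x), format = "d", big.mark = ",")

#' @export
print.fef <- function(x, ...) {
  cfg <- x$config
  cat("Future excess fraction model\n")
  cat(sprintf("  index year %d; horizon %d years (to %d); %d-year intervals\n",
              cfg$index_year, cfg$horizon, cfg$index_year + cfg$horizon - 1L,
              cfg$interval_length))
  cat(sprintf("  %s-decrement life table; %s rate projection; max age %d\n\n",
              cfg$decrement, cfg$projector, cfg$max_age))
  r <- x$results
  rows <- rbind(
    `Population (N_p)`                 = format_count(r$N_p),
    `Proportion exposed (index year)`  = formatC(r$prevalence, format = "g", digits = 3),
    `Number exposed (N_e)`             = format_count(r$N_e),
    `Lifetime risk (LR_p)`             = format_risk_pct(r$LR_p),
    `Expected lifetime cases (FN_p)`   = format_count(r$FN_p),
    `Lifetime excess risk (LR_x)`      = format_risk_pct(r$LR_x),
    `Future excess number (FEN)`       = format_count(r$FEN),
    `Future excess fraction (FEF)`     = format_fraction(r$FEF)
  )
  colnames(rows) <- r$group
  print(rows, quote = FALSE, right = TRUE)
  invisible(x)
}

#' Summarise a fitted future excess fraction model
#'
#' @param object a fitted `"fef"` object.
#' @param ... unused.
#' @return a `summary.fef` list with the group results, pooled totals and
#'   the per-band transparency table at full precision.
#' @export
summary.fef <- function(object, ...) {
  structure(list(results = object$results, total = object$total,
                 by_band = object$by_band, config = object$config),
            class = "summary.fef")
}

#' @export
print.summary.fef <- function(x, ...) {
  cat("Future excess fraction model — group results\n\n")
  print(rbind(x$results, x$total), digits = 4, row.names = FALSE)
  if (!is.null(x$by_band)) {
    cat("\nPer-band results (baseline bands; group-level FEN is computed from\npooled counts, so band FENs need not sum to it)\n\n")
    print(x$by_band, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.fef <- function(object, ...) {
  r <- object$results
  stats::setNames(r$FEF, paste0("FEF_", r$group))
}

#' Plot expected cases per estimation interval
#'
#' Draws the projected number of disease cases in each future estimation
#' interval, one line per sex, against the interval's calendar midpoint.
#'
#' @param x a fitted `"fef"` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fef <- function(x, ...) {
  groups <- names(x$groups)
  ival <- x$groups[[1L]]$pyar$intervals
  mid <- x$config$index_year + ival$midpoint_offset
  D <- sapply(x$groups, function(g) g$cases$by_interval)
  graphics::matplot(mid, D, type = "b", pch = 19, lty = 1,
                    xlab = "calendar year (interval midpoint)",
                    ylab = "expected disease cases per interval", ...)
  graphics::legend("topright", legend = groups, col = seq_along(groups),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}
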