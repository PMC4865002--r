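# Classed conditions so callers and tests can distinguish validation,
# coverage, grid and computation failures programmatically.
fef_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "fef_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    fef_stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                     name, min, max), "fef_validation_error")
  }
  x
}

band_label <- function(lower, upper) paste0(lower, "-", upper)

# "40-44" -> c(40, 44); "85+" -> c(85, Inf)
parse_band <- function(label) {
  label <- trimws(label)
  if (grepl("^[0-9]+\\+$", label)) {
    return(c(as.numeric(sub("\\+$", "", label)), Inf))
  }
  parts <- strsplit(label, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.numeric(parts)))) {
    fef_stop(sprintf("cannot parse age band label '%s' (expected 'lower-upper' or 'lower+')",
                     label), "fef_validation_error")
  }
  as.numeric(parts)
}

# Restrict a table with an optional `sex` column to one group.
filter_sex <- function(x, group) {
  if (is.null(x) || !("sex" %in% names(x))) return(x)
  out <- x[x$sex == group, setdiff(names(x), "sex"), drop = FALSE]
  if (nrow(out) == 0L) {
    fef_stop(sprintf("no rows for sex '%s' in input table", group),
             "fef_coverage_error")
  }
  rownames(out) <- NULL
  out
}
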