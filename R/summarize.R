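#' Species-level summary of per-strike results
#'
#' Aggregates a table of per-strike summaries (one row per strike,
#' chelicerae already averaged) into per-variable mean, sample (n-1)
#' standard deviation, min, max and n, weighting strikes equally
#' regardless of how many strikes each individual contributed. With a
#' single strike the SD is reported as 0 and flagged by `n = 1`.
#'
#' @param summaries Data frame of per-strike values; see
#'   [analyze_strike()]. Non-numeric and identifier columns are ignored.
#' @return Object of class `species_summary`: data frame with columns
#'   `variable, mean, sd, min, max, n`.
#' @export
summarize_strikes <- function(summaries) {
  if (is.null(summaries) || !nrow(summaries)) stop("no strikes to summarize")
  skip <- c("specimen_id", "strike_id", "exceeds_muscle_limit",
            "n_chelicerae", "edf")
  num <- vapply(summaries, is.numeric, logical(1))
  vars <- setdiff(names(summaries)[num], skip)
  rows <- lapply(vars, function(v) {
    x <- summaries[[v]]
    x <- x[is.finite(x)]
    if (!length(x)) return(NULL)
    data.frame(
      variable = v, mean = mean(x),
      sd = if (length(x) > 1L) stats::sd(x) else 0,
      min = min(x), max = max(x), n = length(x),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Render a species summary as report lines
#'
#' Formats each variable as `"mean +/- sd unit (min-max), n=N"` in the
#' style of a Results paragraph, and appends the muscle-power verdict when
#' a mass-specific power output row is present. Empty variables are
#' omitted with a warning.
#'
#' @param species A [summarize_strikes()] result.
#' @param units Optional named character vector mapping variable names to
#'   unit strings.
#' @param digits Significant digits for formatting (passed to [format()]).
#' @return Character vector of report lines (also of class
#'   `strike_report`, printed without quotes).
#' @export
report <- function(species, units = NULL, digits = 7) {
  stopifnot(inherits(species, "species_summary"))
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  lines <- character(0)
  for (i in seq_len(nrow(species))) {
    r <- species[i, ]
    if (!is.finite(r$mean)) {
      warning("variable '", r$variable, "' is empty; omitted from report")
      next
    }
    unit <- if (!is.null(units) && r$variable %in% names(units)) {
      paste0(" ", units[[r$variable]])
    } else ""
    lines <- c(lines, sprintf(
      "%s: %s ± %s%s (%s–%s), n=%d",
      r$variable, fmt(r$mean), fmt(r$sd), unit, fmt(r$min), fmt(r$max), r$n
    ))
  }
  o_row <- match("O_W_per_kg", species$variable)
  if (!is.na(o_row)) {
    verdict <- if (species$mean[o_row] > MUSCLE_POWER_LIMIT_W_KG) {
      "exceeds conventional muscle power (power amplification indicated)"
    } else {
      "does not exceed conventional muscle power"
    }
    lines <- c(lines, sprintf(
      "mass-specific power output %s W/kg vs %g W/kg muscle ceiling: %s",
      fmt(species$mean[o_row]), MUSCLE_POWER_LIMIT_W_KG, verdict
    ))
  }
  structure(lines, class = "strike_report")
}

#' @export
print.strike_report <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
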