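#' Format a proportion as a percentage string
#'
#' Percentages are reported to one decimal place using round-half-even,
#' the convention used throughout the package's rendered tables.
#' Non-finite or missing values render as an em dash.
#'
#' @param x Numeric vector of proportions in \[0, 1\] (or `NA`).
#' @param digits Decimal places on the percent scale.
#' @return Character vector.
#' @examples
#' fmt_pct(0.18154) # "18.2"
#' fmt_pct(NA)      # "—"
#' @export
fmt_pct <- function(x, digits = 1) {
  out <- ifelse(
    is.na(x) | !is.finite(x),
    "—",
    formatC(round(100 * x, digits), format = "f", digits = digits)
  )
  as.character(out)
}

# percentage point + CI, e.g. "54.4 (52.0-56.8)"
fmt_pct_ci <- function(est, lo, hi, digits = 1) {
  ifelse(
    is.na(est) | !is.finite(est),
    "—",
    paste0(
      fmt_pct(est, digits), " (",
      fmt_pct(lo, digits), "–", fmt_pct(hi, digits), ")"
    )
  )
}

abort_schema <- function(missing, where) {
  abort(
    sprintf(
      "Input to %s is missing required column(s): %s",
      where, paste(missing, collapse = ", ")
    ),
    class = "ctgperf_schema_error"
  )
}

check_columns <- function(data, cols, where) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) abort_schema(missing, where)
  invisible(data)
}

check_proportion <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) >= 1 && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) {
    bound <- if (open) "strictly inside (0, 1)" else "within [0, 1]"
    abort(sprintf("`%s` must be %s.", name, bound),
          class = "ctgperf_config_error")
  }
  invisible(x)
}
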