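#' @importFrom rlang %||% .data
#' @importFrom stats rnorm runif rpois rbinom rlnorm quantile var cov sd setNames
#' @importFrom utils head tail
NULL

# Canonical time origin for synthetic calendars
.ww_origin <- function() as.POSIXct("2011-01-01 00:00:00", tz = "UTC")

hours_between <- function(a, b) as.numeric(difftime(a, b, units = "hours"))

add_hours <- function(t, h) t + h * 3600

# synthetic timestamps are kept at whole-second resolution so that text
# serialisation round-trips exactly
round_time <- function(t) {
  as.POSIXct(round(as.numeric(t)), origin = "1970-01-01", tz = "UTC")
}

#' Assign an age in years to one of the matching age bins
#'
#' Bins follow the convention used for control matching: `<1`, `1-4`, `5-11`,
#' `12-17`, `>=18` years.
#'
#' @param age_years numeric vector of ages in years.
#' @return character vector of bin labels.
#' @export
age_bin <- function(age_years) {
  stopifnot(is.numeric(age_years))
  cut(age_years,
    breaks = c(-Inf, 1, 5, 12, 18, Inf),
    labels = c("<1", "1-4", "5-11", "12-17", ">=18"),
    right = FALSE
  ) |> as.character()
}

#' Age bin labels in increasing order
#' @return character vector of the five bin labels.
#' @export
age_bins <- function() c("<1", "1-4", "5-11", "12-17", ">=18")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stable order by (timestamp, arrival order); used everywhere "newest"/"2nd
# newest" matters so that duplicate timestamps resolve deterministically
stable_time_order <- function(t) order(t, seq_along(t))

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive number", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
    stop(sprintf("`%s` must be a nonnegative integer", name), call. = FALSE)
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
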