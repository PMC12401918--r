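# internal helpers shared across modules

# All timestamps are handled in UTC so that clock arithmetic is free of DST.
.tz <- "UTC"

#' @importFrom rlang abort warn `%||%`
NULL

# hour-of-day in [0, 24) for a POSIXct (UTC epoch is midnight-aligned)
hour_of_day <- function(t) {
  (as.numeric(t) %% 86400) / 3600
}

# noon-anchored night: a session starting after noon belongs to that calendar
# date, one starting before noon to the previous date (standard actigraphy
# convention so a night wrapping midnight keeps the evening's date)
noon_night <- function(t) {
  as.Date(as.POSIXct(as.numeric(t) - 12 * 3600, origin = "1970-01-01", tz = .tz))
}

# population (divide-by-n) standard deviation; fixed so thresholds are
# bit-stable across platforms
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Circular mean of clock times
#'
#' Mean direction of times-of-day on the 24 h circle, so that e.g. onsets at
#' 23.5 h and 0.5 h average to 0.0 h rather than the meaningless naive 12.0 h.
#'
#' @param hours numeric vector of clock times in hours, each in `[0, 24)`.
#' @return mean clock time in hours, in `[0, 24)`.
#' @seealso [circular_sd_hours()]
#' @export
circular_mean_hours <- function(hours) {
  stopifnot(is.numeric(hours), length(hours) >= 1)
  theta <- hours / 24 * 2 * pi
  m <- atan2(mean(sin(theta)), mean(cos(theta)))
  h <- (m / (2 * pi) * 24) %% 24
  if (24 - h < 1e-9) h <- 0 # float wrap: treat 24 - eps as midnight
  h
}

#' Circular dispersion of clock times
#'
#' Angular deviation `sqrt(2 * (1 - Rbar))` of times-of-day on the 24 h
#' circle, mapped back to hours. `Rbar` is the mean resultant length, so the
#' result is 0 for identical times and bounded (about 5.4 h for a uniform
#' scatter), never exploding for onsets that straddle midnight.
#'
#' @inheritParams circular_mean_hours
#' @return dispersion in hours, `>= 0`.
#' @export
circular_sd_hours <- function(hours) {
  stopifnot(is.numeric(hours), length(hours) >= 1)
  theta <- hours / 24 * 2 * pi
  rbar <- sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
  rbar <- min(rbar, 1) # guard tiny float excess
  sqrt(2 * (1 - rbar)) * 24 / (2 * pi)
}

# coerce a named numeric vector or a two-column data frame (activity, value)
# into a named numeric vector
as_activity_vector <- function(x, value_col = NULL, arg = "x") {
  if (is.data.frame(x)) {
    if (!"activity" %in% names(x)) {
      abort(sprintf("`%s` data frame must have an `activity` column.", arg))
    }
    cand <- value_col %||% setdiff(names(x), c("activity", "day", "night"))
    cand <- intersect(cand, names(x))
    cand <- cand[vapply(x[cand], is.numeric, logical(1))]
    if (length(cand) == 0) {
      abort(sprintf("`%s` has no numeric value column.", arg))
    }
    v <- stats::setNames(x[[cand[[1]]]], x$activity)
    return(v)
  }
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    abort(sprintf("`%s` must be a named numeric vector or a data frame with `activity` and a value column.", arg))
  }
  x
}

# parse "HH:MM" or numeric hours into numeric hours in [0, 24]
as_clock_hours <- function(x, arg = "window") {
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)
    x <- vapply(parts, function(p) {
      as.numeric(p[1]) + if (length(p) > 1) as.numeric(p[2]) / 60 else 0
    }, numeric(1))
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 24)) {
    abort(sprintf("`%s` clock times must lie in [0, 24].", arg))
  }
  x
}
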