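#' Aggregate labeled intervals into daily activity durations
#'
#' Sums interval durations per day and activity. Days with no intervals are
#' absent from the output; an interval crossing the day anchor was already
#' assigned wholly to its start day by [pair_activity_intervals()].
#'
#' @param intervals an interval tibble with `source_day`, `activity` and
#'   `duration_s` columns.
#' @return a long tibble with columns `day`, `activity`, `duration_s`.
#' @export
aggregate_daily_durations <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0) {
    return(tibble::tibble(day = as.Date(character()), activity = character(),
                          duration_s = numeric()))
  }
  intervals |>
    dplyr::group_by(day = .data$source_day, .data$activity) |>
    dplyr::summarise(duration_s = sum(.data$duration_s), .groups = "drop") |>
    dplyr::arrange(.data$day, .data$activity)
}

#' Normalize daily durations to proportions
#'
#' Adds the per-day proportion of labeled time spent on each activity,
#' \eqn{A_i = d_i / \sum_j d_j}. Unlabeled time never enters the
#' denominator: proportions are fractions of that day's total *labeled*
#' time and sum to 1 on every non-empty day. Days whose total labeled time
#' is zero are excluded and reported via the `"empty_days"` attribute.
#'
#' @param daily a tibble from [aggregate_daily_durations()].
#' @return the tibble with a `proportion` column added.
#' @export
normalize_proportions <- function(daily) {
  stopifnot(is.data.frame(daily), all(c("day", "activity", "duration_s") %in% names(daily)))
  if (any(daily$duration_s < 0)) abort("Durations must be non-negative.")
  totals <- daily |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(total = sum(.data$duration_s), .groups = "drop")
  empty <- totals$day[totals$total <= 0]
  if (length(empty) > 0) {
    warn(sprintf("%d day(s) with zero labeled time excluded from scoring: %s",
                 length(empty), paste(empty, collapse = ", ")))
  }
  out <- daily |>
    dplyr::inner_join(totals[totals$total > 0, , drop = FALSE], by = "day") |>
    dplyr::mutate(proportion = .data$duration_s / .data$total) |>
    dplyr::select(-"total")
  attr(out, "empty_days") <- empty
  out
}

#' Build daily activity profiles from intervals
#'
#' Convenience wrapper chaining [aggregate_daily_durations()] and
#' [normalize_proportions()].
#'
#' @inheritParams aggregate_daily_durations
#' @return a long tibble with `day`, `activity`, `duration_s`, `proportion`.
#' @export
daily_profiles <- function(intervals) {
  normalize_proportions(aggregate_daily_durations(intervals))
}

#' Build the reference activity routine
#'
#' The reference proportion of activity *i* is its mean daily duration over
#' the baseline days divided by the sum over activities of those mean
#' durations (pooled-duration normalization), so the reference proportions
#' always sum to exactly 1 and are comparable to any day's proportions.
#' Activities absent on a day contribute 0 seconds to that day's mean term.
#'
#' @param profiles a long tibble with `day`, `activity`, `duration_s`
#'   columns (proportions optional).
#' @param method `"pooled_mean"` (default, above) or `"mean_proportion"`,
#'   which instead averages each day's proportions; the two differ when
#'   total labeled time varies across days.
#' @param baseline_days optional: use only the first `baseline_days` days as
#'   an individual baseline instead of all available days (the mean
#'   routine).
#' @return a tibble with columns `activity`, `r` (reference proportions,
#'   summing to 1), of class `"reference_routine"`, with attributes
#'   `n_days` and `method`.
#' @examples
#' profiles <- tibble::tibble(
#'   day = rep(as.Date("2016-01-01") + 0:1, each = 2),
#'   activity = rep(c("A", "B"), 2),
#'   duration_s = c(2, 8, 4, 6) * 3600)
#' build_reference_routine(profiles) # A 0.3, B 0.7
#' @export
build_reference_routine <- function(profiles,
                                    method = c("pooled_mean", "mean_proportion"),
                                    baseline_days = NULL) {
  stopifnot(is.data.frame(profiles))
  method <- match.arg(method)
  if (nrow(profiles) == 0) abort("Cannot build a reference routine from zero days.")
  if (!is.null(baseline_days)) {
    keep <- sort(unique(profiles$day))[seq_len(min(baseline_days, dplyr::n_distinct(profiles$day)))]
    profiles <- profiles[profiles$day %in% keep, , drop = FALSE]
  }
  n_days <- dplyr::n_distinct(profiles$day)
  if (method == "pooled_mean") {
    means <- profiles |>
      dplyr::group_by(.data$activity) |>
      dplyr::summarise(mean_s = sum(.data$duration_s) / n_days, .groups = "drop")
    ref <- dplyr::mutate(means, r = .data$mean_s / sum(.data$mean_s)) |>
      dplyr::select("activity", "r")
  } else {
    if (!"proportion" %in% names(profiles)) {
      profiles <- normalize_proportions(profiles)
    }
    ref <- profiles |>
      dplyr::group_by(.data$activity) |>
      dplyr::summarise(r = sum(.data$proportion) / n_days, .groups = "drop")
    ref$r <- ref$r / sum(ref$r)
  }
  ref <- dplyr::arrange(ref, .data$activity)
  class(ref) <- c("reference_routine", class(ref))
  attr(ref, "n_days") <- n_days
  attr(ref, "method") <- method
  ref
}
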