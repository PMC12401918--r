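#' Overlap of activity- and sleep-flagged days
#'
#' Intersects the flagged date sets of two `drift_scores` tables (typically
#' [wadi_scores()] and [sdp_scores()] output) and reports each score's flag
#' fraction over its own covered days. Days flagged by both indices are the
#' strongest anomaly candidates.
#'
#' @param wadi_records,sdp_records `drift_scores` tibbles (any two flagging
#'   results over possibly different date ranges).
#' @return a list of class `overlap_report` with elements `wadi_flagged`,
#'   `sdp_flagged`, `overlap` (Date vectors) and `flag_fractions`.
#' @export
overlap_days <- function(wadi_records, sdp_records) {
  stopifnot(is.data.frame(wadi_records), is.data.frame(sdp_records))
  wf <- wadi_records$day[wadi_records$flagged]
  sf <- sdp_records$day[sdp_records$flagged]
  structure(list(
    wadi_flagged = sort(wf),
    sdp_flagged = sort(sf),
    overlap = sort(as.Date(intersect(wf, sf), origin = "1970-01-01")),
    flag_fractions = c(wadi = mean(wadi_records$flagged),
                       sdp = mean(sdp_records$flagged))
  ), class = "overlap_report")
}

#' Count night-time events per night
#'
#' Counts events whose start falls in a clock-time window (default
#' 22:00-06:00, half-open, wrapping midnight), attributed to the
#' noon-anchored night. Matches events by activity label when annotated,
#' otherwise by sensor id, so unannotated bathroom-area sensor firings can
#' be counted directly. Interval `end` markers are not counted, so a
#' begin/end-annotated occurrence counts once.
#'
#' @param events event tibble.
#' @param targets character vector of activity labels and/or sensor ids to
#'   count (e.g. bathroom motion sensors).
#' @param window length-2 clock window `c(start, end)`, hours or `"HH:MM"`
#'   strings; half-open `[start, end)`, may wrap midnight.
#' @return a tibble `night`, `n` covering every night in the event range
#'   (zero-count nights included).
#' @export
night_activity_count <- function(events, targets, window = c(22, 6)) {
  stopifnot(is.data.frame(events), length(targets) >= 1)
  w <- as_clock_hours(window)
  if (length(w) != 2 || w[1] == w[2]) {
    abort("`window` must be two distinct clock times (half-open, may wrap midnight).")
  }
  if (nrow(events) == 0) {
    return(tibble::tibble(night = as.Date(character()), n = integer()))
  }
  nights <- seq(min(noon_night(events$timestamp)),
                max(noon_night(events$timestamp)), by = 1)
  hit <- (ifelse(is.na(events$activity), events$sensor_id, events$activity) %in% targets |
            events$sensor_id %in% targets) &
    (is.na(events$marker) | events$marker == "begin")
  h <- hour_of_day(events$timestamp)
  in_win <- if (w[1] < w[2]) h >= w[1] & h < w[2] else h >= w[1] | h < w[2]
  counted <- events[hit & in_win, , drop = FALSE]
  counts <- tibble::tibble(night = noon_night(counted$timestamp)) |>
    dplyr::count(.data$night)
  tibble::tibble(night = nights) |>
    dplyr::left_join(counts, by = "night") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Long-duration night-time episodes of an activity
#'
#' Per night, sums the seconds an activity (e.g. stove-backed cooking)
#' spends inside the night window, flags nights whose total strictly
#' exceeds `min_seconds`, and, when sleep sessions are supplied, pairs each
#' night with its sleep duration and reports a Spearman rank correlation
#' between usage and sleep as a descriptive statistic (no causal claim).
#' Intervals are clipped to the window, so only in-window seconds count.
#'
#' @param intervals interval tibble.
#' @param activity the activity label to total.
#' @param window night window as in [night_activity_count()].
#' @param min_seconds flagging cutoff in seconds, `> 0`.
#' @param sleep_sessions optional [extract_sleep_sessions()] tibble for the
#'   usage-vs-sleep pairing.
#' @return a tibble `night`, `total_seconds`, `event_count`, `flagged`
#'   (plus `sleep_duration_s` when sessions are given), with attribute
#'   `spearman_rho` in that case.
#' @export
long_duration_episodes <- function(intervals, activity, window = c(22, 6),
                                   min_seconds, sleep_sessions = NULL) {
  stopifnot(is.data.frame(intervals), is.character(activity))
  if (!is.numeric(min_seconds) || min_seconds <= 0) abort("`min_seconds` must be > 0.")
  w <- as_clock_hours(window)
  if (length(w) != 2 || w[1] == w[2]) abort("`window` must be two distinct clock times.")
  iv <- intervals[intervals$activity == activity, , drop = FALSE]
  if (nrow(iv) == 0) {
    out <- tibble::tibble(night = as.Date(character()), total_seconds = numeric(),
                          event_count = integer(), flagged = logical())
    return(out)
  }
  # candidate nights: any night whose window could intersect the intervals
  nights <- seq(min(noon_night(iv$start)) - 1, max(noon_night(iv$end)) + 1, by = 1)
  per_night <- purrr::map_dfr(nights, function(nt) {
    # window [start, end) anchored to night nt (noon-to-noon day)
    day0 <- as.POSIXct(paste(nt, "00:00:00"), tz = .tz)
    win_start <- day0 + (if (w[1] >= 12) w[1] else w[1] + 24) * 3600
    win_end <- day0 + (if (w[2] >= 12) w[2] else w[2] + 24) * 3600
    ov <- pmin(as.numeric(iv$end), as.numeric(win_end)) -
      pmax(as.numeric(iv$start), as.numeric(win_start))
    ov <- pmax(ov, 0)
    tibble::tibble(night = nt, total_seconds = sum(ov),
                   event_count = sum(ov > 0))
  })
  per_night <- per_night[per_night$event_count > 0 | per_night$total_seconds > 0, , drop = FALSE]
  per_night$flagged <- per_night$total_seconds > min_seconds
  if (!is.null(sleep_sessions)) {
    per_night <- dplyr::left_join(
      per_night,
      dplyr::select(sleep_sessions, night = "night", sleep_duration_s = "duration_s"),
      by = "night")
    ok <- stats::complete.cases(per_night[, c("total_seconds", "sleep_duration_s")])
    if (sum(ok) >= 3 && stats::sd(per_night$total_seconds[ok]) > 0 &&
        stats::sd(per_night$sleep_duration_s[ok]) > 0) {
      attr(per_night, "spearman_rho") <- stats::cor(
        per_night$total_seconds[ok], per_night$sleep_duration_s[ok],
        method = "spearman")
    }
  }
  per_night
}
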