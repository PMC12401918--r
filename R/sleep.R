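#' Extract nightly sleep sessions from labeled intervals
#'
#' Sleep intervals are grouped into nights by a noon anchor (a session
#' wrapping midnight belongs to the evening's calendar date). Per night:
#' onset `O` is the clock time of the first sleep interval's start (hours),
#' duration `D` is the total sleep-labeled seconds, and the interruption
#' count `I` is either the number of `Bed_Toilet_Transition` occurrences
#' within the session span (default; the canonical ambient interruption
#' signal) or the number of inter-sleep gaps no longer than `max_gap_hours`.
#'
#' @param intervals interval tibble from [pair_activity_intervals()].
#' @param sleep_label activity label marking sleep (default `"Sleep"`).
#' @param interruption_label label counted as an interruption
#'   (default `"Bed_Toilet_Transition"`).
#' @param interruptions `"label"` (count `interruption_label` spans inside
#'   the session) or `"gaps"` (count inter-sleep gaps `<= max_gap_hours`).
#' @param max_gap_hours gap cap for `interruptions = "gaps"`.
#' @return a tibble with columns `night` (Date), `onset_hours`,
#'   `duration_s`, `interruptions`; nights in the covered range with no
#'   sleep label are listed in the `"missing_nights"` attribute.
#' @export
extract_sleep_sessions <- function(intervals,
                                   sleep_label = "Sleep",
                                   interruption_label = "Bed_Toilet_Transition",
                                   interruptions = c("label", "gaps"),
                                   max_gap_hours = 2) {
  stopifnot(is.data.frame(intervals))
  interruptions <- match.arg(interruptions)
  sl <- intervals[intervals$activity == sleep_label, , drop = FALSE]
  if (nrow(sl) == 0) {
    out <- tibble::tibble(night = as.Date(character()), onset_hours = numeric(),
                          duration_s = numeric(), interruptions = integer())
    attr(out, "missing_nights") <- sort(unique(noon_night(intervals$start)))
    return(out)
  }
  sl$night <- noon_night(sl$start)
  bt <- intervals[intervals$activity == interruption_label, , drop = FALSE]
  sessions <- sl |>
    dplyr::group_by(.data$night) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$start), , drop = FALSE]
      span <- c(min(as.numeric(d$start)), max(as.numeric(d$end)))
      n_int <- if (interruptions == "label") {
        sum(as.numeric(bt$start) >= span[1] & as.numeric(bt$start) <= span[2])
      } else {
        gaps <- as.numeric(d$start[-1]) - as.numeric(d$end[-nrow(d)])
        sum(gaps > 0 & gaps <= max_gap_hours * 3600)
      }
      tibble::tibble(onset_hours = hour_of_day(d$start[1]),
                     duration_s = sum(d$duration_s),
                     interruptions = as.integer(n_int))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$night)
  covered <- seq(min(noon_night(intervals$start)), max(noon_night(intervals$start)), by = 1)
  attr(sessions, "missing_nights") <- setdiff2_dates(covered, sessions$night)
  sessions
}

setdiff2_dates <- function(a, b) as.Date(setdiff(a, b), origin = "1970-01-01")

#' Build the sleep reference from a set of sessions
#'
#' The reference onset `R_O` is the circular mean of onsets on the 24 h
#' circle; the reference duration `R_D` is the mean duration; `sigma_O` is
#' the circular dispersion of onsets in hours; `sigma_D` the population
#' standard deviation of durations (seconds, same unit as `R_D`).
#'
#' @param sessions tibble from [extract_sleep_sessions()].
#' @return a list of class `sleep_reference` with elements `r_onset_hours`,
#'   `r_duration_s`, `sigma_onset_hours`, `sigma_duration_s`, `n_nights`.
#' @export
build_sleep_reference <- function(sessions) {
  stopifnot(is.data.frame(sessions))
  if (nrow(sessions) == 0) abort("Cannot build a sleep reference from zero nights.")
  structure(list(
    r_onset_hours = circular_mean_hours(sessions$onset_hours),
    r_duration_s = mean(sessions$duration_s),
    sigma_onset_hours = circular_sd_hours(sessions$onset_hours),
    sigma_duration_s = pop_sd(sessions$duration_s),
    n_nights = nrow(sessions)
  ), class = "sleep_reference")
}

#' Sleep onset deviation (hours)
#'
#' Circular distance on the 24 h clock between the observed and reference
#' onsets, `min(|O - R_O|, 24 - |O - R_O|)`; always in `[0, 12]` and
#' symmetric in its arguments.
#'
#' @param o,r_o clock times in hours, each in `[0, 24)`. Vectorized.
#' @export
compute_sod <- function(o, r_o) {
  if (any(o < 0 | o >= 24) || any(r_o < 0 | r_o >= 24)) {
    abort("Onset times must lie in [0, 24).")
  }
  d <- abs(o - r_o)
  pmin(d, 24 - d)
}

#' Sleep duration deviation (hours)
#'
#' `|D - R_D| / 3600` for durations in seconds.
#'
#' @param d,r_d durations in seconds, `> 0`. Vectorized.
#' @export
compute_sdd <- function(d, r_d) {
  if (any(d <= 0) || any(r_d <= 0)) abort("Durations must be positive.")
  abs(d - r_d) / 3600
}

#' Sleep interruption index (interruptions per hour)
#'
#' `I / D` with the sleep duration `D` in hours.
#'
#' @param i interruption counts, `>= 0`.
#' @param d_hours sleep duration in hours, `> 0`. Vectorized.
#' @export
compute_sii <- function(i, d_hours) {
  if (any(i < 0)) abort("Interruption counts must be non-negative.")
  if (any(d_hours <= 0)) abort("Sleep duration must be positive to define the interruption index.")
  i / d_hours
}

#' Sleep consistency index (unitless, in [0, 1])
#'
#' `max(0, 1 - sigma_O/24 - sigma_D/R_D)`: 1 for a perfectly regular
#' sleeper, shrinking as onset or duration variability grows, clamped at 0.
#' `sigma_D` and `R_D` must share a unit so their ratio is unit-free.
#'
#' @param sigma_o circular onset dispersion in hours, `>= 0`.
#' @param sigma_d duration dispersion, `>= 0`.
#' @param r_d reference duration, `> 0`, same unit as `sigma_d`.
#' @export
compute_sci <- function(sigma_o, sigma_d, r_d) {
  if (any(r_d <= 0)) abort("Reference duration must be positive.")
  if (any(sigma_o < 0) || any(sigma_d < 0)) abort("Dispersions must be non-negative.")
  pmax(0, 1 - sigma_o / 24 - sigma_d / r_d)
}

#' Sleep deviation weights
#'
#' Weights for the four sleep metrics in the aggregate score. Defaults are
#' equal (0.25 each); strict mode requires them to sum to 1.
#'
#' @param w1,w2,w3,w4 non-negative weights for onset deviation, duration
#'   deviation, interruption index and (1 - consistency).
#' @param strict enforce sum-to-one.
#' @return a named numeric vector of class `sdp_weights`.
#' @export
sdp_weights <- function(w1 = 0.25, w2 = 0.25, w3 = 0.25, w4 = 0.25,
                        strict = FALSE) {
  w <- c(w1 = w1, w2 = w2, w3 = w3, w4 = w4)
  if (any(w < 0)) abort("Sleep metric weights must be non-negative.")
  if (strict && abs(sum(w) - 1) > 1e-9) {
    abort(sprintf("Sleep metric weights sum to %.6g, not 1.", sum(w)))
  }
  structure(w, class = c("sdp_weights", "numeric"))
}

#' Aggregate sleep deviation score
#'
#' `SDP = w1*SOD + w2*SDD + w3*SII + w4*(1 - SCI)`; lower is better (0 for
#' a night matching the reference perfectly under full consistency). The
#' four terms are summed as printed even though their native units differ
#' (hours, hours, events/hour, unitless); see the methods vignette.
#'
#' @param sod,sdd,sii,sci component metrics (vectorized).
#' @param weights an [sdp_weights()] vector.
#' @export
compute_sdp <- function(sod, sdd, sii, sci, weights = sdp_weights()) {
  if (any(weights < 0)) abort("Sleep metric weights must be non-negative.")
  weights[["w1"]] * sod + weights[["w2"]] * sdd +
    weights[["w3"]] * sii + weights[["w4"]] * (1 - sci)
}

#' Score every night's sleep deviation and flag anomalies
#'
#' Computes per-night SOD, SDD, SII against the reference, the
#' reference-level SCI (a constant per reference, from its onset and
#' duration dispersions), aggregates them with [compute_sdp()], and flags
#' nights with [flag_days()]. Default fixed cutoff 0.4, the conventional
#' boundary between stable (`< 0.2`) and disrupted (`> 0.4`) sleepers.
#'
#' @param sessions tibble from [extract_sleep_sessions()].
#' @param reference a [build_sleep_reference()]; defaults to one built from
#'   `sessions`.
#' @param weights an [sdp_weights()] vector.
#' @param threshold a [threshold_config()].
#' @return a `drift_scores` tibble with columns `day` (the night), `sod`,
#'   `sdd`, `sii`, `sci`, `score`, `threshold`, `flagged`; attribute
#'   `index = "sdp"`.
#' @export
sdp_scores <- function(sessions, reference = NULL, weights = sdp_weights(),
                       threshold = threshold_config(value = 0.4)) {
  stopifnot(is.data.frame(sessions))
  if (nrow(sessions) == 0) abort("No sleep sessions to score.")
  if (is.null(reference)) reference <- build_sleep_reference(sessions)
  stopifnot(inherits(reference, "sleep_reference"))
  sod <- compute_sod(sessions$onset_hours, reference$r_onset_hours)
  sdd <- compute_sdd(sessions$duration_s, reference$r_duration_s)
  sii <- compute_sii(sessions$interruptions, sessions$duration_s / 3600)
  sci <- compute_sci(reference$sigma_onset_hours, reference$sigma_duration_s,
                     reference$r_duration_s)
  per_night <- tibble::tibble(day = sessions$night, sod = sod, sdd = sdd,
                              sii = sii, sci = sci,
                              score = compute_sdp(sod, sdd, sii, sci, weights))
  out <- flag_days(per_night[, c("day", "score")], threshold)
  out <- dplyr::bind_cols(per_night[, c("day", "sod", "sdd", "sii", "sci")],
                          out[, c("score", "threshold", "flagged")])
  class(out) <- c("drift_scores", class(out))
  attr(out, "flag_fraction") <- mean(out$flagged)
  attr(out, "config") <- threshold
  attr(out, "index") <- "sdp"
  attr(out, "reference") <- reference
  out
}

#' @rdname sdp_scores
#' @param scores a data frame with `night` (or `day`) and `score` columns.
#' @param config a [threshold_config()].
#' @export
flag_sleep_days <- function(scores, config = threshold_config(value = 0.4)) {
  out <- flag_days(scores, config)
  attr(out, "index") <- "sdp"
  out
}
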