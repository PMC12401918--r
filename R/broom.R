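#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a reference routine
#'
#' @param x a [build_reference_routine()] result.
#' @param ... unused.
#' @return a tibble `activity`, `r`.
#' @method tidy reference_routine
#' @export
tidy.reference_routine <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("activity", "r")])
}

#' @rdname tidy.reference_routine
#' @method glance reference_routine
#' @export
glance.reference_routine <- function(x, ...) {
  tibble::tibble(n_days = attr(x, "n_days"),
                 n_activities = nrow(x),
                 method = attr(x, "method"))
}

#' Tidy a sleep reference
#'
#' @param x a [build_sleep_reference()] result.
#' @param ... unused.
#' @return a one-row tibble of the reference statistics.
#' @method tidy sleep_reference
#' @export
tidy.sleep_reference <- function(x, ...) {
  tibble::tibble(r_onset_hours = x$r_onset_hours,
                 r_duration_s = x$r_duration_s,
                 sigma_onset_hours = x$sigma_onset_hours,
                 sigma_duration_s = x$sigma_duration_s,
                 n_nights = x$n_nights)
}

#' Tidy or summarise flagged day scores
#'
#' @param x a `drift_scores` tibble ([wadi_scores()], [sdp_scores()],
#'   [flag_days()]).
#' @param ... unused.
#' @return `tidy()`: the underlying tibble; `glance()`: a one-row summary
#'   with the day count, flag count and fraction, and score moments.
#' @method tidy drift_scores
#' @export
tidy.drift_scores <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.drift_scores
#' @method glance drift_scores
#' @export
glance.drift_scores <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(index = attr(x, "index") %||% NA_character_,
                 n_days = nrow(x),
                 n_flagged = sum(x$flagged),
                 flag_fraction = mean(x$flagged),
                 mean_score = mean(x$score),
                 max_score = max(x$score),
                 threshold_mode = if (is.null(cfg)) NA_character_ else cfg$mode)
}

#' Tidy a flag-overlap report
#'
#' @param x an [overlap_days()] result.
#' @param ... unused.
#' @return `tidy()`: one row per flagged date with the set(s) that flagged
#'   it; `glance()`: counts and flag fractions.
#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) {
  days <- sort(unique(c(x$wadi_flagged, x$sdp_flagged)))
  tibble::tibble(day = days,
                 wadi_flagged = days %in% x$wadi_flagged,
                 sdp_flagged = days %in% x$sdp_flagged,
                 overlap = days %in% x$overlap)
}

#' @rdname tidy.overlap_report
#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(n_wadi_flagged = length(x$wadi_flagged),
                 n_sdp_flagged = length(x$sdp_flagged),
                 n_overlap = length(x$overlap),
                 wadi_flag_fraction = x$flag_fractions[["wadi"]],
                 sdp_flag_fraction = x$flag_fractions[["sdp"]])
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> wadi: %d flagged (%.1f%%); sdp: %d flagged (%.1f%%); overlap: %d day(s)\n",
              length(x$wadi_flagged), 100 * x$flag_fractions[["wadi"]],
              length(x$sdp_flagged), 100 * x$flag_fractions[["sdp"]],
              length(x$overlap)))
  invisible(x)
}

#' @export
print.sleep_reference <- function(x, ...) {
  cat(sprintf("<sleep_reference> onset %.2f h (sigma %.2f h); duration %.0f s (sigma %.0f s); %d night(s)\n",
              x$r_onset_hours, x$sigma_onset_hours,
              x$r_duration_s, x$sigma_duration_s, x$n_nights))
  invisible(x)
}
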