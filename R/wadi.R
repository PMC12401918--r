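#' Weighted activity deviation index for one day
#'
#' The index is the weighted sum of absolute deviations between a day's
#' activity proportions and the reference routine,
#' \deqn{\mathrm{WADI} = \sum_i w_i \, |A_i - R_i|,}
#' evaluated over the union of the day's and the reference's activities
#' (absent entries count as 0, so a dropped activity is still penalized).
#' Zero means the day matches the reference exactly on every weighted
#' activity; absolute deviations penalize under- and over-performance
#' equally, so the index is symmetric in `day` and `reference`.
#'
#' @param day daily proportions \eqn{A_i}: a named numeric vector or a data
#'   frame with `activity` and `proportion` columns (one day).
#' @param reference reference proportions \eqn{R_i}: a named numeric vector
#'   or a [build_reference_routine()] result.
#' @param weights per-activity weights \eqn{w_i \ge 0}: named numeric vector
#'   or data frame with `activity` and `weight` columns. Activities in the
#'   union with no weight get weight 0, with a warning.
#' @return a single non-negative number.
#' @examples
#' compute_wadi(
#'   day       = c(Sleep = 0.25, Personal_Hygiene = 0.12, Cook_Breakfast = 0.10),
#'   reference = c(Sleep = 0.30, Personal_Hygiene = 0.10, Cook_Breakfast = 0.05),
#'   weights   = c(Sleep = 0.25, Personal_Hygiene = 0.10, Cook_Breakfast = 0.08))
#' # 0.0185
#' @export
compute_wadi <- function(day, reference, weights) {
  a <- as_activity_vector(day, c("proportion", "a"), "day")
  r <- as_activity_vector(reference, c("r", "proportion"), "reference")
  w <- as_activity_vector(weights, c("weight", "w"), "weights")
  if (any(w < 0)) abort("Weights must be non-negative.")
  acts <- union(names(a), names(r))
  missing_w <- setdiff(acts, names(w))
  if (length(missing_w) > 0) {
    warn(sprintf("No weight for activities: %s; using 0.",
                 paste(missing_w, collapse = ", ")))
  }
  av <- ifelse(acts %in% names(a), a[acts], 0)
  rv <- ifelse(acts %in% names(r), r[acts], 0)
  wv <- ifelse(acts %in% names(w), w[acts], 0)
  sum(wv * abs(av - rv))
}

#' Validate an activity weight scheme
#'
#' Negative weights are an error in both modes. In strict mode the weights
#' must sum to 1 (within 1e-9); in lax mode a deviating sum only produces a
#' warning, which permits partially specified importance weights (weights
#' covering a subset of activities, the rest implicitly 0).
#'
#' @param weights named numeric vector or data frame of weights.
#' @param strict logical; enforce the sum-to-one constraint.
#' @return invisibly, a list with `ok`, `total` and `messages`.
#' @export
validate_weights <- function(weights, strict = TRUE) {
  w <- as_activity_vector(weights, c("weight", "w"), "weights")
  if (any(w < 0)) abort("Weights must be non-negative.")
  total <- sum(w)
  ok <- abs(total - 1) <= 1e-9
  msgs <- character()
  if (!ok) {
    msg <- sprintf("Weights sum to %.6g, not 1.", total)
    msgs <- msg
    if (strict) abort(msg) else warn(msg)
  }
  invisible(list(ok = ok, total = total, messages = msgs))
}

#' Threshold configuration for day flagging
#'
#' @param mode `"fixed"` or `"dynamic"`. Fixed compares scores to
#'   `value`; dynamic compares to `mean + alpha * sd` of the score history
#'   (population standard deviation).
#' @param value fixed cutoff in score units; the default 0.02 is the
#'   conventional fixed cutoff for activity deviation scores.
#' @param alpha non-negative scaling factor for the dynamic threshold;
#'   larger values flag fewer days (more conservative). Default 2.
#' @param window optional integer: compute the dynamic threshold from a
#'   trailing window of the most recent `window` scores *before* each day
#'   (rolling mode) instead of the whole history (global mode, the
#'   default). With fewer than 2 prior scores a rolling day is left
#'   unflagged.
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(mode = c("fixed", "dynamic"), value = 0.02,
                             alpha = 2, window = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (!is.numeric(value) || value < 0)) {
    abort("Fixed mode requires `value` >= 0.")
  }
  if (!is.numeric(alpha) || alpha < 0) abort("`alpha` must be >= 0.")
  structure(list(mode = mode, value = value, alpha = alpha, window = window),
            class = "threshold_config")
}

#' Dynamic anomaly threshold from a score history
#'
#' `mean(scores) + alpha * sd(scores)` with the population (divide-by-n)
#' standard deviation. `alpha` scales how conservative flagging is: the
#' flagged set under a larger `alpha` is always a subset of the flagged set
#' under a smaller one.
#'
#' @param scores numeric vector of at least 2 scores.
#' @param alpha non-negative scaling factor.
#' @return the threshold value.
#' @examples
#' dynamic_threshold(c(0.01, 0.02, 0.03), alpha = 1) # 0.02 + 0.008165
#' @export
dynamic_threshold <- function(scores, alpha) {
  if (!is.numeric(scores) || length(scores) < 2) {
    abort("Dynamic thresholding needs at least 2 scores; use a fixed threshold instead.")
  }
  if (!is.numeric(alpha) || alpha < 0) abort("`alpha` must be >= 0.")
  mean(scores) + alpha * pop_sd(scores)
}

#' Flag anomalous days from per-day scores
#'
#' A day is flagged iff its score *strictly* exceeds the threshold (ties are
#' not flagged). Every input day yields one record.
#'
#' @param scores a data frame with a `day` (or `night`) column and a `score`
#'   column.
#' @param config a [threshold_config()].
#' @return a tibble of class `drift_scores` with columns `day`, `score`,
#'   `threshold`, `flagged`, and a `flag_fraction` attribute.
#' @export
flag_days <- function(scores, config = threshold_config()) {
  stopifnot(is.data.frame(scores), inherits(config, "threshold_config"))
  if (nrow(scores) == 0) abort("`scores` must be non-empty.")
  day_col <- intersect(c("day", "night"), names(scores))[1]
  if (is.na(day_col) || !"score" %in% names(scores)) {
    abort("`scores` needs a `day` (or `night`) column and a `score` column.")
  }
  s <- scores$score
  if (any(s < 0, na.rm = TRUE)) abort("Scores must be non-negative.")
  thr <- if (config$mode == "fixed") {
    rep(config$value, length(s))
  } else if (is.null(config$window)) {
    rep(dynamic_threshold(s, config$alpha), length(s))
  } else {
    vapply(seq_along(s), function(i) {
      h <- s[seq_len(i - 1)]
      h <- utils::tail(h, config$window)
      if (length(h) < 2) Inf else dynamic_threshold(h, config$alpha)
    }, numeric(1))
  }
  out <- tibble::tibble(day = scores[[day_col]], score = s,
                        threshold = thr, flagged = s > thr)
  class(out) <- c("drift_scores", class(out))
  attr(out, "flag_fraction") <- mean(out$flagged)
  attr(out, "config") <- config
  out
}

#' Score every day's activity deviation and flag anomalies
#'
#' Pipeline verb: computes the weighted activity deviation index for each
#' day in `profiles` against `reference`, then flags days with
#' [flag_days()].
#'
#' @param profiles long tibble from [daily_profiles()].
#' @param reference a [build_reference_routine()] result; defaults to the
#'   mean routine over all days in `profiles`.
#' @param weights per-activity weights; defaults to equal weights `1/n` over
#'   the reference activities (a neutral scheme when no importance ranking
#'   is supplied).
#' @param threshold a [threshold_config()].
#' @return a `drift_scores` tibble (`day`, `score`, `threshold`, `flagged`)
#'   with attribute `index = "wadi"`.
#' @export
wadi_scores <- function(profiles, reference = NULL, weights = NULL,
                        threshold = threshold_config()) {
  stopifnot(is.data.frame(profiles))
  if (!"proportion" %in% names(profiles)) profiles <- normalize_proportions(profiles)
  if (is.null(reference)) reference <- build_reference_routine(profiles)
  r <- as_activity_vector(reference, c("r", "proportion"), "reference")
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(r), length(r)), names(r))
  }
  per_day <- profiles |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(function(d, key) {
      a <- stats::setNames(d$proportion, d$activity)
      tibble::tibble(score = compute_wadi(a, r, weights))
    }) |>
    dplyr::ungroup()
  out <- flag_days(per_day, threshold)
  attr(out, "index") <- "wadi"
  out
}
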