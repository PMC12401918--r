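#' Specify a synthetic daily routine
#'
#' Parameters of the generative model behind [simulate_days()]: a fixed
#' menu of daytime activities with log-normally distributed durations, a
#' nightly sleep session with wrapped-normal onset and normal (truncated
#' positive) total duration, and a Poisson-distributed number of night-time
#' interruptions realized as `Bed_Toilet_Transition` spans inside wake gaps.
#' Defaults describe a regular older adult: lights-out around 22:30 with
#' half-hour onset jitter, about 8 h of sleep, roughly one bathroom
#' transition per night, and modest (20% cv) day-to-day variation in the
#' activity time budget.
#'
#' @param activity_means named vector of mean daily seconds per daytime
#'   activity.
#' @param activity_cv coefficient of variation of daily activity durations
#'   (single value or per-activity named vector); 0 gives identical days.
#' @param onset_mean,onset_sd sleep onset mean clock time and jitter, hours
#'   (onset is wrapped onto the 24 h circle).
#' @param duration_mean,duration_sd total nightly sleep seconds (truncated
#'   at 10 min).
#' @param interruption_rate expected interruptions per night (Poisson).
#' @param seed optional default seed used by [simulate_days()].
#' @return a `routine_spec` list.
#' @export
routine_spec <- function(activity_means = c(Cook_Breakfast = 1800,
                                            Eat = 3600,
                                            Personal_Hygiene = 1800,
                                            Work = 14400,
                                            Relax = 7200),
                         activity_cv = 0.2,
                         onset_mean = 22.5, onset_sd = 0.5,
                         duration_mean = 28800, duration_sd = 2700,
                         interruption_rate = 1,
                         seed = NULL) {
  if (length(activity_means) < 1 || any(activity_means <= 0) ||
      is.null(names(activity_means))) {
    abort("`activity_means` must be a named vector of positive mean seconds.")
  }
  if (any(activity_cv < 0) || onset_sd < 0 || duration_sd < 0 ||
      interruption_rate < 0) {
    abort("Variability parameters must be non-negative.")
  }
  if (duration_mean <= 0) abort("`duration_mean` must be positive.")
  if (onset_mean < 0 || onset_mean >= 24) abort("`onset_mean` must lie in [0, 24).")
  cv <- if (length(activity_cv) == 1) {
    stats::setNames(rep(activity_cv, length(activity_means)), names(activity_means))
  } else activity_cv[names(activity_means)]
  structure(list(activity_means = activity_means, activity_cv = cv,
                 onset_mean = onset_mean, onset_sd = onset_sd,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 interruption_rate = interruption_rate, seed = seed),
            class = "routine_spec")
}

# deterministic sensor id per activity label (stable across runs)
sensor_map <- function(activities) {
  acts <- sort(unique(activities))
  stats::setNames(sprintf("M%03d", seq_along(acts)), acts)
}

# build the truth rows for one night: sleep segments plus interruption spans.
# `onset_instant` is a POSIXct; total_s is total *sleep* seconds; each
# interruption inserts a 600 s wake gap (Bed_Toilet_Transition spanning its
# middle 360 s) that extends the session without reducing sleep time.
build_night <- function(day, onset_instant, total_s, n_interruptions) {
  n_seg <- n_interruptions + 1
  seg <- rep(total_s / n_seg, n_seg)
  rows <- vector("list", n_seg * 2 - 1)
  cur <- as.numeric(onset_instant)
  for (k in seq_len(n_seg)) {
    rows[[2 * k - 1]] <- tibble::tibble(
      day = day, block = "sleep", activity = "Sleep",
      start = cur, end = cur + seg[k])
    cur <- cur + seg[k]
    if (k < n_seg) {
      rows[[2 * k]] <- tibble::tibble(
        day = day, block = "sleep", activity = "Bed_Toilet_Transition",
        start = cur + 120, end = cur + 480)
      cur <- cur + 600
    }
  }
  dplyr::bind_rows(rows)
}

# daytime schedule: activities back to back from 08:00 with 10 min gaps
build_daytime <- function(day, durations) {
  cur <- as.numeric(as.POSIXct(paste(day, "08:00:00"), tz = .tz))
  rows <- purrr::imap(durations, function(d, a) {
    r <- tibble::tibble(day = day, block = "daytime", activity = a,
                        start = cur, end = cur + d)
    cur <<- cur + d + 600
    r
  })
  dplyr::bind_rows(rows)
}

#' Simulate an annotated smart-home event stream
#'
#' Draws `n_days` days from a [routine_spec()]: daytime activities with
#' log-normal durations scheduled back to back from 08:00, then a nightly
#' sleep session whose onset is wrapped-normal on the 24 h circle (an onset
#' before noon places the session after midnight, so the noon anchor keeps
#' it on the evening's date), with Poisson interruptions. The ground-truth
#' interval table is rendered deterministically into begin/end-annotated
#' sensor events, so the same spec and seed give byte-identical streams.
#'
#' @param spec a [routine_spec()].
#' @param n_days number of days, `>= 0`.
#' @param start_date first calendar date.
#' @param seed integer seed; defaults to `spec$seed`. `NULL` leaves the RNG
#'   state alone.
#' @return an object of class `sim_home`: a list with `events` (event
#'   tibble as from [read_event_log()]), `truth` (tibble `day`, `block`,
#'   `activity`, `start`, `end`), `anomalies` (empty tibble until
#'   [inject_anomalies()]), and `spec`.
#' @export
simulate_days <- function(spec, n_days, start_date = as.Date("2016-01-01"),
                          seed = spec$seed) {
  stopifnot(inherits(spec, "routine_spec"))
  if (!is.numeric(n_days) || n_days < 0) abort("`n_days` must be >= 0.")
  if (!is.null(seed)) set.seed(seed)
  days <- if (n_days > 0) start_date + seq_len(n_days) - 1 else as.Date(character())
  truth <- purrr::map_dfr(days, function(d) {
    # daytime durations: log-normal with the spec's mean and cv (cv 0 => constant)
    m <- spec$activity_means
    cv <- spec$activity_cv
    dur <- vapply(names(m), function(a) {
      if (cv[[a]] == 0) return(m[[a]])
      sdlog <- sqrt(log(1 + cv[[a]]^2))
      meanlog <- log(m[[a]]) - sdlog^2 / 2
      stats::rlnorm(1, meanlog, sdlog)
    }, numeric(1))
    day_rows <- build_daytime(d, dur)
    # sleep: wrapped-normal onset; onset < 12 means after midnight (next date)
    o <- (stats::rnorm(1, spec$onset_mean, spec$onset_sd)) %% 24
    onset_date <- if (o >= 12) d else d + 1
    onset_instant <- as.POSIXct(paste(onset_date, "00:00:00"), tz = .tz) + o * 3600
    total_s <- max(600, stats::rnorm(1, spec$duration_mean, spec$duration_sd))
    n_int <- stats::rpois(1, spec$interruption_rate)
    dplyr::bind_rows(day_rows, build_night(d, onset_instant, total_s, n_int))
  })
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(day = as.Date(character()), block = character(),
                            activity = character(), start = numeric(), end = numeric())
  }
  new_sim_home(truth, spec)
}

new_sim_home <- function(truth, spec, anomalies = NULL) {
  anomalies <- anomalies %||% tibble::tibble(day = as.Date(character()),
                                             type = character(),
                                             magnitude = numeric())
  structure(list(events = render_events(truth), truth = truth,
                 anomalies = anomalies, spec = spec),
            class = "sim_home")
}

# deterministic rendering: truth intervals -> begin/end sensor events
render_events <- function(truth) {
  if (nrow(truth) == 0) {
    return(tibble::tibble(timestamp = as.POSIXct(character(), tz = .tz),
                          sensor_id = character(), status = character(),
                          activity = character(), marker = character()))
  }
  sensors <- sensor_map(truth$activity)
  ev <- dplyr::bind_rows(
    tibble::tibble(timestamp = truth$start, sensor_id = sensors[truth$activity],
                   status = "ON", activity = truth$activity, marker = "begin"),
    tibble::tibble(timestamp = truth$end, sensor_id = sensors[truth$activity],
                   status = "OFF", activity = truth$activity, marker = "end"))
  ev$timestamp <- as.POSIXct(ev$timestamp, origin = "1970-01-01", tz = .tz)
  ev <- ev[order(ev$timestamp, ev$marker == "begin"), , drop = FALSE]
  # ties: emit 'end' before 'begin' so back-to-back spans pair cleanly
  tibble::as_tibble(ev)
}

#' Plan anomalies to inject into a simulated stream
#'
#' @param day Date vector of days to perturb.
#' @param type one of `"onset_shift"` (shift the night's sleep block by
#'   `magnitude` hours), `"short_sleep"` (remove `magnitude` seconds of
#'   sleep from the end of the night), `"fragmentation"` (rebuild the night
#'   with `magnitude` interruptions), `"routine_swap"` (cyclically permute
#'   the day's activity durations; magnitude ignored), `"night_appliance"`
#'   (insert a `magnitude`-second cooking episode at 02:00).
#' @param magnitude per-day magnitude (hours, seconds or a count, by type).
#' @return a tibble of class `anomaly_plan`.
#' @export
anomaly_plan <- function(day, type, magnitude = 0) {
  types <- c("onset_shift", "short_sleep", "fragmentation", "routine_swap",
             "night_appliance")
  bad <- setdiff(unique(type), types)
  if (length(bad) > 0) {
    abort(sprintf("Unknown anomaly type(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(magnitude < 0)) abort("Anomaly magnitudes must be >= 0.")
  out <- tibble::tibble(day = as.Date(day), type = type, magnitude = magnitude)
  class(out) <- c("anomaly_plan", class(out))
  out
}

#' Inject planned anomalies into a simulated stream
#'
#' Perturbs the ground-truth intervals of the listed days and re-renders
#' the event stream; all other days are untouched (the rendering is a pure
#' function of the truth table, so their event lines are byte-identical).
#' The realized plan is stored in `$anomalies` as ground truth for
#' recovery experiments.
#'
#' @param sim a `sim_home` from [simulate_days()].
#' @param plan an [anomaly_plan()].
#' @return a perturbed `sim_home`.
#' @export
inject_anomalies <- function(sim, plan) {
  stopifnot(inherits(sim, "sim_home"))
  if (!inherits(plan, "anomaly_plan")) {
    plan <- anomaly_plan(plan$day, plan$type, plan$magnitude)
  }
  truth <- sim$truth
  missing <- setdiff(plan$day, truth$day)
  if (length(missing) > 0) {
    abort(sprintf("Plan refers to day(s) not in the stream: %s",
                  paste(as.Date(missing, origin = "1970-01-01"), collapse = ", ")))
  }
  for (i in seq_len(nrow(plan))) {
    d <- plan$day[i]
    mag <- plan$magnitude[i]
    night <- truth$day == d & truth$block == "sleep"
    if (plan$type[i] == "onset_shift") {
      truth$start[night] <- truth$start[night] + mag * 3600
      truth$end[night] <- truth$end[night] + mag * 3600
    } else if (plan$type[i] == "short_sleep") {
      segs <- which(night & truth$activity == "Sleep")
      remaining <- mag
      for (k in rev(segs)) {
        len <- truth$end[k] - truth$start[k]
        cut <- min(len, remaining)
        truth$end[k] <- truth$end[k] - cut
        remaining <- remaining - cut
        if (remaining <= 0) break
      }
      keep_end <- max(truth$end[night & truth$activity == "Sleep" &
                                  truth$end > truth$start])
      drop <- night & (truth$end <= truth$start | truth$start >= keep_end)
      truth <- truth[!drop, , drop = FALSE]
      night <- truth$day == d & truth$block == "sleep"
    } else if (plan$type[i] == "fragmentation") {
      segs <- truth[night & truth$activity == "Sleep", , drop = FALSE]
      onset <- min(segs$start)
      total_s <- sum(segs$end - segs$start)
      truth <- truth[!night, , drop = FALSE]
      nb <- build_night(d, as.POSIXct(onset, origin = "1970-01-01", tz = .tz),
                        total_s, as.integer(round(mag)))
      truth <- dplyr::bind_rows(truth, nb)
    } else if (plan$type[i] == "routine_swap") {
      idx <- which(truth$day == d & truth$block == "daytime")
      if (length(idx) > 1) {
        dur <- truth$end[idx] - truth$start[idx]
        dur <- dur[c(seq_along(dur)[-1], 1)] # cyclic shift of durations
        cur <- truth$start[idx[1]]
        for (j in seq_along(idx)) {
          truth$start[idx[j]] <- cur
          truth$end[idx[j]] <- cur + dur[j]
          cur <- cur + dur[j] + 600
        }
      }
    } else if (plan$type[i] == "night_appliance") {
      st <- as.numeric(as.POSIXct(paste(d + 1, "02:00:00"), tz = .tz))
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        day = d, block = "night_appliance", activity = "Cook",
        start = st, end = st + mag))
    }
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  new_sim_home(truth, sim$spec, anomalies = dplyr::bind_rows(sim$anomalies, plan))
}

#' Ground-truth intervals of a simulation as an interval table
#'
#' Converts the `truth` table of a `sim_home` into the same shape
#' [pair_activity_intervals()] returns, bypassing event rendering (useful
#' to compare the paired intervals against ground truth).
#'
#' @param sim a `sim_home`.
#' @param day_anchor as in [pair_activity_intervals()].
#' @return an interval tibble.
#' @export
truth_intervals <- function(sim, day_anchor = 0) {
  stopifnot(inherits(sim, "sim_home"))
  t <- sim$truth
  tibble::tibble(
    activity = t$activity,
    start = as.POSIXct(t$start, origin = "1970-01-01", tz = .tz),
    end = as.POSIXct(t$end, origin = "1970-01-01", tz = .tz),
    duration_s = t$end - t$start,
    source_day = as.Date(as.POSIXct(t$start - day_anchor * 3600,
                                    origin = "1970-01-01", tz = .tz)))
}

#' @export
print.sim_home <- function(x, ...) {
  cat(sprintf("<sim_home> %d events over %d day(s); %d anomalous day(s)\n",
              nrow(x$events), dplyr::n_distinct(x$truth$day), nrow(x$anomalies)))
  invisible(x)
}
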