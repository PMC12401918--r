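#' Parse one annotated smart-home event line
#'
#' CASAS-dialect logs are whitespace-delimited with fields in the order
#' date, time, sensor id, sensor status, and an optional activity label with
#' an optional `begin`/`end` marker. Both `HH:MM:SS` and fractional-second
#' timestamps are accepted.
#'
#' @param line a single log line.
#' @param line_number optional line number used in error messages.
#' @return a one-row tibble with columns `timestamp` (POSIXct, UTC),
#'   `sensor_id`, `status`, `activity` and `marker` (the last two `NA` when
#'   the line carries no annotation).
#' @examples
#' parse_event_line("2016-12-23 19:35:00.000000 M003 ON Sleep begin")
#' parse_event_line("2016-12-23 19:35:02 D001 OPEN")
#' @export
parse_event_line <- function(line, line_number = NA_integer_) {
  stopifnot(is.character(line), length(line) == 1)
  where <- if (is.na(line_number)) "" else sprintf(" (line %d)", line_number)
  fields <- strsplit(trimws(line), "[ \t]+")[[1]]
  fields <- fields[nzchar(fields)]
  if (length(fields) < 4) {
    abort(sprintf("Malformed event%s: expected at least 4 whitespace-separated fields, got %d.",
                  where, length(fields)))
  }
  ts <- as.POSIXct(paste(fields[1], fields[2]),
                   format = "%Y-%m-%d %H:%M:%OS", tz = .tz)
  if (is.na(ts)) {
    abort(sprintf("Malformed event%s: cannot parse timestamp '%s %s'.",
                  where, fields[1], fields[2]))
  }
  marker <- if (length(fields) >= 6) fields[6] else NA_character_
  if (!is.na(marker) && !marker %in% c("begin", "end")) {
    abort(sprintf("Malformed event%s: marker '%s' is not 'begin' or 'end'.", where, marker))
  }
  tibble::tibble(
    timestamp = ts,
    sensor_id = fields[3],
    status    = fields[4],
    activity  = if (length(fields) >= 5) fields[5] else NA_character_,
    marker    = marker
  )
}

#' Read a CASAS-dialect event log
#'
#' All parseable lines become events in file order. Malformed lines and
#' timestamp-order violations are collected into a validation report attached
#' as the `"validation"` attribute (a tibble with columns `line`, `reason`);
#' nothing is silently reordered or dropped without being reported.
#'
#' @param path path to a plain-text event log.
#' @return a tibble of events (see [parse_event_line()] for columns) with
#'   attributes `validation` and `provenance`.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read event log: '%s' does not exist.", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  issues <- list()
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    rows[[k]] <- tryCatch(parse_event_line(lines[i], line_number = i),
                          error = function(e) {
                            issues[[length(issues) + 1]] <<-
                              tibble::tibble(line = i, reason = conditionMessage(e))
                            NULL
                          })
  }
  n_bad <- length(issues)
  if (length(idx) > 0 && n_bad / length(idx) > 0.5) {
    abort(sprintf("More than half of the lines in '%s' are malformed (%d of %d); likely not a CASAS-dialect log.",
                  path, n_bad, length(idx)))
  }
  events <- dplyr::bind_rows(rows)
  if (nrow(events) == 0) {
    events <- tibble::tibble(timestamp = as.POSIXct(character(), tz = .tz),
                             sensor_id = character(), status = character(),
                             activity = character(), marker = character())
  }
  if (nrow(events) > 1) {
    ooo <- which(diff(as.numeric(events$timestamp)) < 0)
    for (j in ooo) {
      issues[[length(issues) + 1]] <- tibble::tibble(
        line = idx[!vapply(rows, is.null, logical(1))][j + 1],
        reason = "timestamp earlier than preceding event")
    }
  }
  validation <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(line = integer(), reason = character())
  attr(events, "validation") <- validation
  attr(events, "provenance") <- path
  events
}

#' Write events back to the CASAS dialect
#'
#' Inverse of [read_event_log()]: well-formed input round-trips to
#' field-equivalent lines (timestamps are written with six fractional
#' digits).
#'
#' @param events an event tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  stopifnot(is.data.frame(events))
  ts <- format(events$timestamp, "%Y-%m-%d %H:%M:%OS6", tz = .tz)
  ann <- ifelse(is.na(events$activity), "",
                paste0(" ", events$activity,
                       ifelse(is.na(events$marker), "", paste0(" ", events$marker))))
  writeLines(paste0(ts, " ", events$sensor_id, " ", events$status, ann), path)
  invisible(path)
}

#' Pair begin/end markers into labeled activity intervals
#'
#' Each `begin` marker is matched to the next `end` marker carrying the same
#' activity label; nested same-label begins are closed in LIFO order and
#' reported. Unmatched markers (an `end` before any `begin`, or a `begin`
#' left open at the end of the stream) become orphans in the `"orphans"`
#' attribute, never exceptions. Interleaved unannotated sensor events are
#' ignored by the pairing but retained upstream for night-time counts.
#'
#' @param events an event tibble from [read_event_log()] or
#'   [simulate_days()].
#' @param day_anchor clock time (hours in `[0, 24)`) at which the day rolls
#'   over for `source_day` assignment. The default 0 (midnight) matches daily
#'   activity aggregation; sleep attribution applies its own noon anchor
#'   downstream. An interval crossing the anchor is assigned wholly to the
#'   day containing its start.
#' @return a tibble with columns `activity`, `start`, `end`, `duration_s`
#'   and `source_day` (Date), plus an `"orphans"` attribute (tibble with
#'   `activity`, `timestamp`, `marker`, `reason`).
#' @export
pair_activity_intervals <- function(events, day_anchor = 0) {
  stopifnot(is.data.frame(events))
  day_anchor <- as_clock_hours(day_anchor, "day_anchor")
  ann <- events[!is.na(events$activity) & !is.na(events$marker), , drop = FALSE]
  open <- list() # per-label stack of begin timestamps
  out <- list()
  orphans <- list()
  if (nrow(ann) > 0) {
    for (i in seq_len(nrow(ann))) {
      a <- ann$activity[i]
      ts <- ann$timestamp[i]
      if (ann$marker[i] == "begin") {
        stk <- open[[a]] %||% numeric(0)
        if (length(stk) > 0) {
          orphans[[length(orphans) + 1]] <- tibble::tibble(
            activity = a, timestamp = ts, marker = "begin",
            reason = "nested begin for an already-open label (closed LIFO)")
        }
        open[[a]] <- c(stk, as.numeric(ts))
      } else {
        stk <- open[[a]] %||% numeric(0)
        if (length(stk) == 0) {
          orphans[[length(orphans) + 1]] <- tibble::tibble(
            activity = a, timestamp = ts, marker = "end",
            reason = "end without matching begin")
        } else {
          st <- stk[length(stk)] # LIFO
          open[[a]] <- stk[-length(stk)]
          if (as.numeric(ts) > st) {
            out[[length(out) + 1]] <- tibble::tibble(
              activity = a,
              start = as.POSIXct(st, origin = "1970-01-01", tz = .tz),
              end = ts)
          } else {
            orphans[[length(orphans) + 1]] <- tibble::tibble(
              activity = a, timestamp = ts, marker = "end",
              reason = "non-positive interval duration")
          }
        }
      }
    }
  }
  for (a in names(open)) {
    for (st in open[[a]]) {
      orphans[[length(orphans) + 1]] <- tibble::tibble(
        activity = a,
        timestamp = as.POSIXct(st, origin = "1970-01-01", tz = .tz),
        marker = "begin", reason = "begin never closed before end of stream")
    }
  }
  intervals <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(activity = character(),
                   start = as.POSIXct(character(), tz = .tz),
                   end = as.POSIXct(character(), tz = .tz))
  intervals <- dplyr::arrange(intervals, .data$start)
  intervals$duration_s <- as.numeric(intervals$end) - as.numeric(intervals$start)
  intervals$source_day <- as.Date(as.POSIXct(
    as.numeric(intervals$start) - day_anchor * 3600,
    origin = "1970-01-01", tz = .tz))
  attr(intervals, "orphans") <- if (length(orphans)) dplyr::bind_rows(orphans) else
    tibble::tibble(activity = character(),
                   timestamp = as.POSIXct(character(), tz = .tz),
                   marker = character(), reason = character())
  intervals
}
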