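# small in-code fixtures shared across test files

# write log lines to a temp file and return the path
write_log <- function(lines) {
  f <- tempfile(fileext = ".log")
  writeLines(lines, f)
  f
}

# a minimal well-formed annotated log: one sleep session wrapping midnight
# with a bathroom transition, plus a morning cook interval and an
# interleaved unannotated door event
tiny_log_lines <- c(
  "2016-12-23 19:35:00.000000 M003 ON Sleep begin",
  "2016-12-23 23:59:00 D001 OPEN",
  "2016-12-24 01:00:00.000000 M004 ON Bed_Toilet_Transition begin",
  "2016-12-24 01:05:00.000000 M004 OFF Bed_Toilet_Transition end",
  "2016-12-24 03:35:00.000000 M003 OFF Sleep end",
  "2016-12-24 08:00:00.000000 M017 ON Cook begin",
  "2016-12-24 08:30:00.000000 M017 OFF Cook end"
)

# worked-example vectors (three-activity day)
example_weights <- c(Sleep = 0.25, Personal_Hygiene = 0.10, Cook_Breakfast = 0.08)
example_reference <- c(Sleep = 0.30, Personal_Hygiene = 0.10, Cook_Breakfast = 0.05)
example_day <- c(Sleep = 0.25, Personal_Hygiene = 0.12, Cook_Breakfast = 0.10)

# a zero-noise routine spec: every simulated day identical
flat_spec <- function(seed = NULL) {
  routine_spec(activity_cv = 0, onset_sd = 0, duration_sd = 0,
               interruption_rate = 0, seed = seed)
}

# end-to-end scoring helpers
sessions_of <- function(sim) {
  extract_sleep_sessions(pair_activity_intervals(sim$events))
}
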