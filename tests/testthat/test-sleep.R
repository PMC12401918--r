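mk_sleep_log <- function() {
  write_log(c(
    # night 1: uninterrupted 23:00-07:00
    "2016-01-01 23:00:00 M003 ON Sleep begin",
    "2016-01-02 07:00:00 M003 OFF Sleep end",
    # night 2: split sleep with a bathroom transition in the gap
    "2016-01-02 23:00:00 M003 ON Sleep begin",
    "2016-01-03 03:00:00 M003 OFF Sleep end",
    "2016-01-03 03:02:00 M004 ON Bed_Toilet_Transition begin",
    "2016-01-03 03:04:00 M004 OFF Bed_Toilet_Transition end",
    "2016-01-03 03:10:00 M003 ON Sleep begin",
    "2016-01-03 07:00:00 M003 OFF Sleep end",
    # a sleepless day with only daytime activity
    "2016-01-04 12:30:00 M017 ON Cook begin",
    "2016-01-04 13:00:00 M017 OFF Cook end"))
}

test_that("sleep sessions carry onset, total duration and interruption count", {
  iv <- pair_activity_intervals(read_event_log(mk_sleep_log()))
  ss <- extract_sleep_sessions(iv)
  expect_equal(nrow(ss), 2)
  expect_equal(ss$onset_hours, c(23, 23))
  expect_equal(ss$duration_s[1], 28800)
  expect_equal(ss$duration_s[2], (4 + 3 + 50 / 60) * 3600) # 28200 s
  expect_equal(ss$interruptions, c(0L, 1L))
  # the sleepless day appears in the missing-nights report
  expect_true(as.Date("2016-01-04") %in% attr(ss, "missing_nights"))
})

test_that("gap-based interruption counting is available as an alternative", {
  iv <- pair_activity_intervals(read_event_log(mk_sleep_log()))
  ss <- extract_sleep_sessions(iv, interruptions = "gaps", max_gap_hours = 2)
  expect_equal(ss$interruptions, c(0L, 1L))
})

test_that("the sleep reference uses circular onset statistics", {
  ident <- tibble::tibble(night = as.Date("2016-01-01") + 0:2,
                          onset_hours = 22.5, duration_s = 28800,
                          interruptions = 0L)
  ref <- build_sleep_reference(ident)
  expect_equal(ref$r_onset_hours, 22.5)
  expect_equal(ref$r_duration_s, 28800)
  expect_equal(ref$sigma_onset_hours, 0)
  expect_equal(ref$sigma_duration_s, 0)

  wrap <- tibble::tibble(night = as.Date("2016-01-01") + 0:1,
                         onset_hours = c(23.5, 0.5),
                         duration_s = c(7, 9) * 3600, interruptions = 0L)
  refw <- build_sleep_reference(wrap)
  expect_equal(refw$r_onset_hours, 0) # naive mean 12.0 would be wrong
  expect_equal(refw$r_duration_s, 8 * 3600)
  expect_equal(refw$sigma_duration_s, 3600)

  expect_error(build_sleep_reference(ident[0, ]), "zero nights")
})

test_that("onset deviation is the circular clock distance", {
  expect_equal(compute_sod(5, 5), 0)
  expect_equal(compute_sod(23.5, 0.5), 1)
  expect_equal(compute_sod(2, 22), 4)
  expect_error(compute_sod(25, 1), "\\[0, 24\\)")
  # symmetry and rotation invariance on the circle
  set.seed(5)
  o <- stats::runif(50, 0, 24)
  r <- stats::runif(50, 0, 24)
  expect_equal(compute_sod(o, r), compute_sod(r, o))
  shift <- 7.3
  expect_equal(compute_sod((o + shift) %% 24, (r + shift) %% 24),
               compute_sod(o, r), tolerance = 1e-12)
  expect_true(all(compute_sod(o, r) <= 12))
  # circular dispersion is also rotation-invariant
  expect_equal(circular_sd_hours((o + shift) %% 24), circular_sd_hours(o),
               tolerance = 1e-12)
})

test_that("duration, interruption and consistency metrics follow their formulas", {
  expect_equal(compute_sdd(28800, 28800), 0)
  expect_equal(compute_sdd(21600, 28800), 2)
  expect_equal(compute_sdd(30600, 28800), 0.5)
  expect_error(compute_sdd(0, 28800), "positive")

  expect_equal(compute_sii(0, 8), 0)
  expect_equal(compute_sii(3, 6), 0.5)
  expect_error(compute_sii(3, 0), "positive")
  expect_error(compute_sii(-1, 8), "non-negative")

  expect_equal(compute_sci(0, 0, 28800), 1)
  expect_equal(compute_sci(12, 28800, 28800), 0) # clamped at zero
  expect_equal(compute_sci(2.4, 2880, 28800), 0.8)
  expect_error(compute_sci(1, 1, 0), "positive")
})

test_that("the aggregate sleep score is the printed weighted sum", {
  expect_equal(compute_sdp(0, 0, 0, 1), 0) # perfect night
  expect_equal(compute_sdp(1, 2, 0.5, 0.8), 0.925)
  expect_equal(compute_sdp(1, 1, 1, 1, sdp_weights(0.4, 0.3, 0.2, 0.1)), 0.9)
  expect_error(sdp_weights(-0.1), "non-negative")
  expect_error(sdp_weights(0.3, 0.3, 0.3, 0.3, strict = TRUE), "not 1")
  # monotone: worse metrics never lower the score
  base <- compute_sdp(1, 1, 1, 0.9)
  expect_gte(compute_sdp(2, 1, 1, 0.9), base)
  expect_gte(compute_sdp(1, 2, 1, 0.9), base)
  expect_gte(compute_sdp(1, 1, 2, 0.9), base)
  expect_gte(compute_sdp(1, 1, 1, 0.5), base)
})

test_that("night flagging matches the day-flagging contract", {
  nights <- as.Date("2016-01-01") + 0:9
  flat <- tibble::tibble(night = nights, score = rep(0.3, 10))
  expect_equal(sum(flag_sleep_days(flat, threshold_config("dynamic", alpha = 2))$flagged), 0)

  one_out <- tibble::tibble(night = nights, score = c(rep(0.1, 9), 1.2))
  rec <- flag_sleep_days(one_out, threshold_config("dynamic", alpha = 1))
  expect_equal(rec$day[rec$flagged], nights[10])

  pos <- tibble::tibble(night = nights, score = stats::runif(10, 0.01, 1))
  expect_true(all(flag_sleep_days(pos, threshold_config("fixed", value = 0))$flagged))
})

test_that("a zero-variance cohort scores zero every night", {
  sim <- simulate_days(flat_spec(seed = 3), 8)
  ss <- sessions_of(sim)
  sc <- sdp_scores(ss)
  expect_equal(sc$score, rep(0, 8))
  expect_equal(sc$sci, rep(1, 8))
  expect_equal(sum(sc$flagged), 0)
})
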