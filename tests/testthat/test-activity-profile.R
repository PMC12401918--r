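mk_intervals <- function(day, activity, dur_s, start_hour = 9) {
  if (length(day) == 0) {
    return(tibble::tibble(activity = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_s = numeric(), source_day = as.Date(character())))
  }
  start <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC") + start_hour * 3600
  tibble::tibble(activity = activity, start = start, end = start + dur_s,
                 duration_s = dur_s, source_day = as.Date(day))
}

test_that("daily durations aggregate by day and activity", {
  expect_equal(nrow(aggregate_daily_durations(mk_intervals(character(), character(), numeric()))), 0)

  iv <- dplyr::bind_rows(
    mk_intervals("2016-01-01", "Sleep", 28800),
    mk_intervals("2016-01-01", "Eat", 3600),
    mk_intervals("2016-01-01", "Relax", 10800))
  agg <- aggregate_daily_durations(iv)
  expect_equal(sort(agg$duration_s), c(3600, 10800, 28800))

  # repeated same-label intervals on one day sum
  iv2 <- dplyr::bind_rows(mk_intervals("2016-01-01", "Sleep", 3600),
                          mk_intervals("2016-01-01", "Sleep", 1800, start_hour = 14))
  expect_equal(aggregate_daily_durations(iv2)$duration_s, 5400)
})

test_that("proportions normalize to the day's labeled total", {
  daily <- tibble::tibble(day = as.Date("2016-01-01"),
                          activity = c("Sleep", "Eat", "Relax"),
                          duration_s = c(28800, 3600, 3600))
  p <- normalize_proportions(daily)
  expect_equal(p$proportion[match(c("Sleep", "Eat", "Relax"), p$activity)],
               c(0.8, 0.1, 0.1))
  expect_equal(sum(p$proportion), 1)

  single <- tibble::tibble(day = as.Date("2016-01-01"), activity = "Sleep",
                           duration_s = 100)
  expect_equal(normalize_proportions(single)$proportion, 1)

  zero <- tibble::tibble(day = as.Date("2016-01-01"), activity = "Sleep",
                         duration_s = 0)
  expect_warning(out <- normalize_proportions(zero), "zero labeled time")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "empty_days"), as.Date("2016-01-01"))
})

test_that("reference routine pools mean durations and sums to one", {
  one_day <- tibble::tibble(day = as.Date("2016-01-01"),
                            activity = c("A", "B"), duration_s = c(2, 8) * 3600)
  ref1 <- build_reference_routine(one_day)
  expect_equal(ref1$r[match(c("A", "B"), ref1$activity)], c(0.2, 0.8))

  two_days <- tibble::tibble(
    day = rep(as.Date("2016-01-01") + 0:1, each = 2),
    activity = rep(c("A", "B"), 2),
    duration_s = c(2, 8, 4, 6) * 3600)
  ref2 <- build_reference_routine(two_days)
  expect_equal(ref2$r[match(c("A", "B"), ref2$activity)], c(0.3, 0.7))

  # activities absent on a day contribute zero to that day's mean term
  sparse <- tibble::tibble(day = as.Date("2016-01-01") + 0:1,
                           activity = c("A", "B"), duration_s = c(3600, 3600))
  ref3 <- build_reference_routine(sparse)
  expect_equal(ref3$r, c(0.5, 0.5))

  expect_error(build_reference_routine(two_days[0, ]), "zero days")
})

test_that("reference is permutation-invariant and idempotent on identical days", {
  set.seed(42)
  days <- as.Date("2016-01-01") + 0:9
  prof <- tidyr::expand_grid(day = days, activity = c("A", "B", "C")) |>
    dplyr::mutate(duration_s = stats::runif(dplyr::n(), 100, 10000))
  ref <- build_reference_routine(prof)
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(tidy(build_reference_routine(shuffled)), tidy(ref))
  expect_equal(sum(ref$r), 1)

  # k identical days reproduce any one day's proportions
  base <- tibble::tibble(day = as.Date("2016-01-01"),
                         activity = c("A", "B"), duration_s = c(1, 3))
  rep3 <- dplyr::bind_rows(lapply(0:2, function(k) dplyr::mutate(base, day = day + k)))
  expect_equal(build_reference_routine(rep3)$r, c(0.25, 0.75))
})

test_that("the two reference normalizations differ only when day lengths vary", {
  equal_len <- tibble::tibble(
    day = rep(as.Date("2016-01-01") + 0:1, each = 2),
    activity = rep(c("A", "B"), 2),
    duration_s = c(2, 8, 4, 6) * 3600)
  expect_equal(build_reference_routine(equal_len, "mean_proportion")$r,
               build_reference_routine(equal_len, "pooled_mean")$r)

  uneven <- tibble::tibble(
    day = rep(as.Date("2016-01-01") + 0:1, each = 2),
    activity = rep(c("A", "B"), 2),
    duration_s = c(1, 1, 8, 2) * 3600) # day2 five times longer
  expect_false(isTRUE(all.equal(
    build_reference_routine(uneven, "mean_proportion")$r,
    build_reference_routine(uneven, "pooled_mean")$r)))
})

test_that("baseline_days restricts the reference to the first k days", {
  prof <- tibble::tibble(day = as.Date("2016-01-01") + rep(0:2, each = 2),
                         activity = rep(c("A", "B"), 3),
                         duration_s = c(1, 1, 1, 1, 100, 1) * 3600)
  ref <- build_reference_routine(prof, baseline_days = 2)
  expect_equal(ref$r, c(0.5, 0.5))
  expect_equal(attr(ref, "n_days"), 2L)
})
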