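test_that("short gaps are linearly interpolated, long and edge gaps are not", {
  v <- c(100, NA, NA, 130, 120)
  tr <- glucose_trace(0, 15, v)
  out <- interpolate_gaps(tr)
  expect_equal(out$values, c(100, 110, 120, 130, 120))

  v9 <- c(100, rep(NA, 9), 130)
  out9 <- interpolate_gaps(glucose_trace(0, 15, v9))   # 135 min > 120
  expect_equal(out9$values, v9)

  vedge <- c(NA, NA, 100, 110)
  expect_equal(interpolate_gaps(glucose_trace(0, 15, vedge))$values, vedge)

  clean <- glucose_trace(0, 15, c(90, 95, 100))
  expect_identical(interpolate_gaps(clean)$values, clean$values)
})

test_that("interpolated points are collinear and observations unaltered", {
  set.seed(5)
  for (rep in 1:20) {
    v <- runif(30, 80, 200)
    miss <- sample(2:29, 5)
    vm <- v; vm[miss] <- NA
    out <- interpolate_gaps(glucose_trace(0, 15, vm))$values
    expect_identical(out[-miss], vm[-miss])
    r <- rle(is.na(vm))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[j]; e <- ends[j]
      if (s == 1L || e == 30L || r$lengths[j] * 15 > 120) next
      lo <- vm[s - 1L]; hi <- vm[e + 1L]
      k <- seq_len(r$lengths[j])
      expect_equal(out[s:e], lo + (hi - lo) * k / (r$lengths[j] + 1L))
    }
  }
})

test_that("night labeling follows the three-consecutive-low rule", {
  lab <- function(v) label_night(glucose_trace(0, 15, v))
  expect_equal(lab(c(90, 80, 65, 64, 63, 90)), 1L)
  expect_equal(lab(c(65, 64, 71, 63, 62, 90)), 0L)
  expect_equal(lab(rep(85, 24)), 0L)
  # a missing sample breaks a run
  expect_equal(lab(c(90, 65, 64, NA, 63, 62, 90)), 0L)
  # qualifying run wins even with a long gap elsewhere
  expect_equal(lab(c(65, 64, 63, rep(NA, 10), 90)), 1L)
  # long gap and no qualifying run: unevaluable
  expect_true(is.na(lab(c(90, 85, rep(NA, 10), 90))))
  expect_true(is.na(label_night(trace_window(flat_trace(), 5000, 6000))))
})

test_that("labeling ignores missing values outside the qualifying run", {
  base <- c(90, 85, 65, 64, 63, 88, 95, 92)
  with_na <- base; with_na[c(1, 7)] <- NA
  expect_equal(label_night(glucose_trace(0, 15, base)),
               label_night(glucose_trace(0, 15, with_na)))
})

test_that("night records are built, dropped and counted consistently", {
  cfg <- sim_config(n_nights = 5)
  p <- virtual_patient(overnight_sensitivity_multiplier = 1.3)
  traces <- list()
  events <- NULL
  sleep <- NULL
  for (j in 1:5) {
    ev <- scenario_events(c(380, 380), c("meal", "bolus"), c(60, 6),
                          c(60, NA))
    tr <- simulate_night(p, ev, cfg)
    traces[[as.character(j)]] <- tr
    ev$night_id <- j
    events <- rbind(events, ev)
    sleep <- rbind(sleep, data.frame(night_id = j, onset = 585))
  }
  recs <- build_night_records(traces, events, sleep)
  expect_length(recs, 5L)
  expect_equal(attr(recs, "n_dropped"), 0L)
  expect_equal(attr(recs, "n_dropped") + length(recs), attr(recs, "n_total"))

  # onset before trace coverage: record skipped with a warning
  sleep_bad <- data.frame(night_id = 1, onset = -50)
  expect_warning(
    recs0 <- build_night_records(traces["1"], events[events$night_id == 1, ],
                                 sleep_bad),
    "coverage")
  expect_length(recs0, 0L)

  # an unfillable pre-window gap drops the record
  tr_gap <- traces[["1"]]
  tt <- trace_times(tr_gap)
  tr_gap$values[tt >= 300 & tt <= 450] <- NA   # 150-min gap in pre-window
  recs_gap <- build_night_records(list("1" = tr_gap),
                                  events[events$night_id == 1, ],
                                  data.frame(night_id = 1, onset = 585))
  expect_length(recs_gap, 0L)
  expect_equal(attr(recs_gap, "n_dropped"), 1L)
})
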