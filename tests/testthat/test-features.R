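test_that("bolus on board follows the linear remaining-fraction curve", {
  no_bolus <- data.frame(time = numeric(0), magnitude = numeric(0))
  expect_equal(bolus_on_board(no_bolus, 500), 0)
  one <- data.frame(time = 500, magnitude = 6)
  expect_equal(bolus_on_board(one, 500), 6)          # R(0) = 1
  expect_equal(bolus_on_board(one, 620, action_time = 240), 3)  # halfway
  expect_equal(bolus_on_board(one, 800, action_time = 240), 0)  # expired
  # boluses after t are ignored
  expect_equal(bolus_on_board(one, 400), 0)
  # superposition of two boluses
  two <- data.frame(time = c(400, 500), magnitude = c(4, 6))
  expect_equal(bolus_on_board(two, 560, 240),
               4 * (1 - 160 / 240) + 6 * (1 - 60 / 240))
})

test_that("carbohydrate on board matches the bi-exponential closed form", {
  meal <- data.frame(time = 100, magnitude = 50, tau_max = 40)
  expect_equal(cho_on_board(meal, 100), 50)          # nothing absorbed yet
  expect_equal(cho_on_board(meal, 1e6), 0, tolerance = 1e-9)
  expect_equal(cho_on_board(meal, 140), 50 * 2 / exp(1), tolerance = 1e-12)
  # oracle: dose minus numerically integrated absorption rate
  q <- stats::integrate(function(t) cho_absorption_rate(50, 1, 40, t),
                        0, 90, rel.tol = 1e-10)
  expect_equal(cho_on_board(meal, 190), 50 - q$value, tolerance = 1e-6)
})

test_that("carbohydrate mass balance holds at all times", {
  for (tau in c(20, 40, 90)) {
    meal <- data.frame(time = 0, magnitude = 60, tau_max = tau)
    for (t in c(0, 10, 50, 200, 600)) {
      absorbed <- 60 * 0.85 * cho_absorbed_fraction(tau, t)
      expect_equal(cho_on_board(meal, t, bioavailability = 0.85) + absorbed,
                   60 * 0.85, tolerance = 1e-9)
    }
  }
})

test_that("activity on board decays exponentially and is linear in counts", {
  none <- data.frame(time = numeric(0), magnitude = numeric(0))
  expect_equal(activity_on_board(none, 100), 0)
  one <- data.frame(time = 100, magnitude = 1000)
  expect_equal(activity_on_board(one, 160, decay_time = 60), 1000 / exp(1))
  two <- one; two$magnitude <- 2000
  expect_equal(activity_on_board(two, 400), 2 * activity_on_board(one, 400))
})

test_that("risk indices split readings by the sign of the transform", {
  g_neutral <- exp(5.381^(1 / 1.084))
  r <- glycemic_risk_indices(rep(g_neutral, 10))
  expect_equal(unname(r), c(0, 0), tolerance = 1e-9)

  r_low <- glycemic_risk_indices(rep(50, 8))
  expect_gt(r_low["lbgi"], 0)
  expect_equal(unname(r_low["hbgi"]), 0)

  f250 <- 1.509 * (log(250)^1.084 - 5.381)
  r_high <- glycemic_risk_indices(rep(250, 5))
  expect_equal(unname(r_high["hbgi"]), 10 * f250^2, tolerance = 1e-12)
  expect_equal(unname(r_high["lbgi"]), 0)

  # every reading contributes to exactly one index or neither
  set.seed(2)
  g <- runif(50, 40, 350)
  f <- 1.509 * (log(g)^1.084 - 5.381)
  r <- glycemic_risk_indices(g)
  expect_equal(unname(r["lbgi"] + r["hbgi"]),
               mean(10 * f^2 * (f != 0)), tolerance = 1e-12)
  expect_error(glycemic_risk_indices(c(100, -3)), "positive")
})

test_that("area below 70 matches rectangle and fine Riemann oracles", {
  expect_equal(auc_below_70(flat_trace(100, 25)), 0)
  expect_equal(auc_below_70(flat_trace(60, 25)), 3600)  # 10 x 360 min
  # V-shaped dip crossing the threshold vs 1-s Riemann sum
  tt <- seq(0, 360, by = 15)
  v <- 90 - 40 * pmax(0, 1 - abs(tt - 180) / 90)
  tr <- glucose_trace(0, 15, v)
  fine <- seq(0, 360, by = 1 / 60)
  vf <- approx(tt, v, xout = fine)$y
  riemann <- sum(pmax(0, 70 - vf)) * (1 / 60)
  expect_equal(auc_below_70(tr), riemann, tolerance = 1e-3)
})

test_that("feature vectors have 17 features with PA and 15 without", {
  recs <- night_records(test_cohort())
  rec <- Filter(function(r) !is.na(r$label), recs)[[1]]
  fv <- build_feature_vector(rec, include_pa = TRUE)
  expect_length(fv, 17L)
  expect_named(fv, nh_feature_names(TRUE))
  fv15 <- build_feature_vector(rec, include_pa = FALSE)
  expect_length(fv15, 15L)
  expect_false(any(c("aob", "steps") %in% names(fv15)))
})

test_that("a constant gap-free eventless window yields zero deltas", {
  rec <- structure(
    list(patient_id = "T", night_id = 1, sleep_onset = 360,
         pre_window = glucose_trace(0, 15, rep(120, 25)),
         post_window = glucose_trace(360, 15, rep(120, 24)),
         events = scenario_events(), events_pre = scenario_events(),
         label = 0L),
    class = "night_record")
  fv <- build_feature_vector(rec)
  expect_equal(unname(fv[c("dbg_30", "dbg_60", "bob", "cob", "auc70",
                           "roc_30", "aob", "steps")]),
               rep(0, 8))
  expect_equal(unname(fv[paste0("cgm_mean_h", 1:6)]), rep(120, 6))
  expect_equal(unname(fv["cgm_t"]), 120)
})

test_that("feature extraction is invariant to event-log row order", {
  recs <- night_records(test_cohort())
  rec <- Filter(function(r) nrow(r$events_pre) >= 3 && !is.na(r$label),
                recs)[[1]]
  rec2 <- rec
  perm <- rev(seq_len(nrow(rec2$events_pre)))
  rec2$events_pre <- rec2$events_pre[perm, ]
  rec2$events <- rec2$events[rev(seq_len(nrow(rec2$events))), ]
  expect_equal(build_feature_vector(rec), build_feature_vector(rec2))
})

test_that("instance tables carry ids, canonical columns and labels", {
  inst <- test_instances()
  expect_true(all(nh_feature_names(TRUE) %in% names(inst)))
  expect_true(all(inst$label %in% 0:1))
  expect_gt(nrow(inst), 50)
})
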