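test_that("prediction emulation reproduces the target operating point", {
  y <- c(1, 0, 1, 0)
  expect_equal(emulate_prediction(y, 1, 1, u = runif(4)), y)
  set.seed(99)
  pos <- emulate_prediction(rep(1L, 1e5), 0.73, 0.75)
  expect_lt(abs(mean(pos) - 0.73), 0.005)
  neg <- emulate_prediction(rep(0L, 1e5), 0.73, 0.75)
  expect_lt(abs(mean(neg) - 0.25), 0.005)
})

test_that("time in ranges covers the standard glycemic intervals", {
  expect_equal(unname(time_in_ranges(flat_trace(100))), c(0, 0, 100, 0))
  expect_equal(unname(time_in_ranges(flat_trace(60))), c(0, 100, 0, 0))
  half <- glucose_trace(0, 15, c(rep(65, 12), rep(100, 12)))
  expect_equal(unname(time_in_ranges(half)), c(0, 50, 50, 0))
  # partition identity holds exactly for arbitrary traces
  set.seed(4)
  v <- runif(48, 40, 260)
  tir <- time_in_ranges(glucose_trace(0, 15, v))
  expect_identical(unname(tir["below70"] + tir["in_range"] +
                            tir["above180"]), 100)
  expect_lte(tir["below54"], tir["below70"])
  expect_error(time_in_ranges(flat_trace(100), window = c(5000, 6000)))
})

test_that("exact signed-rank p equals brute-force enumeration", {
  set.seed(12)
  for (n in c(5, 6, 8, 10)) {
    for (rep in 1:5) {
      x <- rnorm(n); y <- rnorm(n)
      got <- wilcoxon_signed_rank(x, y)
      expect_true(got$exact)
      expect_equal(got$p.value, wilcoxon_brute(x, y), tolerance = 1e-12)
    }
    # ties in |differences| handled by midranks, still exact
    x <- sample(1:4, n, replace = TRUE); y <- sample(1:4, n, replace = TRUE)
    if (any(x != y)) {
      expect_equal(wilcoxon_signed_rank(x, y)$p.value,
                   wilcoxon_brute(x, y), tolerance = 1e-12)
    }
  }
})

test_that("exact signed-rank agrees with the reference implementation", {
  set.seed(21)
  x <- rnorm(12); y <- rnorm(12)   # continuous: no ties, no zeros
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  got <- wilcoxon_signed_rank(x, y)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(got$statistic), unname(ref$statistic))
})

test_that("ten uniformly improved pairs give the minimal two-sided p", {
  base <- c(29, 27, 21, 29, 23, 32, 19, 34, 27, 31)
  treat <- base - c(9, 11, 4, 8, 9, 15, 10, 12, 7, 10)
  t <- wilcoxon_signed_rank(base, treat)
  expect_equal(t$p.value, 2 / 2^10)
  und <- wilcoxon_signed_rank(base, base)
  expect_true(und$undefined)
  expect_true(is.na(und$p.value))
})

test_that("a perfectly specific, insensitive predictor leaves baseline intact", {
  co <- test_cohort()
  mit <- mitigation_study(co, se = 0, sp = 1, doses = 30, taus = 40,
                          rng_seed = 7)
  arm <- mit$arms$dose30_tau40
  expect_identical(arm$nh, mit$baseline$nh)
  expect_identical(arm$below70, mit$baseline$below70)
  expect_equal(sum(arm$rescued), 0)
})

test_that("rescue never increases hypoglycemia and response is dose-monotone", {
  co <- test_cohort()
  for (seed in c(3, 7, 19)) {
    mit <- mitigation_study(co, doses = c(20, 30), taus = 40,
                            rng_seed = seed)
    n_base <- sum(mit$baseline$nh)
    n20 <- sum(mit$arms$dose20_tau40$nh)
    n30 <- sum(mit$arms$dose30_tau40$nh)
    expect_lte(n30, n20)       # shared draws make the arms nested
    expect_lte(n20, n_base)
  }
})

test_that("mitigation summary tables are consistent with night tables", {
  co <- test_cohort()
  mit <- mitigation_study(co, doses = 30, taus = 40, rng_seed = 5)
  s <- summary(mit, tau_ref = 40)
  base <- mit$baseline
  ids <- unique(base$patient_id)
  manual <- vapply(ids, function(p)
    100 * mean(base$nh[base$patient_id == p]), numeric(1))
  expect_equal(as.numeric(s$pct_nh$baseline[seq_along(ids)]),
               unname(manual))
  expect_equal(as.numeric(s$pct_nh$baseline[length(ids) + 1]),
               cohort_median(manual))
  # reduction column follows the (baseline - treated)/baseline formula
  hb <- as.numeric(s$hypo_counts$hypos_baseline[seq_along(ids)])
  ht <- as.numeric(s$hypo_counts$hypos_dose30_tau40[seq_along(ids)])
  expect_equal(as.numeric(s$hypo_counts$reduction_dose30_tau40[seq_along(ids)]),
               unname(reduction_pct(hb, ht)))
})

test_that("a patient with 29 of 89 hypoglycemic nights reports 32.58%", {
  nights <- data.frame(patient_id = "P12", night_id = 1:89,
                       nh = c(rep(1, 29), rep(0, 60)),
                       below54 = 0, below70 = 0, in_range = 100,
                       above180 = 0)
  s <- noctiguard:::per_patient_summary(nights)
  expect_equal(round(s$pct_nh, 2), 32.58)
})
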