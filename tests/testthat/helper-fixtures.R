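# Shared fixtures, built once per test run.

# small calibrated cohort: 4 patients x 40 nights
test_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) {
      co <<- suppressWarnings(
        generate_cohort(sim_config(n_patients = 4, n_nights = 40,
                                   rng_seed = 421L)))
    }
    co
  }
})

test_instances <- local({
  inst <- NULL
  function() {
    if (is.null(inst)) inst <<- cohort_instances(test_cohort())
    inst
  }
})

# flat trace covering a full scenario, constant glucose
flat_trace <- function(value = 100, n = 89, step = 15, start = 0) {
  glucose_trace(start, step, rep(value, n), "T")
}

# brute-force two-sided exact Wilcoxon signed-rank p over all 2^n signs
wilcoxon_brute <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p_le <- mean(vs <= v + 1e-9)
  p_ge <- mean(vs >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# trapezoidal AUC of the empirical ROC curve
roc_auc_trapezoid <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  sens <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t),
                      numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t),
                     numeric(1)), 1)
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}
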