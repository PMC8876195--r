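#' Emulate an imperfect NH predictor
#'
#' Given the true night label, predicts 1 with probability `se` for true
#' positives and `1 - sp` for true negatives, by comparing a uniform
#' deviate with the corresponding probability.
#'
#' @param true_label Vector of 0/1 true labels.
#' @param se,sp Sensitivity and specificity of the emulated predictor.
#' @param u Uniform(0,1) deviates, one per night (drawn from the current
#'   RNG if not supplied). Reusing the same deviates across intervention
#'   arms makes the rescued-night sets nested.
#' @return Integer vector of predicted 0/1 labels.
#' @export
emulate_prediction <- function(true_label, se, sp,
                               u = stats::runif(length(true_label))) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1,
            length(u) == length(true_label))
  ifelse(true_label == 1L, as.integer(u < se), as.integer(u < 1 - sp))
}

#' Percent time in glycemic intervals
#'
#' Fraction of readings, times 100, in the four standard intervals:
#' below 54 mg/dL (level 2 hypoglycemia), below 70 (level 1, time below
#' range), 70-180 (time in range) and above 180 (time above range). The
#' below-54 readings are a subset of the below-70 readings, and
#' `below70 + in_range + above180 = 100` exactly.
#'
#' @param trace A `glucose_trace`.
#' @param window Optional scenario-minute interval to restrict to.
#' @return Named numeric vector
#'   `c(below54, below70, in_range, above180)`, in percent.
#' @export
time_in_ranges <- function(trace, window = NULL) {
  if (!is.null(window)) trace <- trace_window(trace, window[1], window[2] - 1e-9)
  v <- trace$values[!is.na(trace$values)]
  if (!length(v)) stop("window has no readings", call. = FALSE)
  c(below54 = 100 * mean(v < 54),
    below70 = 100 * mean(v < 70),
    in_range = 100 * mean(v >= 70 & v <= 180),
    above180 = 100 * mean(v > 180))
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of a location shift between paired samples. Zero
#' differences are dropped and tied absolute differences receive
#' midranks. For `n <= 25` retained pairs the null distribution of the
#' positive-rank sum is computed exactly over all `2^n` sign assignments
#' (via the generating-function recursion, identical to full
#' enumeration); beyond that a normal approximation with tie correction
#' is used.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `statistic` (positive-rank sum `V`), `p.value`,
#'   `n` (pairs retained), `exact` (logical) and `undefined` (`TRUE` when
#'   all differences are zero, in which case `p.value` is `NA`).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p.value = NA_real_, n = 0L,
                exact = NA, undefined = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    # distribution of the positive-rank sum over all 2^n sign choices;
    # doubled ranks keep midranks integral
    r2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    tot <- 2^n
    w2 <- as.integer(round(2 * v))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / tot
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = v, p.value = p, n = n, exact = TRUE,
                undefined = FALSE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (v - mu) / sqrt(sig2)
  list(statistic = v, p.value = min(1, 2 * stats::pnorm(-abs(z))), n = n,
       exact = FALSE, undefined = FALSE)
}

#' Relative reduction versus baseline, percent
#'
#' `(baseline - treated) / baseline * 100`; `NA` where the baseline is 0.
#'
#' @param baseline,treated Numeric vectors.
#' @return Percent reduction (positive = improvement).
#' @export
reduction_pct <- function(baseline, treated) {
  ifelse(baseline == 0, NA_real_, (baseline - treated) / baseline * 100)
}

#' Cohort median
#'
#' Median over evaluable (finite) per-patient values; for an even count
#' the midpoint of the two middle values.
#'
#' @param x Numeric vector of per-patient values.
#' @return The median.
#' @export
cohort_median <- function(x) stats::median(x[is.finite(x)])

# rescue minute from clock time, on the cohort's scenario clock
rescue_minute <- function(config, rescue_time) {
  (clock_to_min(rescue_time) - config$origin) %% 1440
}

#' Run one mitigation arm over a cohort
#'
#' For every night, emulates the predictor ([emulate_prediction()]); on a
#' positive prediction inserts a rescue carbohydrate event at
#' `rescue_time` and re-simulates the night with the same
#' sensitivity-noise and CGM-noise draws as baseline (common random
#' numbers), then recomputes the NH indicator and the interval
#' percentages on the overnight window.
#'
#' @param cohort An `nh_cohort`.
#' @param dose Rescue carbohydrate, g.
#' @param tau_max Absorption time-to-peak of the rescue snack, min.
#' @param se,sp Emulated predictor operating point.
#' @param u List (per patient) of per-night uniform deviates for the
#'   prediction emulation.
#' @param rescue_time Clock time of the rescue intake.
#' @return Data frame with one row per night: `patient_id`, `night_id`,
#'   `nh_base`, `predicted`, `rescued`, `nh`, and the four interval
#'   percentages.
#' @export
run_mitigation_arm <- function(cohort, dose, tau_max, se = 0.73, sp = 0.75,
                               u, rescue_time = "23:30") {
  config <- cohort$config
  t_rescue <- rescue_minute(config, rescue_time)
  win <- config$overnight_window
  rows <- vector("list", length(cohort$patients))
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    ui <- u[[i]]
    nh_base <- vapply(p$nights, `[[`, numeric(1), "nh")
    pred <- emulate_prediction(nh_base, se, sp, ui)
    out <- lapply(seq_along(p$nights), function(j) {
      nt <- p$nights[[j]]
      if (pred[j] == 1L) {
        ev <- rbind(nt$events[, c("time", "kind", "magnitude", "tau_max")],
                    data.frame(time = t_rescue, kind = "rescue_cho",
                               magnitude = dose, tau_max = tau_max))
        ev <- ev[order(ev$time), , drop = FALSE]
        pp <- p$params
        pp$basal_glucose <- pp$basal_glucose * nt$gb_factor
        tr <- simulate_night(pp, ev, config, nt$sens_noise, nt$cgm_noise)
      } else {
        tr <- nt$trace
      }
      c(nh = nh_overnight(tr, win), time_in_ranges(tr, win))
    })
    out <- do.call(rbind, out)
    rows[[i]] <- data.frame(
      patient_id = p$params$patient_id,
      night_id = seq_along(p$nights),
      nh_base = nh_base, predicted = pred,
      rescued = pred, out, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' In-silico rescue-carbohydrate intervention study
#'
#' Emulates the NH predictor at a fixed (SE, SP) operating point over a
#' calibrated virtual cohort and, for every combination of rescue dose
#' and absorption time constant, delivers rescue carbohydrate on
#' predicted-positive nights and re-simulates them. Baseline and treated
#' arms share all random draws, so arm contrasts isolate the
#' intervention; the uniform deviates driving the prediction emulation
#' are drawn once and reused across arms.
#'
#' @param cohort An `nh_cohort` from [generate_cohort()].
#' @param se,sp Emulated predictor sensitivity and specificity.
#' @param doses Rescue doses to test, g.
#' @param taus Absorption time constants to test, min.
#' @param rescue_time Clock time of the rescue intake.
#' @param rng_seed Seed for the prediction-emulation deviates.
#' @return An object of class `nh_mitigation` containing the baseline
#'   night table, one night table per `(dose, tau)` arm, and per-patient
#'   summaries.
#' @export
mitigation_study <- function(cohort, se = 0.73, sp = 0.75,
                             doses = c(20, 25, 30, 35),
                             taus = c(20, 40, 60),
                             rescue_time = "23:30", rng_seed = 1L) {
  stopifnot(inherits(cohort, "nh_cohort"), all(doses > 0), all(taus > 0))
  config <- cohort$config
  win <- config$overnight_window
  set.seed(rng_seed)
  u <- lapply(cohort$patients,
              function(p) stats::runif(length(p$nights)))

  base_rows <- do.call(rbind, lapply(cohort$patients, function(p) {
    out <- t(vapply(p$nights, function(nt) {
      c(nh = nh_overnight(nt$trace, win), time_in_ranges(nt$trace, win))
    }, numeric(5)))
    data.frame(patient_id = p$params$patient_id,
               night_id = seq_along(p$nights), out, row.names = NULL)
  }))

  arms <- list()
  for (tau in taus) {
    for (dose in doses) {
      key <- sprintf("dose%g_tau%g", dose, tau)
      arms[[key]] <- run_mitigation_arm(cohort, dose, tau, se, sp, u,
                                        rescue_time)
      arms[[key]]$dose <- dose
      arms[[key]]$tau <- tau
    }
  }
  structure(
    list(baseline = base_rows, arms = arms, se = se, sp = sp,
         doses = doses, taus = taus, rescue_time = rescue_time,
         n_nights = config$n_nights, rng_seed = rng_seed),
    class = "nh_mitigation")
}

# per-patient summary of a night table
per_patient_summary <- function(nights) {
  ids <- unique(nights$patient_id)
  out <- lapply(ids, function(p) {
    d <- nights[nights$patient_id == p, , drop = FALSE]
    data.frame(patient_id = p,
               pct_nh = 100 * mean(d$nh),
               n_hypos = sum(d$nh),
               below54 = mean(d$below54), below70 = mean(d$below70),
               in_range = mean(d$in_range), above180 = mean(d$above180))
  })
  do.call(rbind, out)
}

#' Summarize an in-silico mitigation study
#'
#' Builds the three outcome tables of the intervention analysis:
#' `pct_nh` (percentage of nights with NH per patient and arm, with the
#' cohort median), `hypo_counts` (per-patient hypoglycemic-night counts
#' with relative reductions and exact Wilcoxon signed-rank p-values
#' against baseline) and `tir` (median and IQR across patients of the
#' per-patient percent time in each glycemic interval, the variation of
#' the medians versus baseline, and Wilcoxon p-values), the latter for
#' the requested absorption constant.
#'
#' @param object An `nh_mitigation`.
#' @param tau_ref Absorption constant whose arms populate the count and
#'   TIR tables (default 40 min).
#' @param ... Unused.
#' @return An object of class `summary.nh_mitigation` (a list of data
#'   frames).
#' @export
summary.nh_mitigation <- function(object, tau_ref = 40, ...) {
  base <- per_patient_summary(object$baseline)

  pct <- data.frame(patient_id = base$patient_id, baseline = base$pct_nh)
  for (key in names(object$arms)) {
    pct[[key]] <- per_patient_summary(object$arms[[key]])$pct_nh
  }
  med <- c(patient_id = "Median",
           lapply(pct[-1], cohort_median))
  pct_med <- rbind(pct, as.data.frame(med))

  keys <- names(object$arms)[vapply(object$arms, function(a)
    a$tau[1] == tau_ref, logical(1))]
  counts <- data.frame(patient_id = base$patient_id,
                       pct_nh_baseline = base$pct_nh,
                       hypos_baseline = base$n_hypos)
  tests <- list()
  for (key in keys) {
    s <- per_patient_summary(object$arms[[key]])
    counts[[paste0("hypos_", key)]] <- s$n_hypos
    counts[[paste0("reduction_", key)]] <-
      reduction_pct(base$n_hypos, s$n_hypos)
    tests[[key]] <- wilcoxon_signed_rank(base$n_hypos, s$n_hypos)
  }
  med_row <- c(list(patient_id = "Median"),
               lapply(counts[-1], cohort_median))
  counts_med <- rbind(counts, as.data.frame(med_row))

  iqr_fmt <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
  }
  tir <- NULL
  for (v in c("below54", "below70", "in_range", "above180")) {
    row <- data.frame(interval = v, baseline = iqr_fmt(base[[v]]))
    base_med <- cohort_median(base[[v]])
    for (key in keys) {
      s <- per_patient_summary(object$arms[[key]])
      wt <- wilcoxon_signed_rank(base[[v]], s[[v]])
      arm_med <- cohort_median(s[[v]])
      row[[key]] <- iqr_fmt(s[[v]])
      row[[paste0("variation_", key)]] <-
        if (base_med > 0) (arm_med - base_med) / base_med * 100 else NA_real_
      row[[paste0("p_", key)]] <- wt$p.value
    }
    tir <- rbind(tir, row)
  }

  structure(list(pct_nh = pct_med, hypo_counts = counts_med, tir = tir,
                 tests = tests, se = object$se, sp = object$sp,
                 tau_ref = tau_ref),
            class = "summary.nh_mitigation")
}

#' @export
print.summary.nh_mitigation <- function(x, ...) {
  cat(sprintf("In-silico mitigation, emulated predictor SE=%.2f SP=%.2f\n\n",
              x$se, x$sp))
  cat("Percentage of nights with NH (per patient and arm):\n")
  df <- x$pct_nh
  df[-1] <- lapply(df[-1], function(v) round(as.numeric(v), 2))
  print(df, row.names = FALSE)
  cat(sprintf("\nHypoglycemic-night counts and reductions (tau = %g min):\n",
              x$tau_ref))
  df <- x$hypo_counts
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 2)
  print(df, row.names = FALSE)
  for (key in names(x$tests)) {
    t <- x$tests[[key]]
    cat(sprintf("  %s: V = %g, exact p = %.4g\n", key, t$statistic,
                t$p.value))
  }
  cat("\nPercent time in glycemic intervals (median (IQR) across patients):\n")
  df <- x$tir
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.nh_mitigation <- function(x, ...) {
  base <- per_patient_summary(x$baseline)
  cat(sprintf(
    paste0("<nh_mitigation> %d patients, %d nights, SE=%.2f SP=%.2f, ",
           "doses {%s} g, tau {%s} min\n",
           "  baseline median %% nights with NH: %.2f\n"),
    nrow(base), x$n_nights, x$se, x$sp,
    paste(x$doses, collapse = ", "), paste(x$taus, collapse = ", "),
    cohort_median(base$pct_nh)))
  cat("  use summary() for the outcome tables\n")
  invisible(x)
}
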