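#' Nocturnal hypoglycemia indicator on the overnight window
#'
#' Applies the episode rule (>= `min_run` consecutive readings below
#' 70 mg/dL) to the samples of a trace falling in the overnight clock
#' window.
#'
#' @param trace A `glucose_trace` covering the window.
#' @param window Numeric length-2, overnight window in scenario minutes.
#' @param min_run,threshold Episode rule parameters.
#' @return `1L` or `0L`.
#' @export
nh_overnight <- function(trace, window = c(600, 960), min_run = 3L,
                         threshold = 70) {
  w <- trace_window(trace, window[1], window[2] - 1e-9)
  as.integer(longest_low_run(w$values, threshold) >= min_run)
}

# draw one night's behavioral scenario; returns list of draws
draw_night_scenario <- function(params, config, night_noise_sd, pa_prob,
                                pa_effect) {
  dinner_t <- min(max(stats::rnorm(1, 380, 25), 320), 440)
  dinner_cho <- min(max(stats::rnorm(1, 55, 12), 30), 90)
  est_err <- min(max(stats::rnorm(1, 0, 0.15), -0.35), 0.35)
  bolus <- dinner_cho * (1 + est_err) / params$carb_ratio
  onset <- min(max(stats::rnorm(1, config$sleep_onset_mean,
                                config$sleep_onset_sd), 520), 660)
  gb_factor <- exp(stats::rnorm(1, 0, 0.07))   # day-level glycemia drift
  base_steps <- stats::rlnorm(1, log(6500), 0.4)
  pa_extra <- 0; pa_t <- NA_real_
  if (stats::runif(1) < pa_prob) {
    pa_extra <- stats::runif(1, 2000, 8000)
    pa_t <- min(max(stats::rnorm(1, 450, 45), 360), 530)
  }
  sens_noise <- exp(stats::rnorm(1, 0, night_noise_sd)) *
    (1 + pa_effect * pa_extra / 10000)

  n_cgm <- floor(config$horizon / config$cgm_step) + 1L
  cgm_noise <- stats::rnorm(n_cgm, 0, params$noise_sd)

  gap_mask <- rep(FALSE, n_cgm)
  n_gaps <- stats::rpois(1, config$gap_rate)
  if (n_gaps > 0) {
    for (k in seq_len(n_gaps)) {
      gs <- stats::runif(1, 0, config$horizon)
      gd <- stats::rlnorm(1, config$gap_meanlog, config$gap_sdlog)
      st <- config$cgm_step * (seq_len(n_cgm) - 1L)
      gap_mask <- gap_mask | (st >= gs & st < gs + gd)
    }
  }

  ev <- list(time = c(dinner_t, dinner_t, 120),
             kind = c("meal", "bolus", "steps"),
             magnitude = c(dinner_cho, bolus, base_steps),
             tau_max = c(params$tau_max_meal, NA, NA))
  if (pa_extra > 0) {
    ev$time <- c(ev$time, pa_t); ev$kind <- c(ev$kind, "steps")
    ev$magnitude <- c(ev$magnitude, pa_extra); ev$tau_max <- c(ev$tau_max, NA)
  }
  events <- scenario_events(ev$time, ev$kind, ev$magnitude, ev$tau_max)
  list(events = events, onset = onset, sens_noise = sens_noise,
       gb_factor = gb_factor, cgm_noise = cgm_noise, gap_mask = gap_mask)
}

# simulate one pre-drawn night, applying its day-level glucose drift
simulate_cohort_night <- function(params, nt, config) {
  params$basal_glucose <- params$basal_glucose * nt$gb_factor
  simulate_night(params, nt$events, config, nt$sens_noise, nt$cgm_noise)
}

# NH fraction across pre-drawn nights for a candidate multiplier
cohort_nh_fraction_at <- function(params, multiplier, nights, config) {
  params$overnight_sensitivity_multiplier <- multiplier
  mean(vapply(nights, function(nt) {
    nh_overnight(simulate_cohort_night(params, nt, config),
                 config$overnight_window)
  }, numeric(1)))
}

#' Generate a calibrated virtual T1D cohort
#'
#' Draws heterogeneous virtual patients, samples per-night behavior
#' (dinner and its bolus with carbohydrate-estimation error, sleep onset,
#' daily steps with occasional evening activity, CGM noise and sensor
#' gaps), and calibrates each patient's overnight insulin-sensitivity
#' multiplier by bisection so that the patient's fraction of nights with
#' nocturnal hypoglycemia matches a per-patient target scattered around
#' `target_nh_fraction`. Evening physical activity scales the night's
#' sensitivity excess, so activity features carry predictive signal.
#'
#' All randomness is governed by `config$rng_seed`; identical
#' configurations reproduce the cohort bit for bit.
#'
#' @param config A [sim_config()].
#' @param target_nh_fraction Desired cohort-level fraction of NH nights.
#' @param target_spread Half-width of the uniform per-patient scatter of
#'   the target fraction.
#' @param night_noise_sd Standard deviation (log scale) of the nightly
#'   insulin-sensitivity perturbation.
#' @param pa_prob Probability of an evening physical-activity bout.
#' @param pa_effect Sensitivity increase per 10,000 evening steps.
#' @param multiplier_range Bisection bracket for the overnight multiplier.
#' @param calib_iter Bisection iterations per patient.
#' @return An object of class `nh_cohort`.
#' @export
generate_cohort <- function(config = sim_config(),
                            target_nh_fraction = 1 / 3,
                            target_spread = 0.05,
                            night_noise_sd = 0.12,
                            pa_prob = 0.35, pa_effect = 0.5,
                            multiplier_range = c(1, 8),
                            calib_iter = 13L) {
  stopifnot(target_nh_fraction > 0, target_nh_fraction < 1)
  set.seed(config$rng_seed)
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  patients <- vector("list", config$n_patients)
  names(patients) <- ids

  for (i in seq_len(config$n_patients)) {
    body_mass <- stats::runif(1, 55, 90)
    vol_kg <- stats::runif(1, 1.6, 2.0)
    egp <- stats::runif(1, 0.9, 1.3)
    basal <- stats::runif(1, 0.7, 1.2)
    bio <- stats::runif(1, 0.8, 0.95)
    act_time <- stats::runif(1, 200, 260)
    # carb ratio consistent with the patient's own insulin sensitivity
    # (patients under MDI carry an approximately correct ratio), with a
    # +/-15% personal bias
    si <- egp / (basal / 60 * act_time / 4)
    cr_balanced <- si * (act_time / 4) * (vol_kg * body_mass) / (bio * 1000)
    carb_ratio <- min(max(cr_balanced * (1 + stats::runif(1, -0.15, 0.15)),
                          4), 30)
    params <- virtual_patient(
      patient_id = ids[i],
      body_mass = body_mass,
      glucose_dist_volume = vol_kg,
      basal_glucose = stats::runif(1, 125, 150),
      glucose_effectiveness = stats::runif(1, 0.005, 0.008),
      egp_rate = egp,
      basal_rate = basal,
      carb_ratio = carb_ratio,
      cho_bioavailability = bio,
      tau_max_meal = stats::runif(1, 60, 80),
      insulin_action_time = act_time
    )
    target_i <- min(max(
      target_nh_fraction + stats::runif(1, -target_spread, target_spread),
      0.02), 0.95)

    nights <- lapply(seq_len(config$n_nights), function(j) {
      draw_night_scenario(params, config, night_noise_sd, pa_prob, pa_effect)
    })

    # bisection on the overnight multiplier; NH fraction is monotone in the
    # multiplier because every night's glucose is pointwise decreasing in it
    lo <- multiplier_range[1]; hi <- multiplier_range[2]
    f_hi <- cohort_nh_fraction_at(params, hi, nights, config)
    f_lo <- cohort_nh_fraction_at(params, lo, nights, config)
    if (f_hi < target_i || f_lo > target_i) {
      stop(sprintf(
        paste0("calibration failed to bracket target for %s: NH fraction ",
               "is %.3f at multiplier %g and %.3f at %g (target %.3f)"),
        ids[i], f_lo, lo, f_hi, hi, target_i), call. = FALSE)
    }
    for (k in seq_len(calib_iter)) {
      mid <- (lo + hi) / 2
      if (cohort_nh_fraction_at(params, mid, nights, config) < target_i) {
        lo <- mid
      } else {
        hi <- mid
      }
    }
    params$overnight_sensitivity_multiplier <- hi

    nights <- lapply(seq_along(nights), function(j) {
      nt <- nights[[j]]
      tr <- simulate_cohort_night(params, nt, config)
      attr(tr, "profile") <- NULL
      nt$night_id <- j
      nt$trace <- tr
      nt$nh <- nh_overnight(tr, config$overnight_window)
      nt
    })
    patients[[i]] <- list(
      params = params, target_fraction = target_i,
      achieved_fraction = mean(vapply(nights, `[[`, numeric(1), "nh")),
      nights = nights)
  }

  structure(
    list(config = config, target_nh_fraction = target_nh_fraction,
         patients = patients),
    class = "nh_cohort")
}

#' Per-patient fraction of nights with nocturnal hypoglycemia
#'
#' @param cohort An `nh_cohort`.
#' @return Named numeric vector of per-patient NH-night fractions.
#' @export
nh_fraction <- function(cohort) {
  vapply(cohort$patients, `[[`, numeric(1), "achieved_fraction")
}

#' @export
print.nh_cohort <- function(x, ...) {
  fr <- nh_fraction(x)
  cat(sprintf(
    paste0("<nh_cohort> %d patients x %d nights (seed %d)\n",
           "  NH-night fraction: median %.3f (range %.3f-%.3f), ",
           "target %.3f\n"),
    length(x$patients), x$config$n_nights, x$config$rng_seed,
    stats::median(fr), min(fr), max(fr), x$target_nh_fraction))
  invisible(x)
}

#' Night records for a generated cohort
#'
#' Applies the preprocessing stage ([build_night_records()]) to the
#' sensor-realistic traces of a cohort: CGM noise retained, gap mask
#' applied, short gaps interpolated downstream.
#'
#' @param cohort An `nh_cohort`.
#' @return A flat list of `night_record` objects across all patients, with
#'   attribute `n_dropped`.
#' @export
night_records <- function(cohort) {
  all <- list(); dropped <- 0L; total <- 0L
  for (p in cohort$patients) {
    traces <- list(); sleep <- NULL; events <- NULL
    for (nt in p$nights) {
      tr <- nt$trace
      tr$values[nt$gap_mask] <- NA_real_
      traces[[as.character(nt$night_id)]] <- tr
      sleep <- rbind(sleep, data.frame(night_id = nt$night_id,
                                       onset = nt$onset))
      ev <- nt$events
      ev$night_id <- nt$night_id
      events <- rbind(events, ev)
    }
    recs <- suppressWarnings(build_night_records(traces, events, sleep))
    dropped <- dropped + attr(recs, "n_dropped")
    total <- total + attr(recs, "n_total")
    all <- c(all, recs)
  }
  structure(all, n_dropped = dropped, n_total = total)
}

#' Instance table for a generated cohort
#'
#' Convenience wrapper chaining [night_records()] and [build_instances()].
#'
#' @param cohort An `nh_cohort`.
#' @param include_pa Include the two physical-activity features?
#' @return Instance `data.frame` (see [build_instances()]).
#' @export
cohort_instances <- function(cohort, include_pa = TRUE) {
  build_instances(night_records(cohort), include_pa = include_pa)
}
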