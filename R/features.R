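#' Bolus on board
#'
#' Residual active rapid-acting insulin at time `t`, summing each earlier
#' bolus scaled by a remaining-fraction curve `R` with `R(0) = 1` and
#' `R(x) = 0` for `x >= 1`, where `x` is elapsed time over the insulin
#' action time. The default curve is linear decay, `R(x) = 1 - x`. Boluses
#' after `t` are ignored.
#'
#' @param boluses Data frame with columns `time` (min) and `magnitude` (U);
#'   rows of other kinds are ignored if a `kind` column is present.
#' @param t Evaluation time, minutes.
#' @param action_time Insulin action time, minutes (> 0; default 240).
#' @return Insulin on board, U.
#' @export
bolus_on_board <- function(boluses, t, action_time = 240) {
  if (action_time <= 0) stop("`action_time` must be positive", call. = FALSE)
  if (!nrow(boluses)) return(0)
  if ("kind" %in% names(boluses)) {
    boluses <- boluses[boluses$kind == "bolus", , drop = FALSE]
  }
  el <- t - boluses$time
  keep <- el >= 0
  if (!any(keep)) return(0)
  x <- el[keep] / action_time
  sum(boluses$magnitude[keep] * pmax(0, 1 - x))
}

#' Carbohydrate on board
#'
#' Ingested carbohydrate not yet absorbed into plasma at time `t`, under
#' the bi-exponential absorption model:
#' \eqn{COB(t) = \sum_i D_i f (1 + \Delta t_i/\tau_i) e^{-\Delta t_i/\tau_i}}.
#'
#' @param meals Data frame with columns `time`, `magnitude` (g) and
#'   `tau_max` (min); rows of other kinds are ignored if a `kind` column is
#'   present (both `meal` and `rescue_cho` count as carbohydrate).
#' @param t Evaluation time, minutes.
#' @param bioavailability Fraction of each dose that will appear in plasma.
#' @param default_tau Fallback `tau_max` (min) for rows lacking one.
#' @return Carbohydrate on board, g.
#' @export
cho_on_board <- function(meals, t, bioavailability = 1, default_tau = 40) {
  if (!nrow(meals)) return(0)
  if ("kind" %in% names(meals)) {
    meals <- meals[meals$kind %in% c("meal", "rescue_cho"), , drop = FALSE]
  }
  if (!nrow(meals)) return(0)
  el <- t - meals$time
  keep <- el >= 0
  if (!any(keep)) return(0)
  tau <- meals$tau_max[keep]
  tau[!is.finite(tau) | tau <= 0] <- default_tau
  sum(meals$magnitude[keep] * bioavailability *
        (1 - cho_absorbed_fraction(tau, el[keep])))
}

#' Activity on board
#'
#' Accumulated, exponentially decaying effect of physical activity:
#' \eqn{AOB(t) = \sum_i s_i e^{-\Delta t_i / \tau}} over step epochs before
#' `t`.
#'
#' @param steps Data frame with columns `time` and `magnitude` (step
#'   counts); rows of other kinds are ignored if a `kind` column exists.
#' @param t Evaluation time, minutes.
#' @param decay_time Decay time constant, minutes (> 0; default 60).
#' @return Dimensionless activity on board.
#' @export
activity_on_board <- function(steps, t, decay_time = 60) {
  if (decay_time <= 0) stop("`decay_time` must be positive", call. = FALSE)
  if (!nrow(steps)) return(0)
  if ("kind" %in% names(steps)) {
    steps <- steps[steps$kind == "steps", , drop = FALSE]
  }
  if (!nrow(steps)) return(0)
  el <- t - steps$time
  keep <- el >= 0
  if (!any(keep)) return(0)
  sum(steps$magnitude[keep] * exp(-el[keep] / decay_time))
}

#' Kovatchev low and high blood glucose risk indices
#'
#' Each reading `g` (mg/dL) is mapped through the symmetrizing transform
#' \eqn{f(g) = 1.509\,((\ln g)^{1.084} - 5.381)} and the risk
#' \eqn{r = 10 f(g)^2}. LBGI is the mean over all readings of the risk
#' restricted to `f < 0` (hypoglycemic side), HBGI the mean restricted to
#' `f > 0`; each reading therefore contributes to exactly one index or, at
#' the risk-neutral glucose, to neither.
#'
#' @param window A `glucose_trace` (missing readings are ignored) or a
#'   numeric vector of glucose values in mg/dL.
#' @return Named numeric vector `c(lbgi =, hbgi =)`.
#' @export
glycemic_risk_indices <- function(window) {
  g <- if (inherits(window, "glucose_trace")) window$values else window
  g <- g[!is.na(g)]
  if (!length(g)) stop("window has no non-missing readings", call. = FALSE)
  if (any(g <= 0)) stop("glucose readings must be positive", call. = FALSE)
  f <- 1.509 * (log(g)^1.084 - 5.381)
  risk <- 10 * f^2
  n <- length(g)
  c(lbgi = sum(risk[f < 0]) / n, hbgi = sum(risk[f > 0]) / n)
}

#' Area below the 70 mg/dL threshold
#'
#' Trapezoidal area of `max(0, 70 - g(t))` over the window, with threshold
#' crossings located by linear interpolation between adjacent samples.
#' Missing samples are skipped (the segment between their non-missing
#' neighbours is not counted).
#'
#' @param window A `glucose_trace`.
#' @param threshold Threshold in mg/dL (default 70).
#' @return Area in mg/dL * min.
#' @export
auc_below_70 <- function(window, threshold = 70) {
  tt <- trace_times(window)
  v <- window$values
  ok <- !is.na(v)
  tt <- tt[ok]; v <- v[ok]
  if (length(v) < 2L) return(0)
  a <- 0
  for (i in seq_len(length(v) - 1L)) {
    if (tt[i + 1L] - tt[i] > window$step + 1e-9) next   # gap: skip segment
    d1 <- threshold - v[i]; d2 <- threshold - v[i + 1L]
    h <- tt[i + 1L] - tt[i]
    if (d1 <= 0 && d2 <= 0) next
    if (d1 > 0 && d2 > 0) {
      a <- a + (d1 + d2) / 2 * h
    } else {
      # one side below threshold: triangle up to the crossing
      dlo <- max(d1, d2)
      a <- a + dlo^2 / (dlo - min(d1, d2)) * h / 2
    }
  }
  a
}

# canonical feature order (17 with physical activity, 15 without)
nh_feature_names <- function(include_pa = TRUE) {
  base <- c("cgm_t", paste0("cgm_mean_h", 1:6), "dbg_30", "dbg_60",
            "bob", "cob", "auc70", "lbgi", "hbgi", "roc_30")
  if (include_pa) c(base, "aob", "steps") else base
}

#' Build the feature vector for one night
#'
#' Computes the 17 time-domain features (15 when physical-activity
#' features are excluded) from the 6-h pre-sleep window of a night record:
#' the glucose at prediction time, six hourly means, the 30- and 60-min
#' glucose changes, bolus/carbohydrate/activity on board, the area below
#' 70 mg/dL, the low and high blood glucose risk indices, the 30-min rate
#' of change, and the daily step count. The instance is rejected (returns
#' `NULL`) when the reading at prediction time or at t-30/t-60 is missing
#' after interpolation, or when any hourly sub-window has no readings.
#'
#' @param record A `night_record`.
#' @param include_pa Include activity-on-board and daily steps?
#' @param action_time Insulin action time for [bolus_on_board()], min.
#' @param aob_decay Decay constant for [activity_on_board()], min.
#' @param bioavailability Carbohydrate bioavailability for
#'   [cho_on_board()].
#' @return Named numeric vector of length 17 (or 15), or `NULL` if the
#'   instance is unusable.
#' @export
build_feature_vector <- function(record, include_pa = TRUE,
                                 action_time = 240, aob_decay = 60,
                                 bioavailability = 1) {
  pre <- record$pre_window
  tt <- trace_times(pre)
  v <- pre$values
  # prediction time = most recent CGM sample at or before sleep onset
  cand <- which(tt <= record$sleep_onset + 1e-9)
  if (!length(cand)) return(NULL)
  t0 <- tt[max(cand)]
  if (record$sleep_onset - t0 > pre$step + 1e-9) return(NULL)

  at <- function(when) {
    i <- which.min(abs(tt - when))
    if (abs(tt[i] - when) > pre$step / 2 + 1e-9) return(NA_real_)
    v[i]
  }
  g_t <- at(t0)
  if (is.na(g_t)) return(NULL)
  g_30 <- at(t0 - 30); g_60 <- at(t0 - 60)
  if (is.na(g_30) || is.na(g_60)) return(NULL)

  hmeans <- numeric(6)
  for (h in 1:6) {
    inwin <- tt > t0 - 60 * h - 1e-9 & tt <= t0 - 60 * (h - 1) + 1e-9
    vals <- v[inwin & !is.na(v)]
    if (!length(vals)) return(NULL)
    hmeans[h] <- mean(vals)
  }

  ev <- record$events_pre
  risk <- glycemic_risk_indices(pre)
  out <- c(
    cgm_t = g_t,
    stats::setNames(hmeans, paste0("cgm_mean_h", 1:6)),
    dbg_30 = g_t - g_30,
    dbg_60 = g_t - g_60,
    bob = bolus_on_board(ev, t0, action_time),
    cob = cho_on_board(ev, t0, bioavailability),
    auc70 = auc_below_70(pre),
    lbgi = unname(risk["lbgi"]),
    hbgi = unname(risk["hbgi"]),
    roc_30 = (g_t - g_30) / 30
  )
  if (include_pa) {
    # "daily steps": calendar-day total over the scenario's waking day
    day_steps <- if (nrow(record$events)) {
      sum(record$events$magnitude[record$events$kind == "steps"])
    } else 0
    out <- c(out, aob = activity_on_board(ev, t0, aob_decay),
             steps = day_steps)
  }
  out
}

#' Build the instance table for a set of night records
#'
#' Applies [build_feature_vector()] to every labeled record and binds the
#' results with patient id, night id and the nocturnal-hypoglycemia label.
#' Records with undefined labels or rejected feature vectors are skipped.
#'
#' @param records List of `night_record` objects (e.g. from
#'   [build_night_records()] or [night_records()]).
#' @inheritParams build_feature_vector
#' @return A `data.frame` with columns `patient_id`, `night_id`, the
#'   feature columns in canonical order, and `label` (0/1).
#' @export
build_instances <- function(records, include_pa = TRUE, action_time = 240,
                            aob_decay = 60, bioavailability = 1) {
  rows <- lapply(records, function(rec) {
    if (is.na(rec$label)) return(NULL)
    fv <- build_feature_vector(rec, include_pa, action_time, aob_decay,
                               bioavailability)
    if (is.null(fv)) return(NULL)
    cbind(data.frame(patient_id = rec$patient_id, night_id = rec$night_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)), data.frame(label = rec$label))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(patient_id = character(0), night_id = integer(0),
                      label = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
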