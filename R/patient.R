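#' Construct a virtual T1D patient
#'
#' Parameters of the lumped glucose-insulin model used by
#' [simulate_night()]. The model keeps plasma glucose (mg/dL) and a remote
#' insulin-action compartment (U). Endogenous glucose production is balanced
#' against basal insulin action so that, absent meals, boluses and any
#' overnight sensitivity modification, glucose sits at `basal_glucose`
#' exactly. During the overnight window insulin action is scaled by
#' `overnight_sensitivity_multiplier` (>= 1), the stand-in for the
#' insulin-sensitivity modification that drives nocturnal hypoglycemia in
#' the study design.
#'
#' By default `insulin_sensitivity_base` is derived from the basal
#' equilibrium condition `egp_rate = SI * basal_insulin_on_board`, where the
#' basal on-board mass is `basal_rate/60 * action_tau` and
#' `action_tau = insulin_action_time / 4` is the remote-compartment time
#' constant. Supplying it explicitly overrides the equilibrium.
#'
#' @param patient_id Character id.
#' @param body_mass Body mass, kg.
#' @param glucose_dist_volume Glucose distribution volume, dL/kg.
#' @param basal_glucose Steady-state glucose under basal conditions, mg/dL.
#' @param glucose_effectiveness Insulin-independent fractional glucose
#'   clearance, 1/min.
#' @param egp_rate Endogenous glucose production, mg/dL/min.
#' @param basal_rate Slow-acting insulin expressed as a continuous basal
#'   rate, U/h.
#' @param carb_ratio Insulin-to-carbohydrate ratio, g/U.
#' @param cho_bioavailability Fraction of ingested carbohydrate appearing
#'   in plasma, in (0, 1].
#' @param tau_max_meal Time-to-peak of meal absorption, min.
#' @param insulin_action_time Duration of rapid-acting insulin action, min.
#' @param insulin_absorption_tau Time-to-peak of subcutaneous bolus
#'   absorption, min.
#' @param overnight_sensitivity_multiplier Factor (>= 1) scaling insulin
#'   action inside the overnight window.
#' @param noise_sd CGM sensor noise standard deviation, mg/dL.
#' @param insulin_sensitivity_base Glucose-lowering effect of on-board
#'   insulin, (mg/dL)/min per U; `NULL` derives it from the basal
#'   equilibrium.
#' @return An object of class `patient_params`.
#' @export
virtual_patient <- function(patient_id = "P1",
                            body_mass = 70,
                            glucose_dist_volume = 1.8,
                            basal_glucose = 130,
                            glucose_effectiveness = 0.0065,
                            egp_rate = 1.1,
                            basal_rate = 1.0,
                            carb_ratio = 10,
                            cho_bioavailability = 0.9,
                            tau_max_meal = 40,
                            insulin_action_time = 240,
                            insulin_absorption_tau = 45,
                            overnight_sensitivity_multiplier = 1,
                            noise_sd = 5,
                            insulin_sensitivity_base = NULL) {
  pos <- c(body_mass = body_mass, glucose_dist_volume = glucose_dist_volume,
           basal_glucose = basal_glucose,
           glucose_effectiveness = glucose_effectiveness,
           egp_rate = egp_rate, basal_rate = basal_rate,
           carb_ratio = carb_ratio, tau_max_meal = tau_max_meal,
           insulin_action_time = insulin_action_time,
           insulin_absorption_tau = insulin_absorption_tau)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    stop("patient parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cho_bioavailability <= 0 || cho_bioavailability > 1) {
    stop("`cho_bioavailability` must lie in (0, 1]", call. = FALSE)
  }
  if (overnight_sensitivity_multiplier < 1) {
    stop("`overnight_sensitivity_multiplier` must be >= 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)

  action_tau <- insulin_action_time / 4
  basal_iob <- basal_rate / 60 * action_tau   # U at basal equilibrium
  if (is.null(insulin_sensitivity_base)) {
    insulin_sensitivity_base <- egp_rate / basal_iob
  }
  if (insulin_sensitivity_base <= 0) {
    stop("`insulin_sensitivity_base` must be strictly positive", call. = FALSE)
  }

  structure(
    list(patient_id = as.character(patient_id),
         body_mass = body_mass,
         glucose_dist_volume = glucose_dist_volume,
         basal_glucose = basal_glucose,
         glucose_effectiveness = glucose_effectiveness,
         egp_rate = egp_rate,
         basal_rate = basal_rate,
         carb_ratio = carb_ratio,
         cho_bioavailability = cho_bioavailability,
         tau_max_meal = tau_max_meal,
         insulin_action_time = insulin_action_time,
         insulin_absorption_tau = insulin_absorption_tau,
         action_tau = action_tau,
         basal_iob = basal_iob,
         insulin_sensitivity_base = insulin_sensitivity_base,
         overnight_sensitivity_multiplier = overnight_sensitivity_multiplier,
         noise_sd = noise_sd),
    class = "patient_params"
  )
}

#' @export
print.patient_params <- function(x, ...) {
  cat(sprintf(
    paste0("<patient_params> %s: %g kg, basal %g mg/dL, basal insulin ",
           "%g U/h, CR %g g/U, overnight sensitivity x%.3g\n"),
    x$patient_id, x$body_mass, x$basal_glucose, x$basal_rate, x$carb_ratio,
    x$overnight_sensitivity_multiplier))
  invisible(x)
}

#' Scenario event table
#'
#' Builds the event log consumed by [simulate_night()]: a data frame with
#' columns `time` (minutes from scenario start), `kind` (one of `"meal"`,
#' `"bolus"`, `"steps"`, `"rescue_cho"`), `magnitude` (g CHO, U insulin or
#' step count) and `tau_max` (min, absorption time constant; `NA` for
#' boluses and steps).
#'
#' @param time,kind,magnitude,tau_max Vectors of equal length (or length 1,
#'   recycled) describing the events.
#' @return A `data.frame` sorted by time.
#' @export
scenario_events <- function(time = numeric(0), kind = character(0),
                            magnitude = numeric(0), tau_max = NA_real_) {
  if (length(tau_max) == 1L && length(time) != 1L) {
    tau_max <- rep(tau_max, length(time))
  }
  ev <- data.frame(time = as.numeric(time), kind = as.character(kind),
                   magnitude = as.numeric(magnitude),
                   tau_max = as.numeric(tau_max))
  if (nrow(ev)) {
    ok <- ev$kind %in% c("meal", "bolus", "steps", "rescue_cho")
    if (!all(ok)) stop("unknown event kind: ",
                       paste(unique(ev$kind[!ok]), collapse = ", "),
                       call. = FALSE)
    if (any(ev$magnitude < 0)) stop("event magnitudes must be >= 0", call. = FALSE)
    needs_tau <- ev$kind %in% c("meal", "rescue_cho")
    if (any(needs_tau & (!is.finite(ev$tau_max) | ev$tau_max <= 0))) {
      stop("meal and rescue_cho events need a positive `tau_max`", call. = FALSE)
    }
    ev <- ev[order(ev$time), , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}
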