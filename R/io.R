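#' Write a cohort to per-patient CSV files
#'
#' Creates one sub-directory per patient containing `cgm.csv` (night id,
#' scenario minute, clock time, glucose in mg/dL with gap-masked samples
#' left empty), `events.csv` (night id, minute, clock, kind, magnitude,
#' tau_max) and `sleep.csv` (night id, onset minute, onset clock time).
#'
#' @param cohort An `nh_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  org <- cohort$config$origin
  for (p in cohort$patients) {
    pd <- file.path(dir, p$params$patient_id)
    dir.create(pd, showWarnings = FALSE)
    cgm <- NULL; events <- NULL; sleep <- NULL
    for (nt in p$nights) {
      tt <- trace_times(nt$trace)
      vals <- nt$trace$values
      vals[nt$gap_mask] <- NA_real_
      cgm <- rbind(cgm, data.frame(
        night_id = nt$night_id, time_min = tt,
        clock = min_to_clock(tt, org),
        glucose_mgdl = round(vals, 2)))
      ev <- nt$events
      events <- rbind(events, data.frame(
        night_id = nt$night_id, time_min = ev$time,
        clock = min_to_clock(ev$time, org), kind = ev$kind,
        magnitude = round(ev$magnitude, 3), tau_max = ev$tau_max))
      sleep <- rbind(sleep, data.frame(
        night_id = nt$night_id, onset_min = round(nt$onset, 2),
        onset_clock = min_to_clock(nt$onset, org)))
    }
    utils::write.csv(cgm, file.path(pd, "cgm.csv"), row.names = FALSE,
                     na = "")
    utils::write.csv(events, file.path(pd, "events.csv"), row.names = FALSE)
    utils::write.csv(sleep, file.path(pd, "sleep.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read per-patient cohort CSV files
#'
#' Reads the directory layout written by [write_cohort_csv()] back into
#' the inputs of [build_night_records()]: for each patient a list with
#' `traces` (one `glucose_trace` per night), `events` and `sleep`.
#'
#' @param dir Directory containing one sub-directory per patient.
#' @param cgm_step CGM sampling interval of the stored traces, min.
#' @return Named list, one element per patient.
#' @export
read_cohort_csv <- function(dir, cgm_step = 15) {
  patients <- list.dirs(dir, recursive = FALSE)
  out <- list()
  for (pd in patients) {
    pid <- basename(pd)
    cgm <- utils::read.csv(file.path(pd, "cgm.csv"))
    events <- utils::read.csv(file.path(pd, "events.csv"))
    sleep <- utils::read.csv(file.path(pd, "sleep.csv"))
    traces <- lapply(split(cgm, cgm$night_id), function(d) {
      d <- d[order(d$time_min), ]
      glucose_trace(d$time_min[1], cgm_step, d$glucose_mgdl, pid)
    })
    ev <- data.frame(night_id = events$night_id, time = events$time_min,
                     kind = events$kind, magnitude = events$magnitude,
                     tau_max = events$tau_max)
    sl <- data.frame(night_id = sleep$night_id, onset = sleep$onset_min)
    out[[pid]] <- list(traces = traces, events = ev, sleep = sl)
  }
  out
}

#' Plot a glucose trace
#'
#' Base-graphics plot of a CGM trace with the hypoglycemia (70 mg/dL) and
#' hyperglycemia (180 mg/dL) thresholds, missing samples left as breaks.
#'
#' @param x A `glucose_trace`.
#' @param shade Optional scenario-minute interval to shade (e.g. the
#'   overnight window).
#' @param ... Passed to [plot()].
#' @export
plot.glucose_trace <- function(x, shade = NULL, ...) {
  tt <- trace_times(x) / 60
  plot(tt, x$values, type = "l", xlab = "time (h from scenario start)",
       ylab = "glucose (mg/dL)", ...)
  if (!is.null(shade)) {
    graphics::rect(shade[1] / 60, graphics::par("usr")[3], shade[2] / 60,
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("grey", 0.3), border = NA)
  }
  graphics::abline(h = c(70, 180), lty = 2, col = c("red", "orange"))
  invisible(x)
}
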