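#' Construct a CGM glucose trace
#'
#' A glucose trace is a regular grid of interstitial glucose readings
#' (mg/dL) with possible missing values, as produced by a CGM sensor
#' sampling every `step` minutes. Time is kept in minutes from an arbitrary
#' scenario origin; conversion to clock time is the caller's concern.
#'
#' @param start Time of the first sample, minutes from scenario origin.
#' @param step Sampling interval in minutes (> 0, constant).
#' @param values Numeric vector of glucose readings in mg/dL; `NA` marks a
#'   missing sample. Non-missing values must be positive.
#' @param patient_id Character patient identifier.
#' @return An object of class `glucose_trace`.
#' @export
glucose_trace <- function(start, step, values, patient_id = "P?") {
  stopifnot(length(step) == 1L, step > 0, length(values) >= 1L)
  if (any(!is.na(values) & values <= 0)) {
    stop("non-missing glucose values must be positive", call. = FALSE)
  }
  structure(
    list(start = as.numeric(start), step = as.numeric(step),
         values = as.numeric(values), patient_id = as.character(patient_id)),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<glucose_trace> %s: %d samples every %g min (%.1f h), %d missing\n",
    x$patient_id, n, x$step, n * x$step / 60, sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.glucose_trace <- function(x) length(x$values)

# sample times in minutes
trace_times <- function(trace) {
  trace$start + trace$step * (seq_along(trace$values) - 1L)
}

#' Extract a sub-window of a trace
#'
#' Returns the samples with time in `[from, to]` (inclusive) as a new
#' `glucose_trace`.
#'
#' @param trace A `glucose_trace`.
#' @param from,to Window bounds in minutes from the scenario origin.
#' @return A `glucose_trace` covering the requested window (may be empty).
#' @export
trace_window <- function(trace, from, to) {
  tt <- trace_times(trace)
  keep <- tt >= from - 1e-9 & tt <= to + 1e-9
  if (!any(keep)) {
    return(structure(
      list(start = from, step = trace$step, values = numeric(0),
           patient_id = trace$patient_id),
      class = "glucose_trace"))
  }
  glucose_trace(tt[which(keep)[1L]], trace$step, trace$values[keep],
                trace$patient_id)
}
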