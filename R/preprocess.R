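#' Linearly interpolate short CGM gaps
#'
#' Interior runs of missing readings whose duration is at most `max_gap`
#' minutes are filled by linear interpolation between the flanking
#' observations; longer runs and gaps touching either edge of the trace are
#' left missing. Observed values are never altered.
#'
#' @param trace A [glucose_trace()].
#' @param max_gap Longest gap (minutes) that is filled; default 120.
#' @return A `glucose_trace` with short gaps filled.
#' @export
interpolate_gaps <- function(trace, max_gap = 120) {
  v <- trace$values
  if (!anyNA(v)) return(trace)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(v)
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    s <- starts[j]; e <- ends[j]
    if (s == 1L || e == n) next                       # edge gap
    if (r$lengths[j] * trace$step > max_gap) next     # too long
    lo <- v[s - 1L]; hi <- v[e + 1L]
    k <- r$lengths[j]
    v[s:e] <- lo + (hi - lo) * seq_len(k) / (k + 1L)
  }
  glucose_trace(trace$start, trace$step, v, trace$patient_id)
}

# longest run of consecutive non-missing readings strictly below `thr`
longest_low_run <- function(values, thr = 70) {
  low <- !is.na(values) & values < thr
  if (!any(low)) return(0L)
  max(rle(low)$lengths[rle(low)$values])
}

#' Label a night for nocturnal hypoglycemia
#'
#' A night is positive when some run of at least three consecutive
#' non-missing readings all lie below 70 mg/dL (3.9 mmol/L) in the 6-h
#' window after sleep onset; a missing sample breaks a run. If no
#' qualifying run exists but a gap longer than `max_gap` minutes overlaps
#' the window, the rule is unevaluable and `NA` is returned; an empty
#' window is likewise `NA`.
#'
#' @param post_window `glucose_trace` covering the 6 h after sleep onset.
#' @param min_run Number of consecutive low readings defining an episode.
#' @param threshold Hypoglycemia threshold, mg/dL.
#' @param max_gap Gap length (minutes) above which an episode-free window
#'   is considered unevaluable.
#' @return `1L`, `0L`, or `NA_integer_` when unevaluable.
#' @export
label_night <- function(post_window, min_run = 3L, threshold = 70,
                        max_gap = 120) {
  v <- post_window$values
  if (length(v) == 0L || all(is.na(v))) return(NA_integer_)
  if (longest_low_run(v, threshold) >= min_run) return(1L)
  if (anyNA(v)) {
    r <- rle(is.na(v))
    if (any(r$values & r$lengths * post_window$step > max_gap)) {
      return(NA_integer_)
    }
  }
  0L
}

#' Assemble per-night records from raw logs
#'
#' Cuts, for every sleep onset, the 6-h pre-sleep window (feature window)
#' and the 6-h post-sleep window (labeling window) from the interpolated
#' CGM trace, and labels the night with [label_night()]. Records are
#' dropped when the sleep onset falls outside trace coverage or when the
#' pre-sleep window retains an uninterpolated gap longer than `max_gap`
#' minutes.
#'
#' @param cgm Named list of `glucose_trace` objects, one per night id, or a
#'   single trace shared by all nights.
#' @param events Data frame of scenario events with a `night_id` column and
#'   the [scenario_events()] columns.
#' @param sleep Data frame with columns `night_id` and `onset` (minutes on
#'   the trace clock).
#' @param window Half-window length in minutes (default 360 = 6 h).
#' @param max_gap Interpolation/drop threshold in minutes.
#' @return A list of `night_record` objects, with attributes `n_dropped`
#'   and `n_total`.
#' @export
build_night_records <- function(cgm, events, sleep, window = 360,
                                max_gap = 120) {
  stopifnot(is.data.frame(sleep), all(c("night_id", "onset") %in% names(sleep)))
  shared <- inherits(cgm, "glucose_trace")
  records <- vector("list", nrow(sleep))
  dropped <- 0L
  for (i in seq_len(nrow(sleep))) {
    nid <- sleep$night_id[i]
    onset <- sleep$onset[i]
    trace <- if (shared) cgm else cgm[[as.character(nid)]]
    if (is.null(trace)) {
      warning("no CGM trace for night ", nid, "; skipped", call. = FALSE)
      dropped <- dropped + 1L
      next
    }
    tt <- trace_times(trace)
    if (onset < tt[1L] || onset > tt[length(tt)]) {
      warning("sleep onset outside trace coverage for night ", nid,
              "; skipped", call. = FALSE)
      dropped <- dropped + 1L
      next
    }
    filled <- interpolate_gaps(trace, max_gap)
    pre <- trace_window(filled, onset - window, onset)
    post <- trace_window(filled, onset, onset + window)
    pre_na <- rle(is.na(pre$values))
    if (any(pre_na$values & pre_na$lengths * pre$step > max_gap)) {
      dropped <- dropped + 1L
      next
    }
    ev_night <- events[events$night_id == nid, , drop = FALSE]
    rec <- structure(
      list(patient_id = trace$patient_id, night_id = nid,
           sleep_onset = onset, pre_window = pre, post_window = post,
           events = ev_night,
           events_pre = ev_night[ev_night$time <= onset, , drop = FALSE],
           label = label_night(post, max_gap = max_gap)),
      class = "night_record")
    records[[i]] <- rec
  }
  records <- Filter(Negate(is.null), records)
  structure(records, n_dropped = dropped, n_total = nrow(sleep))
}

#' @export
print.night_record <- function(x, ...) {
  cat(sprintf("<night_record> %s night %s, onset t=%g min, label=%s\n",
              x$patient_id, x$night_id, x$sleep_onset,
              ifelse(is.na(x$label), "undefined", x$label)))
  invisible(x)
}
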