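# Telemetry phenotyping: the onset phenotype is the first day on which the
# 4-hour windowed mean body temperature falls to or below 25 C, expressed
# in days from hibernaculum placement (day 0 = placement, prior days
# negative). Windows are aligned to local midnight; a window straddling
# nothing (empty) is omitted; a window is dated by the day containing its
# start.

#' Average a telemetry trace over non-overlapping windows
#'
#' @param trace a \code{telemetry_trace} (list with \code{readings}
#'   containing POSIXct \code{timestamp} and \code{temp_c}).
#' @param window_hours window width; windows are aligned to local midnight
#'   and cover [start, start + window_hours).
#' @return data.frame(window_start, mean_temp, n_readings), empty windows
#'   omitted, ordered by time.
#' @export
window_average <- function(trace, window_hours = 4) {
  r <- trace$readings
  stopifnot(nrow(r) >= 1)
  ts <- as.numeric(r$timestamp)
  day0 <- as.numeric(trunc(r$timestamp[1], "days"))
  w <- floor((ts - day0) / (window_hours * 3600))
  mean_temp <- tapply(r$temp_c, w, mean)
  n_readings <- tapply(r$temp_c, w, length)
  wk <- as.numeric(names(mean_temp))
  out <- data.frame(
    window_start = as.POSIXct(day0 + wk * window_hours * 3600,
                              origin = "1970-01-01", tz = "UTC"),
    mean_temp = as.numeric(mean_temp),
    n_readings = as.integer(n_readings))
  out[order(out$window_start), , drop = FALSE]
}

#' Call the first torpor window
#'
#' The first bout of torpor is the earliest window whose mean body
#' temperature falls to or below the threshold (inclusive).
#'
#' @param windows output of [window_average()].
#' @param threshold temperature threshold in degrees C.
#' @return one-row data.frame (window_start, mean_temp), or NULL if the
#'   trace never crosses the threshold.
#' @export
call_first_torpor <- function(windows, threshold = 25.0) {
  hit <- which(windows$mean_temp <= threshold)
  if (!length(hit)) return(NULL)
  windows[hit[1], c("window_start", "mean_temp"), drop = FALSE]
}

#' Qualify a torpor call and center it on hibernaculum placement
#'
#' The onset day is the calendar day containing the hit window's start,
#' minus the placement day, so placement is day 0 and earlier days are
#' negative. A call qualifies only if onset occurred at least
#' \code{min_monitoring_days} after monitoring start and the trace has no
#' recording gap longer than \code{max_gap_factor} times the cadence before
#' onset ("continuous monitoring").
#'
#' @param call output of [call_first_torpor()] (may be NULL).
#' @param trace the \code{telemetry_trace} the call came from; must carry a
#'   \code{placement} timestamp.
#' @param min_monitoring_days minimum continuous-monitoring span before a
#'   call qualifies.
#' @param max_gap_factor largest tolerated gap, as a multiple of the median
#'   cadence.
#' @return an \code{onset_call}: list(sample, onset_day, qualified, reason,
#'   window_start, window_mean).
#' @export
qualify_and_center <- function(call, trace, min_monitoring_days = 10,
                               max_gap_factor = 2) {
  if (is.null(trace$placement) || is.na(trace$placement))
    stop("trace carries no placement timestamp")
  if (is.null(call) || nrow(call) == 0) {
    return(structure(list(sample = trace$sample, onset_day = NA_integer_,
                          qualified = FALSE, reason = "no torpor detected",
                          window_start = NULL, window_mean = NA_real_),
                     class = "onset_call"))
  }
  onset_date <- trunc(call$window_start[1], "days")
  placement_date <- trunc(trace$placement, "days")
  onset_day <- as.integer(round(as.numeric(
    difftime(onset_date, placement_date, units = "days"))))
  mon_start <- trace$monitoring_start %||% trace$readings$timestamp[1]
  span <- as.numeric(difftime(call$window_start[1], mon_start,
                              units = "days"))
  reason <- NULL
  if (span < min_monitoring_days)
    reason <- sprintf("onset %.1f days after monitoring start (< %d)",
                      span, min_monitoring_days)
  pre <- trace$readings$timestamp[trace$readings$timestamp <=
                                    call$window_start[1]]
  if (length(pre) > 2) {
    gaps <- diff(as.numeric(pre))
    cadence <- median(gaps)
    if (max(gaps) > max_gap_factor * cadence)
      reason <- c(reason, sprintf(
        "recording gap of %.0f min before onset (cadence %.0f min)",
        max(gaps) / 60, cadence / 60))
  }
  structure(list(sample = trace$sample, onset_day = onset_day,
                 qualified = is.null(reason),
                 reason = if (is.null(reason)) NA_character_
                          else paste(reason, collapse = "; "),
                 window_start = call$window_start[1],
                 window_mean = call$mean_temp[1]),
            class = "onset_call")
}

#' @export
print.onset_call <- function(x, ...) {
  cat("onset_call:", x$sample, "day", x$onset_day,
      if (isTRUE(x$qualified)) "(qualified)" else paste0("(disqualified: ",
                                                         x$reason, ")"), "\n")
  invisible(x)
}

#' Call torpor onset for a telemetry trace end to end
#'
#' Convenience wrapper: [window_average()], [call_first_torpor()],
#' [qualify_and_center()].
#'
#' @inheritParams window_average
#' @inheritParams call_first_torpor
#' @inheritParams qualify_and_center
#' @return an \code{onset_call}.
#' @export
call_onset <- function(trace, window_hours = 4, threshold = 25.0,
                       min_monitoring_days = 10, max_gap_factor = 2) {
  w <- window_average(trace, window_hours)
  qualify_and_center(call_first_torpor(w, threshold), trace,
                     min_monitoring_days, max_gap_factor)
}
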