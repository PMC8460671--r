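# local maxima with topographic prominence; returns indices into v.
# runs of equal samples are collapsed first so a flat-topped peak counts once
find_peaks <- function(v, min_prominence = 0) {
  r <- rle(as.numeric(v))
  w <- r$values
  m <- length(w)
  if (m < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(w[2:(m - 1L)] > w[1:(m - 2L)] & w[2:(m - 1L)] > w[3:m]) + 1L
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    higher_l <- which(w[seq_len(p - 1L)] > w[p])
    base_l <- min(w[(if (length(higher_l)) max(higher_l) else 1L):p])
    right <- w[p:m]
    higher_r <- which(right > w[p])
    base_r <- min(right[1:(if (length(higher_r)) min(higher_r) else m - p + 1L)])
    keep[i] <- (w[p] - max(base_l, base_r)) >= min_prominence
  }
  (starts[cand[keep]] + ends[cand[keep]]) %/% 2L
}

#' Averaged per-beat peak velocity of a Doppler trace
#'
#' Detects individual beats in a coronary blood-flow velocity trace as
#' local maxima with topographic prominence of at least
#' `prominence_frac` of the trace amplitude and returns the mean of the
#' per-beat maxima — the per-time-point velocity value of the flow-reserve
#' protocol.
#'
#' @param trace numeric vector of velocity samples, or a data.frame with a
#'   `velocity_mm_s` column (e.g. one element of
#'   [simulate_doppler()]`$traces`); uniform sampling assumed.
#' @param min_beats minimum number of detected beats (default 3); fewer is
#'   an error.
#' @param prominence_frac prominence threshold as a fraction of the trace
#'   amplitude (default 0.25).
#'
#' @return Mean of the per-beat maximum velocities.
#' @export
beat_peak_velocity <- function(trace, min_beats = 3, prominence_frac = 0.25) {
  v <- if (is.data.frame(trace)) trace$velocity_mm_s else as.numeric(trace)
  stop_if(length(v) < 3L, "trace too short")
  amp <- diff(range(v))
  peaks <- find_peaks(v, min_prominence = prominence_frac * amp)
  stop_if(length(peaks) < min_beats,
          sprintf("only %d beat(s) detected (need >= %d)",
                  length(peaks), min_beats))
  mean(v[peaks])
}

#' Per-time-point peak-velocity course
#'
#' @param schedule_min measurement times in minutes; must include the
#'   pre-injection baseline t = 0.
#' @param peak_vel_mm_s averaged per-beat peak velocity at each time point
#'   (positive).
#' @param hr_bpm optional heart rate per time point (descriptive only).
#' @return Object of class `"velocity_course"` (data.frame `time_min`,
#'   `peak_vel_mm_s`, and `hr_bpm` when given).
#' @export
velocity_course <- function(schedule_min, peak_vel_mm_s, hr_bpm = NULL) {
  stop_if(length(schedule_min) != length(peak_vel_mm_s),
          "schedule and velocities differ in length")
  stop_if(!(0 %in% schedule_min), "baseline (t = 0) measurement is missing")
  stop_if(any(diff(schedule_min) <= 0), "schedule must be strictly increasing")
  stop_if(any(peak_vel_mm_s <= 0), "velocities must be positive")
  df <- data.frame(time_min = schedule_min, peak_vel_mm_s = peak_vel_mm_s)
  if (!is.null(hr_bpm)) df$hr_bpm <- hr_bpm
  structure(df, class = c("velocity_course", "data.frame"))
}

#' Reduce simulated Doppler traces to a velocity course
#'
#' Applies [beat_peak_velocity()] to each scheduled trace.
#'
#' @param traces a [simulate_doppler()] object.
#' @inheritParams beat_peak_velocity
#' @return A [velocity_course()].
#' @export
course_from_traces <- function(traces, min_beats = 3, prominence_frac = 0.25) {
  stop_if(!inherits(traces, "doppler_traces"), "'traces' must be doppler_traces")
  v <- vapply(traces$traces, beat_peak_velocity, numeric(1),
              min_beats = min_beats, prominence_frac = prominence_frac)
  velocity_course(traces$schedule_min, v, hr_bpm = traces$hr_bpm)
}

#' Coronary flow reserve from a peak-velocity course
#'
#' The reserve at each post-injection time point is the ratio of its peak
#' velocity to the pre-injection baseline. Summaries: `peak_reserve`, the
#' maximum over post-injection points, and `mean_reserve`, the arithmetic
#' mean of the reserve over the scheduled points falling inside the
#' averaging window (default 6 to 18 min inclusive).
#'
#' @param course a [velocity_course()].
#' @param window_min inclusive averaging window in minutes (default
#'   `c(6, 18)`).
#' @return Object of class `"cfr_summary"`: list with `cfr_course`
#'   (data.frame `time_min`, `reserve`), `peak_reserve`, `mean_reserve`,
#'   `window_min`, `window_times`.
#' @export
flow_reserve <- function(course, window_min = c(6, 18)) {
  stop_if(!inherits(course, "velocity_course"), "'course' must be a velocity_course")
  base <- course$peak_vel_mm_s[course$time_min == 0]
  stop_if(length(base) != 1L || base <= 0, "baseline velocity missing")
  reserve <- course$peak_vel_mm_s / base
  post <- course$time_min > 0
  win <- course$time_min >= window_min[1] & course$time_min <= window_min[2]
  structure(list(
    cfr_course = data.frame(time_min = course$time_min, reserve = reserve),
    peak_reserve = max(reserve[post]),
    mean_reserve = mean(reserve[win]),
    window_min = window_min,
    window_times = course$time_min[win]),
    class = "cfr_summary")
}

#' @export
print.cfr_summary <- function(x, ...) {
  cat(sprintf("Coronary flow reserve: peak %.2f; mean %.2f over [%g, %g] min (%d points)\n",
              x$peak_reserve, x$mean_reserve, x$window_min[1], x$window_min[2],
              length(x$window_times)))
  invisible(x)
}
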