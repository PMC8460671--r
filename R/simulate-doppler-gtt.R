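#' Simulate Doppler coronary velocity traces over a vasodilator protocol
#'
#' One velocity trace (default 2000 ms at 1 kHz) per scheduled time point.
#' Each trace is a periodic, diastolic-dominant waveform at the scheduled
#' heart rate, scaled by the reserve profile: baseline peak velocity times
#' `reserve_profile(t)`. The default profiles emulate a regadenoson-type
#' response — roughly a doubling of peak velocity developing within a few
#' minutes and waning after ~18 min, with a concomitant heart-rate rise.
#'
#' @param baseline_vel_mm_s baseline per-beat peak velocity (default 300).
#' @param reserve_profile function of time (min) returning the velocity
#'   scale factor (must be 1 at t = 0), or a numeric vector matched to
#'   `schedule_min`.
#' @param hr_profile heart rate in bpm: function of time (min) or vector
#'   matched to `schedule_min`.
#' @param schedule_min measurement times in minutes, 0 = pre-injection
#'   baseline; default is the 18-point vasodilation protocol
#'   `{0, 1..10, 12, 14, 16, 18, 20, 25, 40}`.
#' @param duration_ms trace length (default 2000).
#' @param noise_mm_s additive Gaussian noise sd on the velocity samples.
#' @param seed integer seed.
#'
#' @return Object of class `"doppler_traces"`: list with `schedule_min`
#'   and `traces` (one data.frame `time_ms`, `velocity_mm_s` per time point).
#' @export
simulate_doppler <- function(baseline_vel_mm_s = 300,
                             reserve_profile = NULL, hr_profile = NULL,
                             schedule_min = c(0, 1:10, 12, 14, 16, 18, 20, 25, 40),
                             duration_ms = 2000, noise_mm_s = 0, seed = 1L) {
  check_number(baseline_vel_mm_s, "baseline_vel_mm_s", lower = 0)
  stop_if(!(0 %in% schedule_min), "schedule must include the baseline t = 0")
  stop_if(any(diff(sort(schedule_min)) <= 0), "schedule times must be distinct")
  if (is.null(reserve_profile))
    reserve_profile <- function(t) 1 + 1.0 * (1 - exp(-t / 2)) * exp(-pmax(0, t - 18) / 8)
  if (is.null(hr_profile))
    hr_profile <- function(t) 500 + 50 * (1 - exp(-t / 2)) * exp(-pmax(0, t - 18) / 10)
  sched <- sort(schedule_min)
  reserve <- if (is.function(reserve_profile)) reserve_profile(sched) else {
    stop_if(length(reserve_profile) != length(sched),
            "'reserve_profile' vector must match the schedule length")
    reserve_profile
  }
  hr <- if (is.function(hr_profile)) hr_profile(sched) else {
    stop_if(length(hr_profile) != length(sched),
            "'hr_profile' vector must match the schedule length")
    hr_profile
  }
  stop_if(abs(reserve[sched == 0] - 1) > 1e-9, "reserve profile must be 1 at baseline")

  tm <- seq(0, duration_ms - 1)
  traces <- with_seed(seed, lapply(seq_along(sched), function(i) {
    period <- 60000 / hr[i]
    phase <- (tm %% period) / period
    # single dominant (diastolic) peak per beat, nonzero systolic floor
    v <- baseline_vel_mm_s * reserve[i] * (0.2 + 0.8 * sin(pi * phase)^4)
    if (noise_mm_s > 0) v <- v + rnorm(length(v), sd = noise_mm_s)
    data.frame(time_ms = tm, velocity_mm_s = v)
  }))
  structure(list(schedule_min = sched, hr_bpm = hr, traces = traces),
            class = "doppler_traces")
}

#' Glucose-tolerance-test curve specification
#'
#' Blood glucose sampled at the standard intraperitoneal GTT schedule
#' (0, 15, 30, 45, 60, 120 min after a 2 g/kg bolus). The underlying curve
#' is baseline plus a gamma-variate excursion peaking at `peak_time_min`.
#'
#' @param baseline_mgdl fasting glucose (default 100 mg/dl).
#' @param peak_mgdl post-bolus peak glucose of the reference (control)
#'   curve (default 250 mg/dl).
#' @param peak_time_min time of the excursion peak (default 30 min).
#' @param decay gamma-variate shape exponent controlling the return to
#'   baseline (default 1; larger = faster return).
#' @param sample_times_min sampling schedule (default `{0,15,30,45,60,120}`).
#' @return Object of class `"gtt_spec"`.
#' @export
gtt_spec <- function(baseline_mgdl = 100, peak_mgdl = 250, peak_time_min = 30,
                     decay = 1, sample_times_min = c(0, 15, 30, 45, 60, 120)) {
  check_number(baseline_mgdl, "baseline_mgdl", lower = 0)
  check_number(peak_mgdl, "peak_mgdl", lower = baseline_mgdl)
  check_number(peak_time_min, "peak_time_min", lower = 0)
  check_number(decay, "decay", lower = 0)
  stop_if(any(diff(sample_times_min) <= 0) || sample_times_min[1] != 0,
          "'sample_times_min' must start at 0 and be strictly increasing")
  structure(list(baseline_mgdl = baseline_mgdl, peak_mgdl = peak_mgdl,
                 peak_time_min = peak_time_min, decay = decay,
                 sample_times_min = as.numeric(sample_times_min)),
            class = "gtt_spec")
}

# normalised excursion shape (peak 1 at peak_time)
gtt_shape <- function(t, spec) {
  ifelse(t <= 0, 0,
         (t / spec$peak_time_min)^spec$decay *
           exp(spec$decay * (1 - t / spec$peak_time_min)))
}

#' Group scale factor achieving a target total-AUC ratio
#'
#' The insulin-resistant (HFD) phenotype is generated by inflating the
#' incremental glucose excursion by a factor `s`; this helper solves for
#' the `s` that makes the noiseless total AUC exactly `auc_ratio` times the
#' control AUC on the [gtt_spec()] sampling schedule (trapezoid rule).
#' The default ratio 2 reproduces the twofold AUC increase of the 14-day
#' high-fat-diet condition.
#'
#' @param spec a [gtt_spec()].
#' @param auc_ratio target HFD/control total-AUC ratio (default 2).
#' @return Scalar excursion scale factor.
#' @export
gtt_group_scale <- function(spec = gtt_spec(), auc_ratio = 2) {
  check_number(auc_ratio, "auc_ratio", lower = 0)
  tt <- spec$sample_times_min
  base_auc <- trapz(tt, rep(spec$baseline_mgdl, length(tt)))
  exc_auc <- trapz(tt, (spec$peak_mgdl - spec$baseline_mgdl) * gtt_shape(tt, spec))
  1 + (auc_ratio - 1) * (base_auc + exc_auc) / exc_auc
}

#' Simulate a glucose-tolerance-test curve
#'
#' @param spec a [gtt_spec()].
#' @param group_scale multiplier on the incremental excursion above
#'   baseline; 1 for controls, [gtt_group_scale()] for the HFD phenotype.
#' @param noise_mgdl Gaussian measurement noise sd (mg/dl).
#' @param seed integer seed.
#' @return Object of class `"gtt_curve"`: data.frame `time_min`,
#'   `glucose_mgdl`.
#' @export
simulate_gtt <- function(spec = gtt_spec(), group_scale = 1,
                         noise_mgdl = 0, seed = 1L) {
  stop_if(!inherits(spec, "gtt_spec"), "'spec' must be a gtt_spec")
  check_number(group_scale, "group_scale", lower = 0)
  tt <- spec$sample_times_min
  g <- spec$baseline_mgdl +
    group_scale * (spec$peak_mgdl - spec$baseline_mgdl) * gtt_shape(tt, spec)
  if (noise_mgdl > 0)
    g <- with_seed(seed, pmax(0, g + rnorm(length(g), sd = noise_mgdl)))
  structure(data.frame(time_min = tt, glucose_mgdl = g),
            class = c("gtt_curve", "data.frame"))
}
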