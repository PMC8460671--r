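#' Glucose-tolerance-test area under the curve
#'
#' Total trapezoidal area of the blood-glucose concentration-time curve
#' (mg/dl x min) over the sampling interval; by convention the total area
#' from zero, not the incremental area above the fasting baseline
#' (available with `incremental = TRUE`).
#'
#' @param curve a [simulate_gtt()] `"gtt_curve"`, or a numeric glucose
#'   vector when `times_min` is given.
#' @param times_min sampling times in minutes (ignored for a `gtt_curve`).
#' @param incremental subtract the fasting (first) value first.
#' @return AUC in mg/dl x min.
#' @export
#' @examples
#' gtt_auc(rep(100, 6), times_min = c(0, 15, 30, 45, 60, 120))  # 12000
gtt_auc <- function(curve, times_min = NULL, incremental = FALSE) {
  if (inherits(curve, "gtt_curve")) {
    times_min <- curve$time_min
    g <- curve$glucose_mgdl
  } else {
    g <- as.numeric(curve)
  }
  stop_if(is.null(times_min), "'times_min' is required")
  stop_if(length(times_min) != length(g), "times and glucose differ in length")
  stop_if(length(g) < 2L, "need at least 2 samples")
  stop_if(any(diff(times_min) <= 0),
          "'times_min' must be strictly increasing (no duplicates)")
  stop_if(any(g < 0), "glucose must be nonnegative")
  if (incremental) g <- g - g[1]
  trapz(times_min, g)
}

#' Body-mass change relative to the pre-diet mass
#'
#' @param day diet day of each measurement; day 0 (pre-diet) must be
#'   present.
#' @param mass_g body mass in grams.
#' @return data.frame `day`, `pct_change` with
#'   `100 * (mass(d) - mass(0)) / mass(0)`.
#' @export
body_mass_change <- function(day, mass_g) {
  stop_if(length(day) != length(mass_g), "'day' and 'mass_g' differ in length")
  i0 <- which(day == 0)
  stop_if(length(i0) != 1L, "exactly one day-0 (pre-diet) mass is required")
  stop_if(mass_g[i0] <= 0, "pre-diet mass must be positive")
  data.frame(day = day, pct_change = 100 * (mass_g - mass_g[i0]) / mass_g[i0])
}
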