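#' Simulate a multi-flip-angle SPGR image series from a phantom
#'
#' Produces one magnitude image per protocol flip angle whose noiseless
#' pixel means follow [spgr_signal()] applied to the phantom's ground-truth
#' T1/M0 maps. Noise is additive Gaussian on the magnitude images; the SNR
#' is defined as the mean noiseless myocardial signal at the dynamic angle
#' divided by the noise standard deviation. The Rician floor is neglected —
#' at the SNR regime emulated here the Gaussian model keeps the dynamic
#' inversion analytic.
#'
#' @param phantom a [make_phantom()] object.
#' @param protocol an [spgr_protocol()].
#' @param snr signal-to-noise ratio (> 0); `Inf` for noiseless data.
#' @param seed integer seed; identical inputs give bit-identical series.
#'
#' @return Object of class `"spgr_series"`: list with `images` (array
#'   `grid x grid x n_angles`), `flip_angles_deg`, `tr_ms`, `te_ms`,
#'   `noise_sd`, `snr`, `vfa_fittable` (FALSE when fewer than two angles)
#'   and the originating `phantom`.
#' @export
simulate_vfa_series <- function(phantom, protocol = spgr_protocol(),
                                snr = Inf, seed = 1L) {
  stop_if(!inherits(phantom, "phantom"), "'phantom' must be a phantom")
  stop_if(!inherits(protocol, "spgr_protocol"), "'protocol' must be an spgr_protocol")
  stop_if(!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0,
          "'snr' must be a positive number or Inf")
  angles <- protocol$flip_angles_deg
  n <- phantom$spec$grid_size
  imgs <- array(0, dim = c(n, n, length(angles)))
  tissue <- phantom$label_map != 0L
  for (k in seq_along(angles)) {
    s <- matrix(0, n, n)
    s[tissue] <- spgr_signal(phantom$m0_map[tissue], phantom$t1_map[tissue],
                             protocol$tr_ms, angles[k])
    imgs[, , k] <- s
  }
  noise_sd <- 0
  if (is.finite(snr)) {
    ref <- spgr_signal(phantom$spec$m0_scale, phantom$spec$t1_myo_ms,
                       protocol$tr_ms, protocol$fa_dynamic_deg)
    noise_sd <- ref / snr
    imgs <- with_seed(seed, imgs + rnorm(length(imgs), sd = noise_sd))
  }
  structure(list(images = imgs, flip_angles_deg = angles,
                 tr_ms = protocol$tr_ms, te_ms = protocol$te_ms,
                 noise_sd = noise_sd, snr = snr,
                 vfa_fittable = length(angles) >= 2L,
                 phantom = phantom),
            class = "spgr_series")
}

#' Group-dependent myocardial T1 response to NOS inhibition
#'
#' Parametric percent-change curve of myocardial T1 after systemic
#' L-NAME-type NOS inhibition. The control phenotype rises to about +15%
#' of baseline with the maximum at 8 min post-injection; the high-fat-diet
#' phenotype is blunted (smaller, possibly negative peak). The temporal
#' shape is a gamma-variate,
#' \eqn{\phi(t) = (t/t_p)^a \exp\{a(1 - t/t_p)\}}, normalised to 1 at the
#' peak time \eqn{t_p}; with the default exponent `a = 0.8` the curve rises
#' quickly and then declines slowly, emulating a rise-to-plateau response.
#'
#' @param group `"control"` or `"hfd"`.
#' @param peak_delta_t1_pct peak percent change of myocardial T1; defaults
#'   +15 (control) and +4 (hfd; blunted response).
#' @param peak_time_min time of the peak in minutes (default 8).
#' @param timepoints_min mid-times of the six post-injection scans; the
#'   default `{4, 8, 12, 16, 20, 24}` assumes six back-to-back 4-min
#'   acquisitions.
#' @param shape_exponent gamma-variate exponent `a` (> 0); smaller values
#'   give a flatter post-peak plateau.
#'
#' @return Object of class `"group_response_spec"`.
#' @export
group_response_spec <- function(group = c("control", "hfd"),
                                peak_delta_t1_pct = NULL,
                                peak_time_min = 8,
                                timepoints_min = c(4, 8, 12, 16, 20, 24),
                                shape_exponent = 0.8) {
  group <- match.arg(group)
  if (is.null(peak_delta_t1_pct))
    peak_delta_t1_pct <- if (group == "control") 15 else 4
  if (group == "hfd")
    stop_if(abs(peak_delta_t1_pct) >= 15,
            "hfd peak magnitude must be smaller than the control peak (15%)")
  check_number(peak_time_min, "peak_time_min", lower = 0)
  stop_if(length(timepoints_min) < 2L || any(diff(timepoints_min) <= 0),
          "'timepoints_min' must be strictly increasing")
  stop_if(any(timepoints_min <= 0), "'timepoints_min' must be positive")
  check_number(shape_exponent, "shape_exponent", lower = 0)
  structure(list(group = group, peak_delta_t1_pct = peak_delta_t1_pct,
                 peak_time_min = peak_time_min,
                 timepoints_min = as.numeric(timepoints_min),
                 shape_exponent = shape_exponent),
            class = "group_response_spec")
}

# normalised gamma-variate response shape, phi(peak_time) = 1
response_shape <- function(t, peak_time, a) {
  ifelse(t <= 0, 0, (t / peak_time)^a * exp(a * (1 - t / peak_time)))
}

#' Simulate the dynamic post-injection scan series
#'
#' Generates the six single-flip-angle magnitude images acquired after NOS
#' inhibition. The myocardial T1 at scan time t is the baseline value
#' scaled by `1 + peak/100 * phi(t)` with the response shape of
#' [group_response_spec()]; blood and background are unchanged. Images are
#' simulated at the protocol's dynamic angle with the same Gaussian noise
#' model (and SNR definition) as [simulate_vfa_series()].
#'
#' @inheritParams simulate_vfa_series
#' @param resp a [group_response_spec()].
#'
#' @return A list with `series` (class `"spgr_series_dynamic"`: `images`
#'   array `grid x grid x n_times`, `times_min`, `fa_deg`, `tr_ms`,
#'   `noise_sd`) and `truth` (data.frame `time_min`, `t1_myo_ms`,
#'   `delta_t1_pct` — the ground-truth myocardial T1 course).
#' @export
simulate_lname_response <- function(phantom, protocol = spgr_protocol(),
                                    resp = group_response_spec("control"),
                                    snr = Inf, seed = 1L) {
  stop_if(!inherits(phantom, "phantom"), "'phantom' must be a phantom")
  stop_if(!inherits(resp, "group_response_spec"),
          "'resp' must be a group_response_spec")
  times <- resp$timepoints_min
  phi <- response_shape(times, resp$peak_time_min, resp$shape_exponent)
  delta_pct <- resp$peak_delta_t1_pct * phi
  t1_course <- phantom$spec$t1_myo_ms * (1 + delta_pct / 100)

  n <- phantom$spec$grid_size
  imgs <- array(0, dim = c(n, n, length(times)))
  myo <- phantom$label_map == 1L
  cav <- phantom$label_map == 2L
  fa <- protocol$fa_dynamic_deg
  for (k in seq_along(times)) {
    s <- matrix(0, n, n)
    s[myo] <- spgr_signal(phantom$m0_map[myo], t1_course[k], protocol$tr_ms, fa)
    s[cav] <- spgr_signal(phantom$m0_map[cav], phantom$t1_map[cav],
                          protocol$tr_ms, fa)
    imgs[, , k] <- s
  }
  noise_sd <- 0
  if (is.finite(snr)) {
    stop_if(snr <= 0, "'snr' must be positive")
    ref <- spgr_signal(phantom$spec$m0_scale, phantom$spec$t1_myo_ms,
                       protocol$tr_ms, fa)
    noise_sd <- ref / snr
    imgs <- with_seed(seed + 1L, imgs + rnorm(length(imgs), sd = noise_sd))
  }
  series <- structure(list(images = imgs, times_min = times, fa_deg = fa,
                           tr_ms = protocol$tr_ms, noise_sd = noise_sd),
                      class = "spgr_series_dynamic")
  truth <- data.frame(time_min = times, t1_myo_ms = t1_course,
                      delta_t1_pct = delta_pct)
  list(series = series, truth = truth)
}
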