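#' LV time-volume-curve specification
#'
#' Parameters of a synthetic four-phase LV time-volume curve (TVC) over one
#' cardiac cycle, sampled on a uniform frame grid starting at end-diastole.
#' Before noise the curve is exactly piecewise linear: ejection ramp
#' EDV -> ESV, flat isovolumic relaxation, filling ramp ESV -> EDV, flat
#' isovolumic contraction.
#'
#' @param edv_ul,esv_ul end-diastolic and end-systolic volumes in microlitres,
#'   `0 < esv < edv`. Defaults 50/20 ul are typical of a healthy adult mouse.
#' @param rr_ms cardiac cycle length in ms (default 120, i.e. 500 bpm).
#' @param n_frames frames per cycle, >= 20 (default 60).
#' @param phase_fractions fractions of the RR interval occupied by ejection,
#'   isovolumic relaxation, filling and isovolumic contraction (ET, IVRT,
#'   FT, IVCT); each positive, summing to 1.
#' @param bw_g optional body weight in grams (for the cardiac index).
#'
#' @return Object of class `"tvc_spec"`.
#' @export
tvc_spec <- function(edv_ul = 50, esv_ul = 20, rr_ms = 120, n_frames = 60,
                     phase_fractions = c(et = 0.30, ivrt = 0.10,
                                         ft = 0.45, ivct = 0.15),
                     bw_g = NULL) {
  check_number(esv_ul, "esv_ul", lower = 0)
  check_number(edv_ul, "edv_ul", lower = esv_ul)
  check_number(rr_ms, "rr_ms", lower = 0)
  stop_if(!is_count(n_frames) || n_frames < 20, "'n_frames' must be an integer >= 20")
  stop_if(length(phase_fractions) != 4L || any(phase_fractions <= 0) ||
            abs(sum(phase_fractions) - 1) > 1e-8,
          "'phase_fractions' must be four positive fractions summing to 1")
  if (!is.null(bw_g)) check_number(bw_g, "bw_g", lower = 0)
  structure(list(edv_ul = edv_ul, esv_ul = esv_ul, rr_ms = rr_ms,
                 n_frames = as.integer(n_frames),
                 phase_fractions = as.numeric(phase_fractions), bw_g = bw_g),
            class = "tvc_spec")
}

# noiseless piecewise-linear TVC evaluated at normalised times t in [0,1)
tvc_truth_volume <- function(t, spec) {
  f <- spec$phase_fractions
  k <- cumsum(f)[1:3]                      # knots: end-ET, end-IVRT, end-FT
  edv <- spec$edv_ul; esv <- spec$esv_ul
  v <- numeric(length(t))
  seg1 <- t < k[1]
  v[seg1] <- edv - (edv - esv) * t[seg1] / f[1]
  v[t >= k[1] & t < k[2]] <- esv
  seg3 <- t >= k[2] & t < k[3]
  v[seg3] <- esv + (edv - esv) * (t[seg3] - k[2]) / f[3]
  v[t >= k[3]] <- edv
  v
}

#' Simulate a noisy LV time-volume curve
#'
#' Samples the exact four-phase piecewise-linear TVC of [tvc_spec()] at
#' `n_frames` uniform times in `[0, 1)` and adds seeded Gaussian noise.
#' The true interior knot positions (fractions of RR) are attached as
#' attribute `"truth"` for parameter-recovery studies.
#'
#' @param spec a [tvc_spec()].
#' @param noise_ul Gaussian noise standard deviation in microlitres.
#' @param seed integer seed.
#'
#' @return A [tvc()] object.
#' @export
simulate_tvc <- function(spec = tvc_spec(), noise_ul = 0, seed = 1L) {
  stop_if(!inherits(spec, "tvc_spec"), "'spec' must be a tvc_spec")
  stop_if(noise_ul < 0, "'noise_ul' must be nonnegative")
  t <- (seq_len(spec$n_frames) - 1L) / spec$n_frames
  v <- tvc_truth_volume(t, spec)
  if (noise_ul > 0)
    v <- with_seed(seed, v + rnorm(length(v), sd = noise_ul))
  out <- tvc(t, v, rr_ms = spec$rr_ms, bw_g = spec$bw_g)
  attr(out, "truth") <- list(
    knots_norm = cumsum(spec$phase_fractions)[1:3],
    sv_ul = spec$edv_ul - spec$esv_ul,
    er_sv_rr = 1 / spec$phase_fractions[1],
    fr_sv_rr = 1 / spec$phase_fractions[3])
  out
}

# temporal contraction profile: 0 at end-diastole, 1 at end-systole,
# optional hold (diastolic lag), smooth relaxation back to 0
contraction_profile <- function(t, t_peak = 0.35, lag = 0.05) {
  stopifnot(t_peak > 0, t_peak + lag < 1)
  phi <- numeric(length(t))
  rise <- t <= t_peak
  phi[rise] <- (1 - cos(pi * t[rise] / t_peak)) / 2
  hold <- t > t_peak & t <= t_peak + lag
  phi[hold] <- 1
  rel <- t > t_peak + lag
  phi[rel] <- (1 + cos(pi * (t[rel] - t_peak - lag) / (1 - t_peak - lag))) / 2
  phi
}

#' Simulate tracked myocardial point trajectories on a deforming ring
#'
#' Material points on two concentric layers (endocardial and epicardial) of
#' a myocardial annulus contract circumferentially and thicken radially
#' over one cycle, then relax. The layer radii are moved so that the
#' analytic strains are exact in closed form for the estimator of
#' [strain_from_trajectories()]: the sector-averaged linear circumferential
#' strain equals \eqn{-(s)\phi(t)} and the wall-thickness-based linear
#' radial strain equals \eqn{+w\,\phi(t)}, where `s` is the peak
#' circumferential shortening, `w` the peak wall thickening and
#' \eqn{\phi} the temporal contraction profile (peak 1 at end-systole).
#'
#' Concretely, with mid-wall radius R, half-thickness d, circumferential
#' scale \eqn{c(t) = 1 - s\phi(t)} and thickness scale
#' \eqn{h(t) = 1 + w\phi(t)}, the two layers move as
#' \eqn{r_\pm(t) = (R \pm d)\,[c(t) \pm (d/R)(h(t) - c(t))]}, which keeps
#' the mean of the per-point radius ratios exactly `c(t)` and the wall
#' thickness exactly `2 d h(t)`.
#'
#' @param n_points total number of tracked points; an even multiple of 16
#'   so every one of the 8 sectors holds both layers (default 48).
#' @param n_frames frames per cycle (default 60).
#' @param peak_circ_shortening peak fractional circumferential shortening
#'   `s` in (0, 1) (default 0.10).
#' @param wall_thickening peak fractional wall thickening `w` in (0, 1)
#'   (default 0.30).
#' @param diastolic_lag fraction of the cycle the deformation is held at
#'   its peak before relaxation (default 0.05).
#' @param t_peak end-systolic time as fraction of the cycle (default 0.35).
#' @param mid_radius_px,half_thickness_px reference mid-wall radius and
#'   half wall thickness (arbitrary length units).
#'
#' @return data.frame `point_id`, `frame` (0-based; frame 0 is the
#'   reference), `x`, `y`, with attribute `"truth"`: list of `t_norm`,
#'   `ecc_linear`, `err_linear` analytic mean strain curves.
#' @export
simulate_ring_motion <- function(n_points = 48, n_frames = 60,
                                 peak_circ_shortening = 0.10,
                                 wall_thickening = 0.30,
                                 diastolic_lag = 0.05, t_peak = 0.35,
                                 mid_radius_px = 10, half_thickness_px = 1.5) {
  stop_if(!is_count(n_points) || n_points < 16 || n_points %% 2 != 0,
          "'n_points' must be an even integer >= 16")
  stop_if(!is_count(n_frames) || n_frames < 8, "'n_frames' must be an integer >= 8")
  check_number(peak_circ_shortening, "peak_circ_shortening", lower = 0, upper = 1)
  check_number(wall_thickening, "wall_thickening", lower = 0, upper = 1,
               strict = FALSE)
  check_number(mid_radius_px, "mid_radius_px", lower = 0)
  check_number(half_thickness_px, "half_thickness_px",
               lower = 0, upper = mid_radius_px)

  n_ang <- n_points %/% 2L
  # half-step offset keeps points away from sector boundaries
  theta <- 2 * pi * (seq_len(n_ang) - 0.5) / n_ang
  t <- (seq_len(n_frames) - 1L) / n_frames
  phi <- contraction_profile(t, t_peak = t_peak, lag = diastolic_lag)
  cc <- 1 - peak_circ_shortening * phi
  hh <- 1 + wall_thickening * phi
  R <- mid_radius_px; d <- half_thickness_px
  lam_out <- cc + (d / R) * (hh - cc)
  lam_in  <- cc - (d / R) * (hh - cc)

  grid <- expand.grid(ang = seq_len(n_ang), layer = c(-1, 1))
  r0 <- R + grid$layer * d
  res <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    lam <- ifelse(grid$layer > 0, lam_out[k], lam_in[k])
    r <- r0 * lam
    res[[k]] <- data.frame(point_id = seq_len(n_points), frame = k - 1L,
                           x = r * cos(theta[grid$ang]),
                           y = r * sin(theta[grid$ang]))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "truth") <- list(t_norm = t,
                             ecc_linear = cc - 1,
                             err_linear = hh - 1)
  out
}
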