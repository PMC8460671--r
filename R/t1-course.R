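#' Fit a per-pixel T1 map from a multi-angle SPGR series
#'
#' Applies the linearised VFA fit ([fit_vfa_t1()]) pixelwise to an
#' [simulate_vfa_series()]-style series (or any list with an `images`
#' array, `flip_angles_deg` and `tr_ms`).
#'
#' @param series an `"spgr_series"` object.
#' @param roi_mask optional logical matrix marking the myocardial ROI;
#'   defaults to the phantom's myocardium mask when the series carries one.
#'
#' @return Object of class `"t1_map"`: list with matrices `t1_ms`, `m0`,
#'   logical `fit_ok`, `roi_mask`, and the protocol scalars `tr_ms`,
#'   `fa_dynamic_deg`.
#' @export
fit_t1_map <- function(series, roi_mask = NULL) {
  stop_if(is.null(series$images) || is.null(series$flip_angles_deg),
          "'series' must carry an image stack and flip angles")
  stop_if(!isTRUE(series$vfa_fittable) && length(series$flip_angles_deg) < 2L,
          "series is not fittable by VFA (fewer than two flip angles)")
  dm <- dim(series$images)
  sig <- matrix(series$images, nrow = dm[1] * dm[2], ncol = dm[3])
  fit <- fit_vfa_t1(sig, series$flip_angles_deg, series$tr_ms)
  shape <- function(v) matrix(v, dm[1], dm[2])
  if (is.null(roi_mask) && !is.null(series$phantom))
    roi_mask <- series$phantom$roi_mask
  fa_dyn <- if (!is.null(series$fa_dynamic_deg)) series$fa_dynamic_deg
            else max(series$flip_angles_deg)
  structure(list(t1_ms = shape(fit$t1_ms), m0 = shape(fit$m0),
                 fit_ok = shape(fit$fit_ok), roi_mask = roi_mask,
                 tr_ms = series$tr_ms, fa_dynamic_deg = fa_dyn),
            class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  ok <- x$fit_ok
  cat("VFA T1 map: ", sum(ok), "/", length(ok), " pixels fitted\n", sep = "")
  if (!is.null(x$roi_mask)) {
    sel <- x$roi_mask & ok
    cat(sprintf("  ROI: %d px, mean T1 = %.0f ms\n",
                sum(x$roi_mask), mean(x$t1_ms[sel])))
  }
  invisible(x)
}

#' Myocardial percent T1-change time course after NOS inhibition
#'
#' For each dynamic post-injection image, every ROI pixel's post-injection
#' T1 is recovered from the post/pre signal ratio at the dynamic flip angle
#' via [invert_dynamic_t1()] (M0 assumed unchanged by the injection); the
#' valid pixels are then averaged over the whole myocardial ROI and the
#' change is expressed as percent of the baseline ROI-mean T1.
#'
#' The averaging order is pixelwise inversion first, ROI mean second.
#' Pixels whose inversion is out of range at a given time point are
#' excluded from that time point's mean and counted; a time point with more
#' than 50% invalid ROI pixels is flagged (`warn_flag`), not dropped.
#'
#' @param pre_map a [fit_t1_map()] baseline map.
#' @param dynamic an `"spgr_series_dynamic"` object (images + times).
#' @param roi_mask logical ROI; defaults to `pre_map$roi_mask`.
#' @param pre_image optional measured pre-injection image at the dynamic
#'   angle; when `NULL` the reference signal is predicted from the fitted
#'   baseline map through the SPGR model.
#'
#' @return Object of class `"delta_t1_course"`: list with `times_min`,
#'   `delta_t1_pct`, `baseline_t1_ms`, `n_valid`, `n_invalid`, `warn_flag`.
#' @export
delta_t1_course <- function(pre_map, dynamic, roi_mask = NULL,
                            pre_image = NULL) {
  stop_if(!inherits(pre_map, "t1_map"), "'pre_map' must be a t1_map")
  stop_if(is.null(dynamic$images) || is.null(dynamic$times_min),
          "'dynamic' must carry images and times_min")
  times <- dynamic$times_min
  stop_if(any(diff(times) <= 0), "dynamic times must be strictly increasing")
  if (is.null(roi_mask)) roi_mask <- pre_map$roi_mask
  stop_if(is.null(roi_mask) || !any(roi_mask), "myocardial ROI is empty")

  fa <- if (!is.null(dynamic$fa_deg)) dynamic$fa_deg else pre_map$fa_dynamic_deg
  tr <- pre_map$tr_ms
  sel <- roi_mask & pre_map$fit_ok
  stop_if(!any(sel), "no valid baseline fit inside the ROI")
  t1_pre <- pre_map$t1_ms[sel]
  s_pre <- if (is.null(pre_image)) {
    spgr_signal(pre_map$m0[sel], t1_pre, tr, fa)
  } else pre_image[sel]
  stop_if(any(s_pre <= 0), "nonpositive pre-injection reference signal in ROI")

  baseline <- mean(t1_pre)
  nt <- length(times)
  delta <- numeric(nt); n_valid <- integer(nt); warn_flag <- logical(nt)
  for (k in seq_len(nt)) {
    ratio <- dynamic$images[, , k][sel] / s_pre
    inv <- invert_dynamic_t1(ratio, t1_pre, fa, tr)
    n_valid[k] <- sum(inv$valid)
    warn_flag[k] <- n_valid[k] < 0.5 * length(t1_pre)
    if (warn_flag[k])
      warning(sprintf("time point %g min: %d/%d ROI pixels invalid",
                      times[k], length(t1_pre) - n_valid[k], length(t1_pre)))
    post_mean <- mean(inv$t1_post_ms[inv$valid])
    delta[k] <- 100 * (post_mean - baseline) / baseline
  }
  structure(list(times_min = times, delta_t1_pct = delta,
                 baseline_t1_ms = baseline, n_valid = n_valid,
                 n_invalid = length(t1_pre) - n_valid,
                 warn_flag = warn_flag),
            class = "delta_t1_course")
}

#' @export
print.delta_t1_course <- function(x, ...) {
  cat("Myocardial delta-T1 time course (baseline ",
      sprintf("%.0f", x$baseline_t1_ms), " ms)\n", sep = "")
  print(data.frame(time_min = x$times_min,
                   delta_t1_pct = round(x$delta_t1_pct, 2)), row.names = FALSE)
  cat(sprintf("cumulative delta-T1: %.1f %%*min\n", cumulative_delta_t1(x)))
  invisible(x)
}

#' @export
plot.delta_t1_course <- function(x, ...) {
  graphics::plot(c(0, x$times_min), c(0, x$delta_t1_pct), type = "b",
                 xlab = "time post-injection (min)",
                 ylab = expression(Delta * T[1] ~ "(% of baseline)"), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Cumulative delta-T1: area under the percent T1-change curve
#'
#' Signed trapezoidal area of the percent T1-change vs post-injection-time
#' curve, in %·min — the endothelial NO-dependent function index. Since the
#' change is zero at the moment of injection by definition, an implicit
#' anchor (0 min, 0%) is prepended whenever the course does not itself
#' include t = 0. Negative excursions subtract.
#'
#' @param course a [delta_t1_course()] object, or a numeric vector of
#'   percent changes when `times_min` is given.
#' @param times_min time points in minutes (ignored when `course` is a
#'   `delta_t1_course`).
#' @return Area in %·min.
#' @export
#' @examples
#' cumulative_delta_t1(rep(15, 7), times_min = seq(0, 24, 4))  # 360
cumulative_delta_t1 <- function(course, times_min = NULL) {
  if (inherits(course, "delta_t1_course")) {
    times_min <- course$times_min
    y <- course$delta_t1_pct
  } else {
    y <- as.numeric(course)
  }
  stop_if(is.null(times_min), "'times_min' is required")
  stop_if(length(times_min) != length(y), "times and values differ in length")
  stop_if(any(diff(times_min) <= 0), "'times_min' must be strictly increasing")
  if (times_min[1] > 0) {          # anchor at injection: delta-T1(0) = 0
    times_min <- c(0, times_min)
    y <- c(0, y)
  }
  stop_if(length(y) < 2L, "need at least 2 time points")
  trapz(times_min, y)
}
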