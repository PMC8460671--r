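#' Sector strain curves from tracked myocardial point trajectories
#'
#' Computes circumferential (Ecc) and radial (Err) strain-time curves in
#' eight angular sectors from material-point trajectories on a short-axis
#' myocardial cross-section. Frame 0 is the reference configuration
#' (end-diastole), so all strains are 0 at t = 0.
#'
#' Per point, the circumferential stretch is the ratio of its distance to
#' the centroid, \eqn{\lambda_c = r(t)/r(0)}; the radial stretch is
#' estimated per sector from the wall-thickness change: the points of a
#' sector are split at the sector's mean reference radius into an inner and
#' an outer layer and \eqn{\lambda_r(t)} is the ratio of the layer-mean
#' radial separation to its reference value. Strains are
#' \eqn{\lambda - 1} (linear/engineering convention) or
#' \eqn{(\lambda^2 - 1)/2} (Green-Lagrange). Points are binned into eight
#' sectors by their reference angle and per-point Ecc values are
#' sector-averaged. The centroid is recomputed per frame (mean point
#' position) unless a fixed one is supplied, which makes the strains
#' invariant to rigid translation; distances to the centroid make them
#' invariant to rigid rotation.
#'
#' @param trajectories data.frame with columns `point_id`, `frame`
#'   (0-based, frame 0 = reference), `x`, `y`; every point must be present
#'   in every frame.
#' @param centroid optional fixed centroid `c(x, y)`; default: per-frame
#'   mean point position.
#' @param n_sectors number of angular sectors (default 8).
#' @param convention `"linear"` or `"green_lagrange"`.
#'
#' @return Object of class `"strain_curves"`: list with `t_norm`, `ecc`
#'   and `err` (matrices `n_sectors x n_frames`), `n_sectors`,
#'   `convention`.
#' @export
strain_from_trajectories <- function(trajectories, centroid = NULL,
                                     n_sectors = 8,
                                     convention = c("linear", "green_lagrange")) {
  convention <- match.arg(convention)
  need <- c("point_id", "frame", "x", "y")
  stop_if(!all(need %in% names(trajectories)),
          "trajectories need columns point_id, frame, x, y")
  frames <- sort(unique(trajectories$frame))
  pts <- sort(unique(trajectories$point_id))
  np <- length(pts); nf <- length(frames)
  stop_if(nrow(trajectories) != np * nf,
          "every point must be tracked in every frame")

  ord <- order(trajectories$frame, trajectories$point_id)
  xs <- matrix(trajectories$x[ord], np, nf)
  ys <- matrix(trajectories$y[ord], np, nf)
  if (is.null(centroid)) {
    cx <- colMeans(xs); cy <- colMeans(ys)
  } else {
    cx <- rep(centroid[1], nf); cy <- rep(centroid[2], nf)
  }
  rx <- sweep(xs, 2L, cx); ry <- sweep(ys, 2L, cy)
  r <- sqrt(rx^2 + ry^2)
  stop_if(any(r[, 1] < 1e-9), "a point coincides with the centroid")

  ang0 <- atan2(ry[, 1], rx[, 1])
  sector <- findInterval(ang0, seq(-pi, pi, length.out = n_sectors + 1),
                         rightmost.closed = TRUE)
  stop_if(any(tabulate(sector, n_sectors) < 3L),
          "each sector needs at least 3 points")

  to_strain <- function(lambda) {
    if (convention == "linear") lambda - 1 else (lambda^2 - 1) / 2
  }
  lam_c <- r / r[, 1]
  ecc <- matrix(NA_real_, n_sectors, nf)
  err <- matrix(NA_real_, n_sectors, nf)
  for (s in seq_len(n_sectors)) {
    in_s <- sector == s
    ecc[s, ] <- colMeans(to_strain(lam_c[in_s, , drop = FALSE]))
    r0s <- r[in_s, 1]
    outer_l <- r0s > mean(r0s)
    if (any(outer_l) && any(!outer_l)) {
      thick <- colMeans(r[in_s, , drop = FALSE][outer_l, , drop = FALSE]) -
        colMeans(r[in_s, , drop = FALSE][!outer_l, , drop = FALSE])
      err[s, ] <- to_strain(thick / thick[1])
    }
  }
  if (anyNA(err))
    message("radial strain unavailable: no transmural spread of points")
  t_norm <- (frames - frames[1]) / nf
  structure(list(t_norm = t_norm, ecc = ecc, err = err,
                 n_sectors = n_sectors, convention = convention),
            class = "strain_curves")
}

#' Assemble sector strain curves from precomputed values
#'
#' Container constructor for workflows whose tagging software already
#' exports per-sector strain-time curves.
#'
#' @param t_norm frame times as fractions of the cycle, starting at 0.
#' @param ecc,err numeric matrices `n_sectors x n_frames` (circumferential
#'   and radial strain); `err` may be `NULL` when unavailable.
#' @param convention `"linear"` or `"green_lagrange"`.
#' @return Object of class `"strain_curves"`.
#' @export
strain_curves <- function(t_norm, ecc, err = NULL,
                          convention = c("linear", "green_lagrange")) {
  convention <- match.arg(convention)
  ecc <- as.matrix(ecc)
  stop_if(ncol(ecc) != length(t_norm), "'ecc' must be n_sectors x n_frames")
  stop_if(t_norm[1] != 0, "curves must start at the reference frame t = 0")
  stop_if(any(abs(ecc[, 1]) > 1e-9), "strain at t = 0 must be 0")
  if (is.null(err)) {
    err <- matrix(NA_real_, nrow(ecc), ncol(ecc))
  } else {
    err <- as.matrix(err)
    stop_if(!all(dim(err) == dim(ecc)), "'err' must match 'ecc' in shape")
    stop_if(any(abs(err[, 1]) > 1e-9), "strain at t = 0 must be 0")
  }
  structure(list(t_norm = as.numeric(t_norm), ecc = ecc, err = err,
                 n_sectors = nrow(ecc), convention = convention),
            class = "strain_curves")
}

#' @export
print.strain_curves <- function(x, ...) {
  cat(x$n_sectors, "-sector strain curves (", x$convention, "), ",
      length(x$t_norm), " frames\n", sep = "")
  m <- colMeans(x$ecc)
  cat(sprintf("  peak mean Ecc %.3f", min(m)))
  if (!anyNA(x$err)) cat(sprintf("; peak mean Err %.3f", max(colMeans(x$err))))
  cat("\n")
  invisible(x)
}

# derivative on a uniform grid: central differences inside,
# second-order one-sided at the ends
ddt <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * dt)
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * dt)
  d
}

#' Scalar strain indices from sector strain curves
#'
#' Averages the sector curves, then derives: peak Ecc (most negative mean
#' circumferential strain) and peak Err (most positive mean radial strain);
#' strain at one third of diastole; and peak systolic/diastolic strain
#' rates. Systole is defined as `[0, t_peak]` where `t_peak` is the time of
#' peak |mean Ecc|; diastole is the remainder of the cycle, and the
#' "1/3 diastole" time is `t_peak + (1 - t_peak)/3` (values linearly
#' interpolated between frames). Strain rates are derivatives with respect
#' to the normalised cycle time (units: strain per cycle): the systolic
#' rate is the extremal rate in systole in the direction of deformation,
#' the diastolic rate the extremal opposite-signed rate in diastole.
#'
#' @param curves a [strain_from_trajectories()] object.
#' @return Object of class `"strain_indices"`: list with `peak_ecc`,
#'   `peak_err`, `t_peak`, `ecc_third_diastole`, `err_third_diastole`,
#'   `sr_sys_cc`, `sr_dia_cc`, `sr_sys_rr`, `sr_dia_rr`.
#' @export
strain_indices <- function(curves) {
  stop_if(!inherits(curves, "strain_curves"), "'curves' must be strain_curves")
  t <- curves$t_norm
  stop_if(any(diff(t) <= 0), "'t_norm' must be strictly increasing")
  ecc <- colMeans(curves$ecc)
  has_err <- !anyNA(curves$err)
  err <- if (has_err) colMeans(curves$err) else rep(NA_real_, length(t))

  ip <- which.max(abs(ecc))
  t_peak <- t[ip]
  sys_i <- which(t <= t_peak)
  dia_i <- which(t > t_peak)
  if (length(dia_i) == 0L) dia_i <- length(t)

  dt <- t[2] - t[1]
  sr_cc <- ddt(ecc, dt)
  sr_rr <- if (has_err) ddt(err, dt) else rep(NA_real_, length(t))

  t3 <- t_peak + (1 - t_peak) / 3
  interp <- function(y) {
    if (anyNA(y)) return(NA_real_)
    approx(t, y, xout = t3, rule = 2)$y
  }
  structure(list(
    peak_ecc = min(ecc), peak_err = if (has_err) max(err) else NA_real_,
    t_peak = t_peak,
    ecc_third_diastole = interp(ecc), err_third_diastole = interp(err),
    sr_sys_cc = min(sr_cc[sys_i]), sr_dia_cc = max(sr_cc[dia_i]),
    sr_sys_rr = if (has_err) max(sr_rr[sys_i]) else NA_real_,
    sr_dia_rr = if (has_err) min(sr_rr[dia_i]) else NA_real_),
    class = "strain_indices")
}

#' @export
print.strain_indices <- function(x, ...) {
  cat(sprintf("peak Ecc %.3f, peak Err %.3f (end-systole at t = %.2f)\n",
              x$peak_ecc, x$peak_err, x$t_peak))
  cat(sprintf("1/3-diastole Ecc %.3f, Err %.3f\n",
              x$ecc_third_diastole, x$err_third_diastole))
  cat(sprintf("SR (per cycle): sys Ecc %.2f, dia Ecc %.2f, sys Err %.2f, dia Err %.2f\n",
              x$sr_sys_cc, x$sr_dia_cc, x$sr_sys_rr, x$sr_dia_rr))
  invisible(x)
}
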