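#' LV time-volume curve container
#'
#' One cardiac cycle of LV cavity volumes on a normalised time grid. The
#' curve is conventionally ordered to start at end-diastole (the acquisition
#' trigger); [roll_tvc()] re-bases a curve that starts elsewhere.
#'
#' @param t_norm frame times as fractions of the RR interval, strictly
#'   increasing in `[0, 1)`; at least 20 frames.
#' @param volume_ul LV cavity volume per frame, in microlitres, > 0.
#' @param rr_ms cardiac cycle length in ms.
#' @param bw_g optional body weight in grams (enables BSA/cardiac index).
#'
#' @return Object of class `"tvc"`: data.frame `t_norm`, `volume_ul` with
#'   attributes `rr_ms`, `hr_bpm`, `bw_g`.
#' @export
tvc <- function(t_norm, volume_ul, rr_ms, bw_g = NULL) {
  stop_if(length(t_norm) != length(volume_ul), "time and volume lengths differ")
  stop_if(length(t_norm) < 20L, "a TVC needs at least 20 frames")
  stop_if(any(diff(t_norm) <= 0) || any(t_norm < 0) || any(t_norm >= 1),
          "'t_norm' must be strictly increasing within [0, 1)")
  stop_if(any(volume_ul <= 0), "volumes must be positive")
  check_number(rr_ms, "rr_ms", lower = 0)
  if (!is.null(bw_g)) check_number(bw_g, "bw_g", lower = 0)
  structure(data.frame(t_norm = t_norm, volume_ul = volume_ul),
            rr_ms = rr_ms, hr_bpm = 60000 / rr_ms, bw_g = bw_g,
            class = c("tvc", "data.frame"))
}

#' Roll a time-volume curve to start at its maximum (end-diastole)
#'
#' Cyclically permutes the frames so the largest volume becomes frame 1 and
#' re-bases the normalised times. Use on curves whose acquisition did not
#' start at end-diastole before calling [fit_plr()].
#'
#' @param x a [tvc()] object.
#' @return A [tvc()] object starting at its volume maximum, with attribute
#'   `roll_frames` (the applied shift).
#' @export
roll_tvc <- function(x) {
  stop_if(!inherits(x, "tvc"), "'x' must be a tvc")
  v <- x$volume_ul
  n <- length(v)
  # end-diastole: the maximum-volume frame; among exact ties (a flat EDV
  # plateau) take the one the ejection decline follows, i.e. whose cyclic
  # successor is below the maximum
  cand <- which(v == max(v))
  drops <- v[cand %% n + 1L] < max(v)
  i <- if (any(drops)) cand[drops][1L] else cand[1L]
  if (i == 1L) { attr(x, "roll_frames") <- 0L; return(x) }
  ord <- c(i:n, 1:(i - 1L))
  t_new <- (x$t_norm[ord] - x$t_norm[i]) %% 1
  out <- tvc(t_new, x$volume_ul[ord], rr_ms = attr(x, "rr_ms"),
             bw_g = attr(x, "bw_g"))
  attr(out, "roll_frames") <- i - 1L
  out
}

#' Global LV function indices from the time-volume curve
#'
#' Extrema-based indices: EDV = maximum volume, ESV = minimum volume,
#' SV = EDV - ESV, EF = 100 SV/EDV, CO = SV x HR, and — when a body weight
#' is available — BSA = 9.822 (body weight)^(2/3) and cardiac index
#' CI = CO/BSA. Without a body weight BSA/CI are omitted, never defaulted.
#'
#' @param x a [tvc()] object.
#' @return Object of class `"lv_indices"`: list with `edv_ul`, `esv_ul`,
#'   `sv_ul`, `ef_pct`, `hr_bpm`, `co_ml_min`, and `bsa`/`ci` when body
#'   weight is known.
#' @export
#' @examples
#' x <- simulate_tvc(tvc_spec(edv_ul = 50, esv_ul = 20, bw_g = 27))
#' global_indices(x)
global_indices <- function(x) {
  stop_if(!inherits(x, "tvc"), "'x' must be a tvc")
  edv <- max(x$volume_ul); esv <- min(x$volume_ul)
  sv <- edv - esv
  hr <- attr(x, "hr_bpm")
  out <- list(edv_ul = edv, esv_ul = esv, sv_ul = sv,
              ef_pct = 100 * sv / edv, hr_bpm = hr,
              co_ml_min = sv * hr / 1000)
  bw <- attr(x, "bw_g")
  if (!is.null(bw)) {
    out$bsa <- 9.822 * bw^(2 / 3)
    out$ci <- out$co_ml_min / out$bsa
  }
  class(out) <- "lv_indices"
  out
}

#' @export
print.lv_indices <- function(x, ...) {
  cat(sprintf("EDV %.1f ul  ESV %.1f ul  SV %.1f ul  EF %.1f %%\n",
              x$edv_ul, x$esv_ul, x$sv_ul, x$ef_pct))
  cat(sprintf("HR %.0f bpm  CO %.2f ml/min", x$hr_bpm, x$co_ml_min))
  if (!is.null(x$ci)) cat(sprintf("  BSA %.1f  CI %.4f", x$bsa, x$ci))
  cat("\n")
  invisible(x)
}

#' Piecewise-linear regression of the LV time-volume curve
#'
#' Fits a continuous four-segment piecewise-linear model over one cardiac
#' cycle starting at end-diastole: ejection ramp, isovolumic relaxation,
#' filling ramp, isovolumic contraction. The cycle start is a fixed
#' boundary; the three interior knots are found by exhaustive least-squares
#' search over all frame triples (about 34k candidates at 60 frames,
#' evaluated in compiled code). On noiseless piecewise-linear input the
#' minimiser attains RSS = 0 at the true knots.
#'
#' @param x a [tvc()] object whose first frame is end-diastole; set
#'   `roll = TRUE` to re-base the curve at its volume maximum first.
#' @param roll roll the curve to start at its maximum before fitting.
#' @return Object of class `"plr"`: list with `knots_norm` (the three
#'   interior phase boundaries, fractions of RR), `knot_frames`,
#'   `slopes_ul_per_cycle` (four segment slopes in ul per normalised
#'   cycle), `coef` (hinge-basis coefficients), `rss`, `fitted.values`,
#'   `residuals`, and the input data.
#' @export
#' @examples
#' x <- simulate_tvc(tvc_spec())
#' fit <- fit_plr(x)
#' coef(fit)
fit_plr <- function(x, roll = FALSE) {
  stop_if(!inherits(x, "tvc"), "'x' must be a tvc")
  if (roll) x <- roll_tvc(x)
  v <- x$volume_ul
  stop_if(diff(range(v)) < 1e-6 * mean(v),
          "degenerate fit: time-volume curve is (nearly) flat, SV ~ 0")
  res <- plr_search_cpp(x$t_norm, v)
  beta <- as.numeric(res$coef)
  slopes <- beta[2] + cumsum(c(0, beta[3:5]))
  kf <- as.integer(res$knot_frames)
  fitted <- plr_eval(x$t_norm, x$t_norm[kf], beta)
  structure(list(knots_norm = x$t_norm[kf], knot_frames = kf,
                 slopes_ul_per_cycle = slopes, coef = beta,
                 # recompute the RSS from residuals: the search's Gram-matrix
                 # shortcut loses ~1e-10 absolute precision to cancellation
                 rss = sum((v - fitted)^2), fitted.values = fitted,
                 residuals = v - fitted, data = x),
            class = "plr")
}

# evaluate the hinge-basis piecewise-linear model
plr_eval <- function(t, knots, beta) {
  h <- vapply(knots, function(k) pmax(t - k, 0), numeric(length(t)))
  beta[1] + beta[2] * t + as.vector(h %*% beta[3:5])
}

#' @export
print.plr <- function(x, ...) {
  cat("Four-segment piecewise-linear TVC model\n")
  cat("  phase boundaries (fraction of RR): ",
      paste(sprintf("%.3f", x$knots_norm), collapse = ", "), "\n", sep = "")
  cat("  segment slopes (ul/cycle): ",
      paste(sprintf("%.1f", x$slopes_ul_per_cycle), collapse = ", "),
      "\n  RSS: ", format(x$rss, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.plr <- function(object, ...) {
  c(ejection_slope = object$slopes_ul_per_cycle[1],
    ivrt_slope = object$slopes_ul_per_cycle[2],
    filling_slope = object$slopes_ul_per_cycle[3],
    ivct_slope = object$slopes_ul_per_cycle[4],
    knot1 = object$knots_norm[1], knot2 = object$knots_norm[2],
    knot3 = object$knots_norm[3])
}

#' @export
predict.plr <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t_norm
       else if (is.list(newdata)) newdata$t_norm else as.numeric(newdata)
  plr_eval(t, object$knots_norm, object$coef)
}

#' @export
fitted.plr <- function(object, ...) object$fitted.values

#' @export
residuals.plr <- function(object, ...) object$residuals

#' @export
summary.plr <- function(object, ...) {
  sv <- max(object$data$volume_ul) - min(object$data$volume_ul)
  pm <- phase_metrics(object, sv_ul = sv, rr_ms = attr(object$data, "rr_ms"))
  out <- list(model = object, phase = pm,
              sigma = sqrt(object$rss / (nrow(object$data) - 5L)))
  class(out) <- "summary.plr"
  out
}

#' @export
print.summary.plr <- function(x, ...) {
  print(x$model)
  cat(sprintf("  residual sd: %.3f ul\n", x$sigma))
  cat(sprintf("  ER %.2f SV/RR, FR %.2f SV/RR\n", x$phase$er, x$phase$fr))
  cat(sprintf("  ET %.1f%%  IVRT %.1f%%  FT %.1f%%  IVCT %.1f%% of RR\n",
              x$phase$et_pct, x$phase$ivrt_pct, x$phase$ft_pct, x$phase$ivct_pct))
  invisible(x)
}

#' @export
plot.plr <- function(x, ...) {
  graphics::plot(x$data$t_norm, x$data$volume_ul, pch = 16, cex = 0.6,
                 xlab = "time (fraction of RR)", ylab = "LV volume (ul)", ...)
  tt <- seq(0, 1, length.out = 400)
  graphics::lines(tt, plr_eval(tt, x$knots_norm, x$coef), col = 2)
  graphics::abline(v = x$knots_norm, lty = 3)
  invisible(x)
}

#' Ejection/filling rates and phase durations from a fitted PLR model
#'
#' Segment slopes are normalised to the stroke volume and RR interval: the
#' ejection rate ER is |ejection slope| / SV and the filling rate FR is
#' |filling slope| / SV, both in units of SV per RR (the slopes are already
#' expressed per normalised cycle, so the RR normalisation is implicit).
#' Phase durations ET, IVRT, FT, IVCT are the segment lengths as percent of
#' the RR interval; they sum to 100 by construction.
#'
#' @param model a [fit_plr()] object.
#' @param sv_ul stroke volume in microlitres (> 0).
#' @param rr_ms RR interval in ms (carried for reporting; the normalised
#'   quantities do not depend on it).
#' @return List with `er`, `fr` (SV/RR), `et_pct`, `ivrt_pct`, `ft_pct`,
#'   `ivct_pct` (percent of RR) and `rr_ms`.
#' @export
phase_metrics <- function(model, sv_ul, rr_ms = NULL) {
  stop_if(!inherits(model, "plr"), "'model' must be a plr fit")
  check_number(sv_ul, "sv_ul", lower = 0)
  k <- model$knots_norm
  durations <- c(k[1], k[2] - k[1], k[3] - k[2], 1 - k[3])
  list(er = abs(model$slopes_ul_per_cycle[1]) / sv_ul,
       fr = abs(model$slopes_ul_per_cycle[3]) / sv_ul,
       et_pct = 100 * durations[1], ivrt_pct = 100 * durations[2],
       ft_pct = 100 * durations[3], ivct_pct = 100 * durations[4],
       rr_ms = rr_ms)
}
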