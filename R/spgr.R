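#' SPGR acquisition protocol
#'
#' Bundles the acquisition parameters of a spoiled gradient-recalled echo
#' (SPGR/FLASH) protocol used for variable-flip-angle (VFA) T1 mapping:
#' the multi-angle pre-injection scan and the single-angle dynamic scans.
#'
#' @param flip_angles_deg RF excitation angles of the multi-angle scan, in
#'   degrees, each in (0, 90). Default is the five-angle scheme
#'   `c(2, 5, 8, 11, 13)`.
#' @param tr_ms repetition time in ms (default 10).
#' @param te_ms echo time in ms; carried as metadata only — with a fixed TE
#'   across all scans, T2* weighting is constant and cancels in post/pre
#'   signal ratios (it is absorbed into the apparent M0 of the VFA fit).
#' @param fa_dynamic_deg flip angle of the dynamic post-injection scans
#'   (default 13, the largest angle of the default scheme).
#'
#' @return An object of class `"spgr_protocol"`.
#' @export
#' @examples
#' spgr_protocol()
spgr_protocol <- function(flip_angles_deg = c(2, 5, 8, 11, 13),
                          tr_ms = 10, te_ms = 1.6, fa_dynamic_deg = 13) {
  stop_if(length(flip_angles_deg) < 1L, "at least one flip angle is required")
  stop_if(any(!is.finite(flip_angles_deg)) ||
            any(flip_angles_deg <= 0) || any(flip_angles_deg >= 90),
          "flip angles must lie strictly between 0 and 90 degrees")
  stop_if(anyDuplicated(flip_angles_deg) > 0L, "flip angles must be distinct")
  check_number(tr_ms, "tr_ms", lower = 0)
  check_number(te_ms, "te_ms", lower = 0)
  check_number(fa_dynamic_deg, "fa_dynamic_deg", lower = 0, upper = 90)
  structure(list(flip_angles_deg = as.numeric(flip_angles_deg),
                 tr_ms = tr_ms, te_ms = te_ms,
                 fa_dynamic_deg = fa_dynamic_deg),
            class = "spgr_protocol")
}

#' @export
print.spgr_protocol <- function(x, ...) {
  cat("SPGR protocol\n")
  cat("  flip angles: ", paste0(x$flip_angles_deg, collapse = ", "),
      " deg (dynamic: ", x$fa_dynamic_deg, " deg)\n", sep = "")
  cat("  TE/TR: ", x$te_ms, "/", x$tr_ms, " ms\n", sep = "")
  invisible(x)
}

#' Steady-state SPGR signal
#'
#' Signal of the ideally spoiled gradient-echo sequence,
#' \deqn{S = M_0 \sin\alpha \, (1 - E_1) / (1 - E_1 \cos\alpha), \quad
#'       E_1 = e^{-TR/T_1}.}
#' This is the forward model underlying both the VFA fit
#' ([fit_vfa_t1()]) and the dynamic single-angle inversion
#' ([invert_dynamic_t1()]).
#'
#' @param m0 equilibrium signal (proportionality constant; includes coil
#'   sensitivity, proton density and the fixed-TE T2* weighting).
#' @param t1_ms longitudinal relaxation time in ms, > 0.
#' @param tr_ms repetition time in ms, > 0.
#' @param alpha_deg flip angle in degrees, in (0, 90).
#'
#' @return Signal values, recycled to the common length of the inputs.
#' @export
#' @examples
#' spgr_signal(1, 1500, 10, 13)   # ~ 0.0466
spgr_signal <- function(m0, t1_ms, tr_ms, alpha_deg) {
  stop_if(any(t1_ms <= 0, na.rm = TRUE), "'t1_ms' must be positive")
  stop_if(any(tr_ms <= 0), "'tr_ms' must be positive")
  stop_if(any(alpha_deg <= 0 | alpha_deg >= 90),
          "'alpha_deg' must lie strictly between 0 and 90 degrees")
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Ernst angle
#'
#' Flip angle maximising the SPGR signal for given T1 and TR:
#' \eqn{\alpha_E = \arccos(e^{-TR/T_1})}.
#'
#' @inheritParams spgr_signal
#' @return Angle in degrees.
#' @export
ernst_angle <- function(t1_ms, tr_ms) {
  stop_if(any(t1_ms <= 0) || any(tr_ms <= 0), "T1 and TR must be positive")
  acos(exp(-tr_ms / t1_ms)) * 180 / pi
}

#' Variable-flip-angle (DESPOT1) T1 fit
#'
#' Linearised least-squares estimation of T1 and M0 from SPGR signals
#' acquired at two or more flip angles with common TR: regressing
#' \eqn{y = S/\sin\alpha} on \eqn{x = S/\tan\alpha} gives slope
#' \eqn{E_1 = e^{-TR/T_1}} and intercept \eqn{M_0 (1 - E_1)}, so
#' \eqn{T_1 = -TR/\log(\mathrm{slope})} and
#' \eqn{M_0 = \mathrm{intercept}/(1-\mathrm{slope})}.
#'
#' Pixels whose regression slope falls outside (0, 1), or whose signals are
#' degenerate (e.g. all zero), are flagged `fit_ok = FALSE` and carry `NA`
#' estimates; they are never silently filled.
#'
#' @param signals numeric matrix (pixels x angles) or vector (one pixel) of
#'   magnitude signals, one column per flip angle.
#' @param alphas_deg flip angles in degrees matching the columns of
#'   `signals`; at least two distinct angles.
#' @param tr_ms repetition time in ms.
#'
#' @return A list with components `t1_ms`, `m0` (numeric, `NA` where the fit
#'   failed) and `fit_ok` (logical).
#' @seealso [fit_t1_map()] for the image-level wrapper.
#' @export
#' @examples
#' s <- spgr_signal(1, 1500, 10, c(2, 5, 8, 11, 13))
#' fit_vfa_t1(s, c(2, 5, 8, 11, 13), 10)$t1_ms   # 1500
fit_vfa_t1 <- function(signals, alphas_deg, tr_ms) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  na <- length(alphas_deg)
  stop_if(ncol(signals) != na,
          "number of signal columns must match number of flip angles")
  stop_if(length(unique(alphas_deg)) < 2L,
          "VFA fitting needs at least two distinct flip angles")
  stop_if(any(alphas_deg <= 0 | alphas_deg >= 90),
          "flip angles must lie strictly between 0 and 90 degrees")
  check_number(tr_ms, "tr_ms", lower = 0)

  a <- alphas_deg * pi / 180
  x <- sweep(signals, 2L, tan(a), "/")
  y <- sweep(signals, 2L, sin(a), "/")
  sx <- rowSums(x); sy <- rowSums(y)
  sxx <- rowSums(x * x); sxy <- rowSums(x * y)
  den <- na * sxx - sx * sx
  slope <- (na * sxy - sx * sy) / den
  intercept <- (sy - slope * sx) / na

  ok <- is.finite(slope) & slope > 0 & slope < 1 & is.finite(intercept)
  t1 <- rep(NA_real_, nrow(signals))
  m0 <- rep(NA_real_, nrow(signals))
  t1[ok] <- -tr_ms / log(slope[ok])
  m0[ok] <- intercept[ok] / (1 - slope[ok])
  list(t1_ms = t1, m0 = m0, fit_ok = ok)
}

#' Invert a dynamic single-angle signal ratio into a post-injection T1
#'
#' After the baseline VFA map, dynamic scans are acquired at a single flip
#' angle. Assuming M0 is unchanged by the intervention, the post/pre signal
#' ratio at fixed angle determines the new T1 in closed form: with
#' \eqn{g(E) = (1-E)/(1-E\cos\alpha)} and \eqn{q = \mathrm{ratio}\cdot
#' g(E_{pre})}, \eqn{E_{post} = (1-q)/(1-q\cos\alpha)} and
#' \eqn{T_{1,post} = -TR/\log E_{post}}.
#'
#' Ratios mapping outside \eqn{E_{post} \in (0,1)} (e.g. when
#' \eqn{q\cos\alpha \ge 1}) are flagged invalid rather than raising an
#' error, so a handful of noisy pixels cannot abort a whole time point.
#'
#' @param ratio_post_pre post/pre magnitude signal ratio at the dynamic
#'   angle (per pixel), > 0.
#' @param t1_pre_ms baseline T1 in ms (per pixel).
#' @param alpha_deg dynamic flip angle in degrees.
#' @param tr_ms repetition time in ms.
#'
#' @return List with `t1_post_ms` (`NA` where invalid) and logical `valid`.
#' @export
#' @examples
#' p <- spgr_protocol()
#' r <- spgr_signal(1, 1725, 10, 13) / spgr_signal(1, 1500, 10, 13)
#' invert_dynamic_t1(r, 1500, 13, 10)$t1_post_ms   # 1725
invert_dynamic_t1 <- function(ratio_post_pre, t1_pre_ms, alpha_deg, tr_ms) {
  check_number(alpha_deg, "alpha_deg", lower = 0, upper = 90)
  check_number(tr_ms, "tr_ms", lower = 0)
  stop_if(any(ratio_post_pre <= 0, na.rm = TRUE),
          "'ratio_post_pre' must be positive")
  ca <- cos(alpha_deg * pi / 180)
  e_pre <- exp(-tr_ms / t1_pre_ms)
  q <- ratio_post_pre * (1 - e_pre) / (1 - e_pre * ca)
  e_post <- (1 - q) / (1 - q * ca)
  valid <- is.finite(e_post) & e_post > 0 & e_post < 1 &
    is.finite(t1_pre_ms) & t1_pre_ms > 0
  t1_post <- rep(NA_real_, length(q))
  t1_post[valid] <- -tr_ms / log(e_post[valid])
  list(t1_post_ms = t1_post, valid = valid)
}
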