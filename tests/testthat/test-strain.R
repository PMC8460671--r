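# two-layer ring trajectories under uniform scaling r(t) = s(t) * r(0)
uniform_ring <- function(scales, n_ang = 24, radii = c(8.5, 11.5)) {
  grid <- expand.grid(ang = 2 * pi * ((1:n_ang) - 0.5) / n_ang, r0 = radii)
  do.call(rbind, lapply(seq_along(scales), function(k) {
    data.frame(point_id = seq_len(nrow(grid)), frame = k - 1L,
               x = scales[k] * grid$r0 * cos(grid$ang),
               y = scales[k] * grid$r0 * sin(grid$ang))
  }))
}

test_that("uniform 10% ring contraction gives exact linear and Green-Lagrange peaks", {
  sc <- c(1, 0.95, 0.9, 0.95, 1)
  lin <- strain_from_trajectories(uniform_ring(sc), convention = "linear")
  expect_equal(min(colMeans(lin$ecc)), -0.10, tolerance = 1e-12)
  expect_equal(min(colMeans(lin$err)), -0.10, tolerance = 1e-12)
  expect_equal(max(abs(lin$ecc[, 1])), 0)          # reference frame strain-free
  gl <- strain_from_trajectories(uniform_ring(sc), convention = "green_lagrange")
  expect_equal(min(colMeans(gl$ecc)), (0.9^2 - 1) / 2, tolerance = 1e-12)
})

test_that("strain is invariant to rigid translation and rotation", {
  traj <- simulate_ring_motion()
  ref <- strain_from_trajectories(traj)
  moved <- traj
  ang <- 0.7
  x2 <- cos(ang) * traj$x - sin(ang) * traj$y + 5.3 * (traj$frame + 1)
  y2 <- sin(ang) * traj$x + cos(ang) * traj$y - 2.1
  moved$x <- x2; moved$y <- y2
  got <- strain_from_trajectories(moved)
  expect_equal(got$ecc, ref$ecc, tolerance = 1e-9)
  expect_equal(got$err, ref$err, tolerance = 1e-9)
})

test_that("ring generator deformation is recovered exactly: Ecc = -s, Err = +w", {
  traj <- simulate_ring_motion(peak_circ_shortening = 0.1,
                               wall_thickening = 0.3)
  sc <- strain_from_trajectories(traj)
  truth <- attr(traj, "truth")
  expect_equal(colMeans(sc$ecc), truth$ecc_linear, tolerance = 1e-12)
  expect_equal(colMeans(sc$err), truth$err_linear, tolerance = 1e-12)
  expect_equal(min(colMeans(sc$ecc)), -0.10, tolerance = 1e-12)
  expect_equal(max(colMeans(sc$err)), +0.30, tolerance = 1e-12)
})

test_that("sector averaging commutes with sector-independent deformation", {
  traj <- simulate_ring_motion()
  sc <- strain_from_trajectories(traj)
  m <- colMeans(sc$ecc)
  for (s in seq_len(sc$n_sectors))
    expect_equal(sc$ecc[s, ], m, tolerance = 1e-12)
})

test_that("strain indices read peaks, 1/3-diastole value and strain rates off the mean curve", {
  traj <- simulate_ring_motion(peak_circ_shortening = 0.15,
                               wall_thickening = 0.3,
                               t_peak = 0.35, diastolic_lag = 0)
  idx <- strain_indices(strain_from_trajectories(traj))
  expect_equal(idx$peak_ecc, -0.15, tolerance = 1e-9)
  expect_equal(idx$peak_err, +0.30, tolerance = 1e-9)
  expect_lte(idx$peak_ecc, 0); expect_gte(idx$peak_err, 0)
  # end-systole lands on the contraction peak (within one frame)
  expect_lt(abs(idx$t_peak - 0.35), 1 / 60 + 1e-12)
  # 1/3-diastole value matches the analytic relaxation profile
  truth <- attr(traj, "truth")
  t3 <- idx$t_peak + (1 - idx$t_peak) / 3
  expect_equal(idx$ecc_third_diastole,
               approx(truth$t_norm, truth$ecc_linear, xout = t3)$y,
               tolerance = 1e-9)
})

test_that("peak strain rates converge to the analytic derivative at second order", {
  a <- 0.15
  make_idx <- function(n) {
    t <- (0:(n - 1)) / n
    e <- -a * sin(pi * t)
    strain_indices(strain_curves(t, matrix(rep(e, each = 8), nrow = 8)))
  }
  err_n <- function(n) {
    idx <- make_idx(n)
    max(abs(idx$sr_sys_cc - (-a * pi)), abs(idx$sr_dia_cc - (+a * pi)))
  }
  e100 <- err_n(100); e200 <- err_n(200)
  expect_lt(e200, 1e-3)
  # halving the step shrinks the error ~4x (allow slack for higher orders)
  expect_lt(e200, e100 / 3)
})

test_that("degenerate strain inputs are handled explicitly", {
  # identically zero curves give all-zero indices
  t <- (0:59) / 60
  z <- matrix(0, 8, 60)
  idx <- strain_indices(strain_curves(t, z, z))
  expect_equal(idx$peak_ecc, 0)
  expect_equal(idx$sr_dia_rr, 0)
  # too few points per sector is an error
  tiny <- simulate_ring_motion(n_points = 16)
  expect_error(strain_from_trajectories(tiny), "at least 3 points")
})
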