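test_that("phantom construction honours its geometry spec exactly and is deterministic", {
  ph <- make_phantom(phantom_spec(grid_size = 64, t1_myo_ms = 1500))
  expect_true(all(ph$t1_map[ph$label_map == 1L] == 1500))
  expect_true(all(ph$t1_map[ph$label_map == 2L] == 1900))
  expect_true(all(is.na(ph$t1_map[ph$label_map == 0L])))
  # labels mutually exclusive and exhaustive
  expect_true(all(ph$label_map %in% 0:2))
  expect_identical(ph, make_phantom(phantom_spec(grid_size = 64), seed = 1L))
  expect_error(phantom_spec(inner_radius_px = 20, outer_radius_px = 10),
               "inner radius")
})

test_that("noiseless VFA series round-trips through the map fit", {
  ph <- make_phantom(phantom_spec())
  series <- simulate_vfa_series(ph, spgr_protocol(), snr = Inf)
  map <- fit_t1_map(series)
  myo <- ph$label_map == 1L
  expect_true(all(map$fit_ok[myo]))
  expect_lt(max(abs(map$t1_ms[myo] - 1500)) / 1500, 1e-6)
  expect_lt(max(abs(map$t1_ms[ph$label_map == 2L] - 1900)) / 1900, 1e-6)
  # background pixels (zero signal) flagged, not filled
  expect_false(any(map$fit_ok[ph$label_map == 0L]))
})

test_that("noisy VFA series yields myocardial median T1 within 5% of truth", {
  ph <- make_phantom(phantom_spec())
  series <- simulate_vfa_series(ph, spgr_protocol(), snr = 30, seed = 7)
  map <- fit_t1_map(series)
  sel <- ph$label_map == 1L & map$fit_ok
  expect_lt(abs(median(map$t1_ms[sel]) - 1500) / 1500, 0.05)
  # determinism under the seed
  series2 <- simulate_vfa_series(ph, spgr_protocol(), snr = 30, seed = 7)
  expect_identical(series$images, series2$images)
})

test_that("single-angle series is flagged unfittable by VFA", {
  ph <- make_phantom(phantom_spec())
  s1 <- simulate_vfa_series(ph, spgr_protocol(flip_angles_deg = 13), snr = Inf)
  expect_false(s1$vfa_fittable)
  expect_error(fit_t1_map(s1), "not fittable")
})

test_that("null L-NAME response reproduces the pre-injection image at every time", {
  ph <- make_phantom(phantom_spec())
  prot <- spgr_protocol()
  resp0 <- group_response_spec("control", peak_delta_t1_pct = 0)
  dyn <- simulate_lname_response(ph, prot, resp0, snr = Inf)
  pre13 <- simulate_vfa_series(ph, prot, snr = Inf)$images[, , 5]
  for (k in seq_along(dyn$series$times_min))
    expect_equal(dyn$series$images[, , k], pre13, tolerance = 1e-12)
  expect_true(all(dyn$truth$delta_t1_pct == 0))
})

test_that("group response specs encode the study phenotypes", {
  ctl <- group_response_spec("control")
  expect_equal(ctl$peak_delta_t1_pct, 15)
  expect_equal(ctl$peak_time_min, 8)
  expect_equal(ctl$timepoints_min, c(4, 8, 12, 16, 20, 24))
  hfd <- group_response_spec("hfd")
  expect_lt(abs(hfd$peak_delta_t1_pct), abs(ctl$peak_delta_t1_pct))
  expect_error(group_response_spec("hfd", peak_delta_t1_pct = 20), "smaller")
})

test_that("synthetic TVC traces the requested extrema and is exactly piecewise linear", {
  x <- simulate_tvc(tvc_spec(edv_ul = 50, esv_ul = 20), noise_ul = 0)
  expect_equal(min(x$volume_ul), 20)
  expect_equal(max(x$volume_ul), 50)
  expect_identical(x$volume_ul,
                   simulate_tvc(tvc_spec(edv_ul = 50, esv_ul = 20))$volume_ul)
  # noiseless curve is exactly representable by 4 segments: PLR RSS ~ 0
  fit <- fit_plr(x)
  expect_lt(fit$rss, 1e-12)
})

test_that("ring motion with zero deformation gives identically zero strain", {
  traj <- simulate_ring_motion(peak_circ_shortening = 1e-12,
                               wall_thickening = 0)
  sc <- strain_from_trajectories(traj)
  expect_lt(max(abs(sc$ecc)), 1e-9)
  expect_lt(max(abs(sc$err)), 1e-9)
})

test_that("doppler traces carry more beats at higher heart rate", {
  tr <- simulate_doppler(hr_profile = function(t) ifelse(t == 0, 400, 800),
                         schedule_min = c(0, 5))
  count_beats <- function(d) {
    v <- d$velocity_mm_s
    length(cardiomvd:::find_peaks(v, 0.25 * diff(range(v))))
  }
  n0 <- count_beats(tr$traces[[1]])
  n1 <- count_beats(tr$traces[[2]])
  expect_equal(n0, 13)                     # 400 bpm over 2 s: 13 full beats
  expect_lte(abs(n1 - 2 * n0), 1)          # doubled rate ~ doubled beat count
})

test_that("GTT generator hits its analytic AUC and is seed-deterministic", {
  sp <- gtt_spec()
  ctl <- simulate_gtt(sp, group_scale = 1)
  # closed-form trapezoid of baseline + excursion
  tt <- sp$sample_times_min
  shape <- (tt / 30) * exp(1 - tt / 30)
  manual <- sum(diff(tt) * (head(100 + 150 * shape, -1) + tail(100 + 150 * shape, -1)) / 2)
  expect_equal(gtt_auc(ctl), manual)
  a <- simulate_gtt(sp, 1, noise_mgdl = 10, seed = 5)
  b <- simulate_gtt(sp, 1, noise_mgdl = 10, seed = 5)
  expect_identical(a$glucose_mgdl, b$glucose_mgdl)
})

test_that("HFD group scale produces the configured twofold AUC ratio exactly (noiseless)", {
  sp <- gtt_spec()
  s <- gtt_group_scale(sp, auc_ratio = 2)
  expect_equal(gtt_auc(simulate_gtt(sp, s)) / gtt_auc(simulate_gtt(sp, 1)), 2,
               tolerance = 1e-12)
})
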