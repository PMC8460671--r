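test_that("global indices follow the standard formulas and units", {
  x <- simulate_tvc(tvc_spec(edv_ul = 50, esv_ul = 20, rr_ms = 120, bw_g = 27))
  gi <- global_indices(x)
  expect_equal(gi$sv_ul, 30)
  expect_equal(gi$ef_pct, 60)
  expect_equal(gi$co_ml_min, 15)               # 30 ul x 500 bpm
  expect_equal(gi$bsa, 9.822 * 9)              # 27^(2/3) = 9 exactly
  expect_equal(gi$ci, 15 / 88.398)
  # without body weight, BSA/CI are omitted, not defaulted
  gi2 <- global_indices(simulate_tvc(tvc_spec(edv_ul = 50, esv_ul = 20)))
  expect_null(gi2$ci)
  expect_null(gi2$bsa)
})

test_that("PLR recovers the exact knots of a noiseless four-phase curve", {
  fr <- c(0.30, 0.10, 0.45, 0.15)
  x <- simulate_tvc(tvc_spec(phase_fractions = fr), noise_ul = 0)
  fit <- fit_plr(x)
  expect_equal(fit$knots_norm, cumsum(fr)[1:3], tolerance = 1e-12)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fitted(fit), x$volume_ul, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[["ejection_slope"]]), -30 / 0.30,
               tolerance = 1e-9)
})

test_that("PLR rejects a flat curve as degenerate", {
  x <- tvc((0:59) / 60, rep(42, 60), rr_ms = 120)
  expect_error(fit_plr(x), "degenerate")
})

test_that("PLR knots stay near the truth under 1 ul of volume noise", {
  fr <- c(0.30, 0.10, 0.45, 0.15)
  truth <- cumsum(fr)[1:3]
  err_frames <- vapply(1:10, function(seed) {
    x <- simulate_tvc(tvc_spec(phase_fractions = fr), noise_ul = 1, seed = seed)
    mean(abs(fit_plr(x)$knots_norm - truth)) * 60
  }, numeric(1))
  expect_lte(mean(err_frames), 1)
})

test_that("phase metrics are normalised to SV and RR", {
  x <- simulate_tvc(tvc_spec(edv_ul = 50, esv_ul = 20,
                             phase_fractions = c(0.3, 0.1, 0.45, 0.15)))
  fit <- fit_plr(x)
  pm <- phase_metrics(fit, sv_ul = 30, rr_ms = 120)
  expect_equal(pm$er, 1 / 0.3, tolerance = 1e-9)
  expect_equal(pm$fr, 1 / 0.45, tolerance = 1e-9)
  expect_equal(pm$et_pct + pm$ivrt_pct + pm$ft_pct + pm$ivct_pct, 100)
  # changing RR with the same normalised curve leaves everything unchanged
  x2 <- simulate_tvc(tvc_spec(edv_ul = 50, esv_ul = 20, rr_ms = 240,
                              phase_fractions = c(0.3, 0.1, 0.45, 0.15)))
  pm2 <- phase_metrics(fit_plr(x2), sv_ul = 30, rr_ms = 240)
  expect_equal(pm2$er, pm$er)
  expect_equal(pm2$et_pct, pm$et_pct)
})

test_that("EF and normalised rates are invariant to uniform volume rescaling", {
  sp <- tvc_spec(edv_ul = 50, esv_ul = 20)
  x <- simulate_tvc(sp, noise_ul = 0.5, seed = 3)
  y <- tvc(x$t_norm, x$volume_ul * 1000, rr_ms = attr(x, "rr_ms"))
  gx <- global_indices(x); gy <- global_indices(y)
  expect_equal(gx$ef_pct, gy$ef_pct)
  px <- phase_metrics(fit_plr(x), sv_ul = gx$sv_ul)
  py <- phase_metrics(fit_plr(y), sv_ul = gy$sv_ul)
  expect_equal(px$er, py$er, tolerance = 1e-9)
  expect_equal(px$ft_pct, py$ft_pct, tolerance = 1e-9)
})

test_that("rolling re-bases a curve that does not start at end-diastole", {
  sp <- tvc_spec()
  x <- simulate_tvc(sp, noise_ul = 0)
  # rotate so the curve starts mid-ejection
  shift <- 7L
  ord <- c((shift + 1):60, 1:shift)
  y <- tvc((0:59) / 60, x$volume_ul[ord], rr_ms = attr(x, "rr_ms"))
  fit <- fit_plr(y, roll = TRUE)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$knots_norm, cumsum(sp$phase_fractions)[1:3],
               tolerance = 1e-12)
})

test_that("parameter recovery across seeded noisy curves: knots <= 1 frame, rates <= 5%", {
  fr <- c(0.30, 0.10, 0.45, 0.15)
  truth_knots <- cumsum(fr)[1:3]
  n_sim <- 30
  knot_err <- numeric(n_sim); er_rel <- numeric(n_sim); fr_rel <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    x <- simulate_tvc(tvc_spec(phase_fractions = fr), noise_ul = 0.5,
                      seed = 1000 + i)
    fit <- fit_plr(x)
    pm <- phase_metrics(fit, sv_ul = 30)
    knot_err[i] <- mean(abs(fit$knots_norm - truth_knots)) * 60
    er_rel[i] <- abs(pm$er - 1 / 0.3) / (1 / 0.3)
    fr_rel[i] <- abs(pm$fr - 1 / 0.45) / (1 / 0.45)
  }
  expect_lte(mean(knot_err), 1)
  expect_lte(mean(er_rel), 0.05)
  expect_lte(mean(fr_rel), 0.05)
})
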