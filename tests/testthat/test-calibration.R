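test_that("rmse matches hand arithmetic and rejects length mismatches", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(5, 5, 5), c(2, 2, 2)), 3)
  expect_equal(rmse(c(0, 0, 3, 4), c(0, 0, 0, 0)), 2.5)
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("baseline correction removes constants and drifts but keeps transients", {
  t <- seq(0, 1199)
  flat <- signal_record(t = t, y = 0.004, T2 = 30)
  expect_equal(baseline_correct(flat)$y, rep(0, 1200), tolerance = 1e-15)

  drift <- signal_record(t = t, y = 0.002 + 3e-6 * t, T2 = 30)
  expect_lt(max(abs(baseline_correct(drift)$y)), 1e-15)

  bump_shape <- exp(-(t - 600)^2 / 2e3)
  bump <- signal_record(t = t, y = 0.001 + 0.005 * bump_shape, T2 = 30)
  bc <- baseline_correct(bump)
  expect_equal(max(bc$y), 0.005, tolerance = 1e-3)
  expect_lt(abs(mean(bc$y[1:60])), 1e-9)
  expect_lt(abs(mean(bc$y[1141:1200])), 1e-9)
  expect_equal(bc$T2, bump$T2)

  expect_error(baseline_correct(signal_record(t = 0:99, y = 0, T2 = 30),
                                head_window = 60, tail_window = 60),
               "longer than the record")
})

test_that("RC parameters are recovered from noise-free excitation records", {
  cs <- make_calibration_set(s1, n_records = 6, noise = noise_free(),
                             duration = 2700)
  guess <- calorimeter_params(C10 = 2.31, C1 = 5, C2 = 3, P1 = 0.04,
                              P2 = 0.045, P12 = 0.11, k = 0.020,
                              label = "S1")
  res <- identify_rc_params(cs$records, cs$programs, guess)
  expect_true(res$converged)
  for (f in c("C1", "C2", "P1", "P2", "P12", "k"))
    expect_lt(rel_err(res$params[[f]], s1[[f]]), 1e-3)
})

test_that("starting at the true parameters converges immediately to the noise floor", {
  cs <- make_calibration_set(s1, n_records = 4, noise = noise_free(),
                             duration = 1800)
  res <- identify_rc_params(cs$records, cs$programs, s1)
  expect_true(res$converged)
  expect_lt(res$eps_y, 1e-9)
  expect_lt(res$eps_T2, 1e-7)
})

test_that("residual RMSE matches the injected noise level at the optimum", {
  # noise matched to the reference devices' reported residuals
  cs <- make_calibration_set(s1, n_records = 4,
                             noise = noise_spec(16.5e-6, 3.9e-3, seed = 2),
                             duration = 2700)
  res <- identify_rc_params(cs$records, cs$programs, s1)
  expect_gt(res$eps_y, 16.5e-6 * 0.5)
  expect_lt(res$eps_y, 16.5e-6 * 1.5)
  expect_gt(res$eps_T2, 3.9e-3 * 0.5)
  expect_lt(res$eps_T2, 3.9e-3 * 1.5)
})

test_that("parameter recovery error shrinks as measurement noise shrinks", {
  # scaled-down replicate study: 3 noise levels x 5 replicates on short
  # records; the mean recovery error must decrease with the noise level
  guess <- calorimeter_params(C10 = 2.31, C1 = 4.5, C2 = 3.3, P1 = 0.035,
                              P2 = 0.05, P12 = 0.1, k = 0.022)
  mean_err <- vapply(c(8, 2, 0.5), function(scale) {
    errs <- vapply(1:6, function(rep) {
      cs <- make_calibration_set(
        s1, n_records = 4,
        noise = noise_spec(scale * 0.25e-3, scale * 0.01,
                           seed = 100 * scale + rep),
        duration = 900)
      res <- identify_rc_params(cs$records, cs$programs, guess)
      mean(vapply(c("C1", "C2", "P1", "P2", "P12", "k"),
                  function(f) rel_err(res$params[[f]], s1[[f]]), 0))
    }, 0)
    mean(errs)
  }, 0)
  # 6 replicates keep this fast; the trend over 16-fold noise is stable
  expect_gt(mean_err[1], mean_err[2])
  expect_gt(mean_err[2], mean_err[3])
})

test_that("cooling coefficients are recovered for both reference devices", {
  for (p in list(s1, s2)) {
    cs <- make_calibration_set(p, n_records = 8, noise = noise_free(),
                               duration = 1800)
    start <- p; start$alpha <- 0; start$beta <- 0
    fit <- identify_cooling_params(cs$records, cs$programs, start)
    expect_lt(rel_err(fit$alpha, p$alpha), 0.01)
    expect_lt(rel_err(fit$beta, p$beta), 0.01)
  }
})

test_that("cooling fit returns near-zero coefficients for a current-insensitive device", {
  p0 <- calorimeter_params(C10 = 2.31, C1 = 4.02, C2 = 3.8, P1 = 0.029,
                           P2 = 0.057, P12 = 0.092, k = 0.0237,
                           alpha = 0, beta = 0, label = "null-cooling")
  cs <- make_calibration_set(p0, n_records = 6, noise = noise_free(),
                             duration = 1200)
  start <- p0; start$alpha <- 5; start$beta <- -5
  fit <- identify_cooling_params(cs$records, cs$programs, start)
  expect_lt(abs(fit$alpha), 0.05)
  expect_lt(abs(fit$beta), 0.05)
})

test_that("a single Peltier current makes the cooling coefficients unidentifiable", {
  t <- seq(0, 599)
  recs <- lapply(1:2, function(i)
    simulate_forward(s1, forward_inputs(W1 = 0.1 * i, W2 = 1, Ipel = 0.1,
                                        Troom = 21.5), t))
  progs <- lapply(1:2, function(i) list(W1 = 0.1 * i, W2 = 1))
  expect_error(identify_cooling_params(recs, progs, s1), "unidentifiable")
})
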