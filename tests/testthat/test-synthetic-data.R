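test_that("generators are pure functions of their arguments and seed", {
  cs1 <- make_calibration_set(s1, n_records = 4, noise = noise_spec(seed = 4),
                              duration = 600)
  cs2 <- make_calibration_set(s1, n_records = 4, noise = noise_spec(seed = 4),
                              duration = 600)
  expect_identical(cs1$records, cs2$records)
  ses1 <- make_exercise_session(s1, synthetic_subject(),
                                protocol = step_protocol(duration = 1200,
                                                         start = 100,
                                                         end = 600),
                                noise = noise_spec(seed = 8))
  ses2 <- make_exercise_session(s1, synthetic_subject(),
                                protocol = step_protocol(duration = 1200,
                                                         start = 100,
                                                         end = 600),
                                noise = noise_spec(seed = 8))
  expect_identical(ses1$record, ses2$record)
  # byte-identical serialization
  f1 <- tempfile(); f2 <- tempfile()
  write_record(ses1$record, f1); write_record(ses2$record, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed perturbs the channels
  ses3 <- make_exercise_session(s1, synthetic_subject(),
                                protocol = step_protocol(duration = 1200,
                                                         start = 100,
                                                         end = 600),
                                noise = noise_spec(seed = 9))
  expect_false(identical(ses1$record$y, ses3$record$y))
})

test_that("generated sessions have the documented shape", {
  ses <- make_exercise_session(s1, synthetic_subject(),
                               noise = noise_spec(seed = 1))
  expect_equal(nrow(ses$record), 7200)         # 2 h at 1 Hz
  expect_equal(ses$truth$start, 600)
  expect_equal(ses$truth$end, 2400)
  expect_equal(diff(range(ses$record$T2)), 0.0718, tolerance = 0.5)
  expect_true(all(ses$record$W2 > 0))          # PID only heats
})

test_that("a zero-power protocol produces a flat resting flux", {
  subj <- synthetic_subject()
  ses <- make_exercise_session(s1, subj,
                               protocol = power_protocol(seq(0, 1199), 0),
                               noise = noise_free())
  expect_equal(ses$truth$W1,
               rep(subj$flux_exercise$A0 / 1000, 1200), tolerance = 1e-12)
  expect_lt(diff(range(ses$record$y)), 1e-9)
})

test_that("a flat property measurement makes the resistance estimate fail loudly", {
  pm <- make_property_measurement(s1, synthetic_subject(), dT2_step = 0,
                                  noise = noise_free())
  expect_error(skin_properties_from_step(pm$record, s1, pm$truth$step_time),
               "zero")
})

test_that("noise defaults reflect the stated steady oscillation levels", {
  ns <- noise_spec()
  expect_equal(ns$sigma_y, 0.25e-3)   # half of +/-0.5 mV peak-to-peak
  expect_equal(ns$sigma_T2, 0.01)     # half of +/-0.02 degC
  expect_error(noise_spec(sigma_y = -1), "non-negative")
  ses <- make_exercise_session(s1, synthetic_subject(),
                               protocol = step_protocol(duration = 900,
                                                        start = 300,
                                                        end = 600),
                               noise = noise_spec(seed = 3))
  ses0 <- make_exercise_session(s1, synthetic_subject(),
                                protocol = step_protocol(duration = 900,
                                                         start = 300,
                                                         end = 600),
                                noise = noise_free())
  expect_equal(stats::sd(ses$record$y - ses0$record$y), 0.25e-3,
               tolerance = 0.1)
  expect_equal(stats::sd(ses$record$T2 - ses0$record$T2), 0.01,
               tolerance = 0.1)
})

test_that("the optional surroundings dip lowers T01 during exercise only", {
  subj <- synthetic_subject()
  plain <- make_exercise_session(s1, subj, noise = noise_free())
  dip <- make_exercise_session(s1, subj, noise = noise_free(),
                               T01_dip = 0.5)
  t <- plain$record$t
  expect_identical(plain$record$y[t < 600], dip$record$y[t < 600])
  expect_false(identical(plain$record$y[t > 1200], dip$record$y[t > 1200]))
})

test_that("an end-to-end noiseless session is recovered through the full pipeline", {
  subj <- synthetic_subject()
  ses <- make_exercise_session(s1, subj, noise = noise_free())
  out <- run_pipeline(ses$record, s1, exercise_start = ses$truth$start,
                      exercise_end = ses$truth$end, W_input = 80)
  for (p in c("A0", "A1", "A2", "tau")) {
    expect_lt(rel_err(out$fits$exercise[[p]], subj$flux_exercise[[p]]),
              5e-4)
    expect_lt(rel_err(out$fits$recovery[[p]], subj$flux_recovery[[p]]),
              5e-4)
  }
})
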