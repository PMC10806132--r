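test_that("generators are deterministic under a fixed seed", {
  p <- emg_synthesis_params()
  a <- gen_volitional_emg(p, rep(0.4, 1000), seed = 5)
  b <- gen_volitional_emg(p, rep(0.4, 1000), seed = 5)
  expect_identical(a$emg, b$emg)
  c <- gen_volitional_emg(p, rep(0.4, 1000), seed = 6)
  expect_false(identical(a$emg, c$emg))

  f1 <- gen_fsr_traces(2, 3, seed = 4)
  f2 <- gen_fsr_traces(2, 3, seed = 4)
  expect_identical(f1$frames, f2$frames)

  d1 <- gen_isometric_dataset(n_samples = 30, seed = 9)
  d2 <- gen_isometric_dataset(n_samples = 30, seed = 9)
  expect_identical(d1$windows, d2$windows)
  expect_identical(d1$torques, d2$torques)
})

test_that("zero envelope gives a noise-floor-only stream", {
  p <- emg_synthesis_params(noise_floor = 0.01)
  vol <- gen_volitional_emg(p, rep(0, 2000), seed = 1)
  expect_lt(sqrt(mean(vol$emg^2)), 0.05)
  act <- gen_volitional_emg(p, rep(0.5, 2000), seed = 1)
  expect_gt(sqrt(mean(act$emg^2)), 10 * sqrt(mean(vol$emg^2)))
})

test_that("stimulated EMG adds pulse-locked artifacts and scaled M-waves", {
  p <- emg_synthesis_params()
  n <- 2000
  zeros <- matrix(0, n, 1)
  stim1 <- gen_stimulated_emg(zeros, c(0.5), 10, p)
  stim2 <- gen_stimulated_emg(zeros, c(0.5), 20, p)
  i0 <- 501
  # artifact spike at the pulse sample
  expect_equal(stim1$samples[i0, 1], p$artifact_amplitude)
  # doubling the effective amplitude doubles the M-wave peak
  mw1 <- stim1$samples[(i0 + 1):(i0 + 20), 1]
  mw2 <- stim2$samples[(i0 + 1):(i0 + 20), 1]
  expect_equal(max(abs(mw2)), 2 * max(abs(mw1)), tolerance = 1e-12)
  # zero amplitude leaves the volitional stream untouched between pulses
  stim0 <- gen_stimulated_emg(zeros, c(0.5), 0, p)
  expect_equal(stim0$samples[-i0, 1], zeros[-i0, 1])
  # ground truth retained
  expect_equal(stim1$volitional_truth, zeros, ignore_attr = TRUE)
})

test_that("FSR traces honour contact windows and report ground truth", {
  fsr <- gen_fsr_traces(2, 4, noise = 0, seed = 1)
  expect_equal(fsr$cycle_duration, 0.9)
  expect_length(fsr$strikes, 4)
  # heel loaded in 0-40%, unloaded in swing
  heel_on <- fsr$frames$heel_medial[fsr$phase > 5 & fsr$phase < 35]
  heel_off <- fsr$frames$heel_medial[fsr$phase > 45 & fsr$phase < 95]
  expect_true(all(heel_on > 0.9))
  expect_true(all(heel_off < 0.1))
  toe_on <- fsr$frames$toe_medial[fsr$phase > 15 & fsr$phase < 55]
  expect_true(all(toe_on > 0.9))
  # zero cycles gives an empty trace
  f0 <- gen_fsr_traces(2, 0)
  expect_equal(nrow(f0$frames), 0)
  expect_equal(f0$phase, numeric(0))
})

test_that("isometric dataset has a 6:2:2 split and plausible targets", {
  ds <- gen_isometric_dataset(n_samples = 50, seed = 3)
  expect_s3_class(ds, "emg_torque_dataset")
  expect_equal(dim(ds$windows), c(50, 288, 2))
  expect_length(ds$split$train, 30)
  expect_length(ds$split$val, 10)
  expect_length(ds$split$test, 10)
  expect_length(intersect(ds$split$train, ds$split$val), 0)
  expect_length(intersect(ds$split$train, ds$split$test), 0)
  expect_length(intersect(ds$split$val, ds$split$test), 0)
  expect_identical(ds$torque_window, 120L)
  # soleus-dominant windows map to plantar-flexion (positive) torque
  sol_dom <- ds$levels[, "soleus"] > 0.5 & ds$levels[, "TA"] < 0.1
  ta_dom <- ds$levels[, "TA"] > 0.5 & ds$levels[, "soleus"] < 0.1
  expect_true(all(ds$torques[sol_dom] > 0))
  expect_true(all(ds$torques[ta_dom] < 0))
  expect_error(gen_isometric_dataset(n_samples = 10, torque_window = 500))
})

test_that("envelopes are nonnegative and track the commanded activation", {
  ds <- gen_isometric_dataset(n_samples = 40, seed = 13)
  expect_true(all(ds$windows >= 0))
  rc <- hybridgait:::rectified_gaussian_mean()
  # the window-end envelope tracks rc * (activation + noise floor): the
  # end-of-window envelope difference must correlate strongly with the
  # commanded activation difference across windows
  end_diff <- ds$windows[, 288, 2] - ds$windows[, 288, 1]
  lvl_diff <- rc * (ds$levels[, "soleus"] - ds$levels[, "TA"])
  expect_gt(stats::cor(end_diff, lvl_diff), 0.95)
})
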