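test_that("comb filter is exact on identical segments and handles lengths", {
  seg <- cos(1:150 / 9)
  expect_identical(comb_filter(seg, seg), rep(0, 150))
  # unequal lengths resample to the shorter
  out <- comb_filter(seg, seg[1:100])
  expect_length(out, 100)
  expect_error(comb_filter(numeric(0), seg),
               class = "hybridgait_segment_error")
})

test_that("blanking replaces post-pulse samples and segments align to pulses", {
  rate <- 1000
  t <- (0:999) / rate
  x <- matrix(sin(2 * pi * 5 * t), ncol = 1)
  pulses <- c(0.2, 0.5, 0.8)
  stream <- stimulated_emg_stream(t, x, pulses, rate)
  cfg <- filter_config(blanking_ms = 5)
  bl <- blank_artifacts(stream, cfg)
  # blanked samples hold the last pre-pulse value
  i0 <- 201
  expect_true(all(bl$stream$samples[i0:(i0 + 5), 1] == x[i0 - 1, 1]))
  expect_length(bl$segments[[1]], 3)
  # overlapping blanking windows are refused
  s2 <- stimulated_emg_stream(t, x, c(0.2, 0.203), rate)
  expect_error(blank_artifacts(s2, cfg), class = "hybridgait_overlap_error")
})

test_that("low-pass reconstruction is nonnegative with unit DC gain", {
  cfg <- filter_config()
  x <- rep(2, 2000)
  env <- lowpass_reconstruct(x, cfg, 1000)
  expect_true(all(env >= 0))
  expect_equal(mean(env[500:1500]), 2, tolerance = 1e-2)
  expect_error(lowpass_reconstruct(x, filter_config(lowpass_cutoff_hz = 600),
                                   1000),
               class = "hybridgait_config_error")
})

test_that("synthesized volitional EMG has an envelope correlated with truth", {
  params <- emg_synthesis_params()
  n <- 12000
  envelope <- 0.5 + 0.4 * sin(2 * pi * (1:n) / 4000)
  vol <- gen_volitional_emg(params, envelope, seed = 5)
  rec <- lowpass_reconstruct(vol$emg, filter_config(), params$rate)
  expect_gt(stats::cor(rec, envelope), 0.9)
})

test_that("constant-envelope EMG is stationary across blocks", {
  params <- emg_synthesis_params()
  vol <- gen_volitional_emg(params, rep(0.6, 5000), seed = 9)
  blocks <- split(vol$emg, rep(1:5, each = 1000))
  rms <- vapply(blocks, function(b) sqrt(mean(b^2)), numeric(1))
  expect_lt(max(abs(rms - mean(rms)) / mean(rms)), 0.1)
})

test_that("the full cascade reconstructs the volitional envelope under FES", {
  params <- emg_synthesis_params()
  rate <- params$rate
  n <- 10 * rate
  envelope <- clamp(0.4 + 0.3 * sin(2 * pi * (1:n) / (2 * rate)), 0, 1)
  vol <- gen_volitional_emg(params, envelope, seed = 3)
  pulses <- seq(0.05, 10 - 0.05, by = 1 / 40)
  stim <- gen_stimulated_emg(vol, pulses, rep(12, length(pulses)), params)
  ext <- extract_volitional_envelope(stim, filter_config())
  rc <- hybridgait:::rectified_gaussian_mean()
  # compare away from filter edge transients
  sel <- 2000:(n - 2000)
  rel_err <- sqrt(mean((ext$envelope[sel, 1] - rc * envelope[sel])^2)) /
    sqrt(mean((rc * envelope[sel])^2))
  expect_lt(rel_err, 0.25)
  expect_gt(stats::cor(ext$envelope[sel, 1], envelope[sel]), 0.9)
})

test_that("without stimulation the cascade reduces to rectify-and-smooth", {
  params <- emg_synthesis_params()
  vol <- gen_volitional_emg(params, rep(0.5, 3000), seed = 2)
  stream <- stimulated_emg_stream(vol$t, matrix(vol$emg, ncol = 1),
                                  numeric(0), params$rate)
  ext <- extract_volitional_envelope(stream, filter_config())
  direct <- lowpass_reconstruct(vol$emg, filter_config(), params$rate)
  expect_equal(ext$envelope[, 1], direct, tolerance = 1e-12)
})

test_that("volitional torque pads short envelopes and matches direct windows", {
  cnn <- get_trained_cnn()
  L <- cnn$model$config$window_len
  e_ta <- rep(0.05, L + 40)
  e_sol <- seq(0.1, 0.5, length.out = L + 40)
  tau <- volitional_torque(e_ta, e_sol, cnn$model)
  w <- cbind(e_ta[41:(L + 40)], e_sol[41:(L + 40)])
  expect_equal(tau, estimate_torque(cnn$model, w), tolerance = 1e-12)
  # shorter inputs are left-padded with the first value
  tau_short <- volitional_torque(e_ta[1:100], e_sol[1:100], cnn$model)
  expect_true(is.finite(tau_short))
  expect_error(volitional_torque(e_ta, e_sol[-1], cnn$model))
})
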