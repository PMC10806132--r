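# Synthetic generators for every input the stack consumes: volitional EMG,
# stimulation artifacts and M-waves, foot-switch traces, and isometric
# EMG-torque training datasets. Every generator is deterministic under a
# fixed seed and returns ground truth alongside the observations so that
# downstream estimators are testable without recorded data.

#' EMG synthesis parameters
#'
#' @param rate sampling rate, Hz (`>= 1000`).
#' @param carrier_band band of the Gaussian noise carrier, Hz (surface-EMG
#'   convention 20-450 Hz).
#' @param mwave_duration_ms total duration of the biphasic M-wave template.
#' @param mwave_amp_per_mA M-wave peak amplitude per mA of effective
#'   (above-onset) stimulation, mV.
#' @param artifact_amplitude stimulation artifact spike amplitude, mV.
#' @param noise_floor additive baseline activation level (fraction of full
#'   scale) present even at zero commanded activation.
#' @return an object of class `emg_synthesis_params`.
#' @export
emg_synthesis_params <- function(rate = 1000, carrier_band = c(20, 450),
                                 mwave_duration_ms = 15,
                                 mwave_amp_per_mA = 0.1,
                                 artifact_amplitude = 50,
                                 noise_floor = 0.01) {
  stopifnot(rate >= 1000, length(carrier_band) == 2,
            carrier_band[1] > 0, carrier_band[2] < rate / 2,
            mwave_duration_ms > 0)
  structure(list(rate = rate, carrier_band = carrier_band,
                 mwave_duration_ms = mwave_duration_ms,
                 mwave_amp_per_mA = mwave_amp_per_mA,
                 artifact_amplitude = artifact_amplitude,
                 noise_floor = noise_floor),
            class = "emg_synthesis_params")
}

# Unit-variance band-limited Gaussian carrier. Uses the caller's RNG stream.
band_limited_carrier <- function(n, params) {
  w <- stats::rnorm(n + 200L)
  bf <- signal::butter(4, params$carrier_band / (params$rate / 2),
                       type = "pass")
  x <- signal::filter(bf, w)
  x <- x[(length(x) - n + 1L):length(x)]
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Biphasic raised-cosine M-wave template at unit amplitude.
mwave_template <- function(params) {
  n <- max(4L, round(params$mwave_duration_ms / 1000 * params$rate))
  half <- n %/% 2L
  t1 <- seq_len(half); t2 <- seq_len(n - half)
  c(0.5 * (1 - cos(2 * pi * t1 / half)),
    -0.5 * (1 - cos(2 * pi * t2 / (n - half))))
}

#' Generate volitional surface EMG from an activation envelope
#'
#' Amplitude-modulates a band-limited Gaussian carrier with the activation
#' envelope (plus the configured noise floor). Deterministic for a fixed
#' seed.
#'
#' @param params an [emg_synthesis_params()].
#' @param envelope activation envelope in `[0, 1]`, one value per output
#'   sample at `params$rate`.
#' @param seed integer seed.
#' @return list with `t` (s), `emg` (mV, one channel), and the ground-truth
#'   `envelope`.
#' @export
gen_volitional_emg <- function(params, envelope, seed = 1L) {
  stopifnot(all(envelope >= 0), all(envelope <= 1))
  set.seed(seed)
  n <- length(envelope)
  carrier <- band_limited_carrier(n, params)
  emg <- (envelope + params$noise_floor) * carrier
  list(t = (seq_len(n) - 1L) / params$rate, emg = emg, envelope = envelope)
}

#' Add stimulation artifacts and M-waves to volitional EMG
#'
#' For each pulse, adds a one-sample artifact spike and an M-wave template
#' scaled linearly by the effective (above-onset) stimulation amplitude.
#' The unmodified volitional stream is retained as ground truth.
#'
#' @param volitional list as returned by [gen_volitional_emg()] (single
#'   channel), or a numeric matrix of channels with attribute-free columns.
#' @param pulse_times pulse onset times, s, within the stream duration.
#' @param amplitudes effective stimulation amplitude per pulse, mA above
#'   onset (vector, one per pulse; or matrix pulses x channels).
#' @param params an [emg_synthesis_params()].
#' @return a [stimulated_emg_stream()] with extra elements
#'   `volitional_truth` (the clean samples) and `envelope_truth`.
#' @export
gen_stimulated_emg <- function(volitional, pulse_times, amplitudes, params) {
  if (is.list(volitional) && !is.data.frame(volitional)) {
    samples <- as.matrix(volitional$emg)
    t <- volitional$t
    env <- as.matrix(volitional$envelope)
  } else {
    samples <- as.matrix(volitional)
    t <- (seq_len(nrow(samples)) - 1L) / params$rate
    env <- NULL
  }
  amplitudes <- as.matrix(amplitudes)
  if (ncol(amplitudes) == 1L && ncol(samples) > 1L) {
    amplitudes <- matrix(amplitudes, nrow(amplitudes), ncol(samples))
  }
  stopifnot(nrow(amplitudes) == length(pulse_times),
            all(pulse_times >= t[1]), all(pulse_times <= t[length(t)]))
  clean <- samples
  tmpl <- mwave_template(params)
  n <- nrow(samples)
  for (pi in seq_along(pulse_times)) {
    i0 <- findInterval(pulse_times[pi] - 1e-9, t) + 1L
    if (i0 > n) next
    for (ch in seq_len(ncol(samples))) {
      samples[i0, ch] <- samples[i0, ch] +
        sign(tmpl[1] + 1e-12) * params$artifact_amplitude
      a <- max(0, amplitudes[pi, ch])
      if (a > 0) {
        # M-wave begins 1 ms after the pulse
        j0 <- i0 + max(1L, round(0.001 * params$rate))
        idx <- j0:min(j0 + length(tmpl) - 1L, n)
        samples[idx, ch] <- samples[idx, ch] +
          params$mwave_amp_per_mA * a * tmpl[seq_along(idx)]
      }
    }
  }
  out <- stimulated_emg_stream(t, samples, pulse_times, params$rate)
  out$volitional_truth <- clean
  out$envelope_truth <- env
  out
}

#' Generate synthetic foot-switch (FSR) traces
#'
#' Heel channels are loaded over 0-40% of the cycle and toe channels over
#' 10-60%, with raised-cosine edges and additive Gaussian noise. The
#' ground-truth phase series and heel-strike times are retained.
#'
#' @param speed walking speed, km/h, in `[1, 5]`.
#' @param n_cycles number of gait cycles (0 gives an empty trace).
#' @param noise additive noise standard deviation (raw units; contact
#'   amplitude is 1).
#' @param seed integer seed.
#' @param rate sampling rate, Hz.
#' @param speed_calibration cadence-speed calibration `c(slope, intercept)`
#'   used to derive the cycle duration.
#' @param heel_window,toe_window contact windows in percent of cycle.
#' @return list with `frames` (data frame `t` + four channels), and ground
#'   truth `phase` (percent per sample), `strikes` (s), `cycle_duration`
#'   (s).
#' @export
gen_fsr_traces <- function(speed, n_cycles, noise = 0.05, seed = 1L,
                           rate = 1000,
                           speed_calibration = c(1.8, 0),
                           heel_window = c(0, 40), toe_window = c(10, 60)) {
  stopifnot(speed >= 1, speed <= 5, n_cycles >= 0)
  set.seed(seed)
  cd <- speed_calibration[1] / (speed - speed_calibration[2])
  n <- round(n_cycles * cd * rate)
  chans <- c("heel_medial", "heel_lateral", "toe_medial", "toe_lateral")
  if (n == 0L) {
    frames <- as.data.frame(c(list(t = numeric(0)),
                              stats::setNames(rep(list(numeric(0)), 4),
                                              chans)))
    return(list(frames = frames, phase = numeric(0), strikes = numeric(0),
                cycle_duration = cd))
  }
  t <- (seq_len(n) - 1L) / rate
  phase <- (t / cd * 100) %% 100
  contact_profile <- function(win) {
    # trapezoid with 2% raised-cosine edges inside the window
    lo <- win[1]; hi <- win[2]; edge <- 2
    p <- phase
    v <- numeric(n)
    inside <- p >= lo & p < hi
    v[inside] <- 1
    rise <- inside & p < lo + edge
    fall <- inside & p >= hi - edge
    v[rise] <- 0.5 * (1 - cos(pi * (p[rise] - lo) / edge))
    v[fall] <- 0.5 * (1 + cos(pi * (p[fall] - (hi - edge)) / edge))
    v
  }
  heel <- contact_profile(heel_window)
  toe <- contact_profile(toe_window)
  frames <- data.frame(
    t = t,
    heel_medial = pmax(heel + stats::rnorm(n, sd = noise), 0),
    heel_lateral = pmax(0.95 * heel + stats::rnorm(n, sd = noise), 0),
    toe_medial = pmax(toe + stats::rnorm(n, sd = noise), 0),
    toe_lateral = pmax(0.9 * toe + stats::rnorm(n, sd = noise), 0)
  )
  strikes <- (seq_len(n_cycles) - 1L) * cd
  list(frames = frames, phase = phase, strikes = strikes,
       cycle_duration = cd)
}

# Fraction linking an activation level to the rectified-and-low-passed
# envelope of a unit-variance Gaussian carrier: E|X| / sd = sqrt(2/pi).
rectified_gaussian_mean <- function() sqrt(2 / pi)

#' Generate a synthetic isometric EMG-torque dataset
#'
#' Emulates isometric contraction trials in which the subject tracks
#' graded and trapezoidal (ramping) effort levels: each sample holds
#' either a constant or a within-window linear ramp of activation for the
#' tibialis anterior (channel 1) and soleus (channel 2); raw EMG is
#' synthesized per channel and converted to envelopes (rectification +
#' 2 Hz zero-phase low-pass, the same convention used by the
#' volitional-EMG cascade). The torque target is the concurrent torque at
#' the window end: a linear function of the difference of the
#' root-mean-squares over the trailing `torque_window` samples (the
#' muscle's effective torque memory),
#' `tau = gain * (rms_tail(soleus) - rms_tail(TA)) + N(0, noise_sigma)`
#' (plantar flexion positive). Ramp windows force the regressor to weight
#' recent samples, so its predictions track transients with little lag.
#' Split 6:2:2 into train/validation/test.
#'
#' @param n_samples number of windows.
#' @param window_len window length, samples.
#' @param gain torque mapping gain, Nm per unit envelope RMS.
#' @param torque_window trailing samples defining the concurrent torque
#'   (default 120, i.e. 0.12 s of torque memory at 1 kHz).
#' @param noise_sigma label noise standard deviation, Nm.
#' @param seed integer seed.
#' @param params an [emg_synthesis_params()].
#' @param split_ratio train/validation/test fractions summing to 1.
#' @return an object of class `emg_torque_dataset`: list with `windows`
#'   (array n x window_len x 2, envelope domain), `torques` (Nm), `split`
#'   (index vectors), `levels` (ground-truth activations at window end),
#'   `gain`.
#' @export
gen_isometric_dataset <- function(n_samples = 2000, window_len = 288,
                                  gain = 30, torque_window = 120L,
                                  noise_sigma = 0.5, seed = 7L,
                                  params = emg_synthesis_params(),
                                  split_ratio = c(0.6, 0.2, 0.2)) {
  stopifnot(n_samples > 0, abs(sum(split_ratio) - 1) < 1e-9,
            torque_window >= 1, torque_window <= window_len)
  set.seed(seed)
  pad <- 400L
  L <- window_len
  bf_band <- signal::butter(4, params$carrier_band / (params$rate / 2),
                            type = "pass")
  bf_env <- signal::butter(4, 2 / (params$rate / 2))
  windows <- array(0, dim = c(n_samples, L, 2L))
  levels <- matrix(0, n_samples, 2L,
                   dimnames = list(NULL, c("TA", "soleus")))
  kind <- sample(c("dorsi", "plantar", "ramp_dorsi", "ramp_plantar", "rest"),
                 n_samples, replace = TRUE,
                 prob = c(0.25, 0.25, 0.2, 0.2, 0.1))
  for (i in seq_len(n_samples)) {
    lo <- stats::runif(1, 0, 0.08)
    a_series <- switch(kind[i],
      dorsi = cbind(rep(stats::runif(1, 0.05, 1), L), rep(lo, L)),
      plantar = cbind(rep(lo, L), rep(stats::runif(1, 0.05, 1), L)),
      ramp_dorsi = cbind(seq(stats::runif(1, 0, 1), stats::runif(1, 0, 1),
                             length.out = L), rep(lo, L)),
      ramp_plantar = cbind(rep(lo, L),
                           seq(stats::runif(1, 0, 1), stats::runif(1, 0, 1),
                               length.out = L)),
      rest = cbind(rep(stats::runif(1, 0, 0.05), L),
                   rep(stats::runif(1, 0, 0.05), L)))
    levels[i, ] <- a_series[L, ]
    for (ch in 1:2) {
      w <- stats::rnorm(L + 2L * pad)
      a_pad <- c(rep(a_series[1, ch], pad), a_series[, ch],
                 rep(a_series[L, ch], pad))
      x <- (a_pad + params$noise_floor) * signal::filter(bf_band, w)
      env <- signal::filtfilt(bf_env, abs(x))
      windows[i, , ch] <- env[(pad + 1L):(pad + L)]
    }
  }
  tail_cols <- (L - torque_window + 1L):L
  rms <- function(m) sqrt(rowMeans(m^2))
  torques <- gain * (rms(windows[, tail_cols, 2]) -
                       rms(windows[, tail_cols, 1])) +
    stats::rnorm(n_samples, sd = noise_sigma)
  idx <- sample.int(n_samples)
  n_tr <- round(split_ratio[1] * n_samples)
  n_val <- round(split_ratio[2] * n_samples)
  split <- list(train = idx[seq_len(n_tr)],
                val = idx[n_tr + seq_len(n_val)],
                test = idx[(n_tr + n_val + 1L):n_samples])
  structure(list(windows = windows, torques = torques, split = split,
                 levels = levels, gain = gain,
                 torque_window = as.integer(torque_window),
                 noise_sigma = noise_sigma, params = params),
            class = "emg_torque_dataset")
}
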