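# Extraction of volitional EMG from FES-contaminated recordings.
#
# Each stimulation pulse produces a large electrical artifact followed by an
# M-wave (the stimulation-evoked compound action potential), both time-locked
# to the pulse. The cascade is: (1) a blanking window suppresses the artifact
# after each pulse; (2) a comb filter takes the half-difference of
# consecutive inter-pulse segments, cancelling the pulse-periodic M-wave;
# (3) full-wave rectification and a zero-phase 2 Hz low-pass reconstruct the
# volitional envelope and smooth the blanking discontinuities.

#' Stimulated EMG stream
#'
#' @param t sample times, seconds (uniform).
#' @param samples numeric matrix, one column per EMG channel, mV.
#' @param pulse_times strictly increasing FES pulse onset times, seconds.
#' @param rate sampling rate, Hz.
#' @return an object of class `stimulated_emg_stream`.
#' @export
stimulated_emg_stream <- function(t, samples, pulse_times, rate) {
  samples <- as.matrix(samples)
  stopifnot(length(t) == nrow(samples), rate > 0,
            all(diff(pulse_times) > 0))
  structure(list(t = t, samples = samples,
                 pulse_times = as.numeric(pulse_times), rate = rate),
            class = "stimulated_emg_stream")
}

#' Artifact-removal filter configuration
#'
#' @param blanking_ms blanking window after each pulse, milliseconds; must
#'   be shorter than the inter-pulse interval.
#' @param lowpass_cutoff_hz envelope low-pass cut-off, Hz (default 2).
#' @param lowpass_order Butterworth order (default 4).
#' @param comb_gain gain applied to the comb-filter output before
#'   rectification. The half-difference of two independent equal-variance
#'   volitional segments has 1/sqrt(2) of their RMS, so the default
#'   `sqrt(2)` makes the reconstructed envelope unbiased for noise-like
#'   volitional EMG under a stationary M-wave.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(blanking_ms = 5, lowpass_cutoff_hz = 2,
                          lowpass_order = 4, comb_gain = sqrt(2)) {
  stopifnot(blanking_ms > 0, lowpass_cutoff_hz > 0, lowpass_order >= 1)
  structure(list(blanking_ms = blanking_ms,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 lowpass_order = as.integer(lowpass_order),
                 comb_gain = comb_gain),
            class = "filter_config")
}

#' Blank stimulation artifacts
#'
#' Replaces samples inside `[pulse, pulse + blanking_ms]` with the last
#' pre-pulse sample (zero-order hold) and returns the inter-pulse segments
#' (from the end of each blanking window to the next pulse) aligned to their
#' pulse index.
#'
#' @param stream a [stimulated_emg_stream()].
#' @param cfg a [filter_config()].
#' @return list with `stream` (blanked copy) and `segments` (per channel, a
#'   list of numeric matrices: rows samples, one matrix per pulse).
#' @export
blank_artifacts <- function(stream, cfg) {
  dt <- 1 / stream$rate
  blank_n <- max(1L, round(cfg$blanking_ms / 1000 * stream$rate))
  if (length(stream$pulse_times) >= 2 &&
      any(diff(stream$pulse_times) <= cfg$blanking_ms / 1000)) {
    abort("blanking windows of consecutive pulses overlap",
          "hybridgait_overlap_error")
  }
  x <- stream$samples
  n <- nrow(x)
  pulse_idx <- findInterval(stream$pulse_times - 1e-9, stream$t) + 1L
  pulse_idx <- pulse_idx[pulse_idx >= 1L & pulse_idx <= n]
  segments <- vector("list", ncol(x))
  for (ch in seq_len(ncol(x))) segments[[ch]] <- vector("list", length(pulse_idx))
  for (pi in seq_along(pulse_idx)) {
    i0 <- pulse_idx[pi]
    i1 <- min(i0 + blank_n, n)
    hold <- if (i0 > 1L) x[i0 - 1L, ] else x[i0, ]
    x[i0:i1, ] <- matrix(hold, nrow = i1 - i0 + 1L, ncol = ncol(x),
                         byrow = TRUE)
    seg_end <- if (pi < length(pulse_idx)) pulse_idx[pi + 1L] - 1L else n
    if (i1 + 1L <= seg_end) {
      for (ch in seq_len(ncol(x))) {
        segments[[ch]][[pi]] <- stream$samples[(i1 + 1L):seg_end, ch]
      }
    }
  }
  out <- stream
  out$samples <- x
  list(stream = out, segments = segments)
}

#' Comb filter of consecutive inter-pulse segments
#'
#' `y = (x_current - x_previous) / 2` sample-wise: a stationary M-wave,
#' identical in consecutive segments, cancels exactly while the volitional
#' component passes (attenuated by the differencing). Segments of unequal
#' length are linearly resampled to the shorter length.
#'
#' @param segment_current,segment_previous numeric vectors: the inter-pulse
#'   samples following the current and previous pulse.
#' @return volitional segment, same length as the shorter input.
#' @export
comb_filter <- function(segment_current, segment_previous) {
  n1 <- length(segment_current); n0 <- length(segment_previous)
  if (n1 == 0 || n0 == 0) {
    abort("empty inter-pulse segment", "hybridgait_segment_error")
  }
  n <- min(n1, n0)
  resample <- function(x, n_out) {
    if (length(x) == n_out) return(x)
    stats::approx(seq_along(x), x, xout = seq(1, length(x),
                                              length.out = n_out))$y
  }
  (resample(segment_current, n) - resample(segment_previous, n)) / 2
}

#' Rectify and low-pass a signal into an envelope
#'
#' Full-wave rectification followed by a zero-phase (forward-backward)
#' Butterworth low-pass with unit DC gain.
#'
#' @param x numeric signal, uniformly sampled.
#' @param cfg a [filter_config()].
#' @param rate sampling rate, Hz; the cut-off must be below the Nyquist
#'   frequency.
#' @return nonnegative envelope, same length as `x`.
#' @export
lowpass_reconstruct <- function(x, cfg, rate) {
  if (cfg$lowpass_cutoff_hz >= rate / 2) {
    abort("low-pass cutoff at or above the Nyquist frequency",
          "hybridgait_config_error")
  }
  bf <- signal::butter(cfg$lowpass_order, cfg$lowpass_cutoff_hz / (rate / 2))
  y <- signal::filtfilt(bf, abs(x))
  pmax(y, 0)
}

#' Full volitional-EMG extraction cascade
#'
#' Blanking, per-pulse comb filtering (with the configured gain
#' compensation), concatenation of the comb output aligned to the original
#' timeline, rectification and 2 Hz zero-phase low-pass.
#'
#' @param stream a [stimulated_emg_stream()].
#' @param cfg a [filter_config()].
#' @return list with `t` (sample times) and `envelope` (numeric matrix, one
#'   column per channel): the reconstructed volitional envelope.
#' @export
extract_volitional_envelope <- function(stream, cfg = filter_config()) {
  n <- nrow(stream$samples)
  nch <- ncol(stream$samples)
  if (length(stream$pulse_times) < 2) {
    # no stimulation: the raw signal is volitional
    env <- sapply(seq_len(nch), function(ch) {
      lowpass_reconstruct(stream$samples[, ch], cfg, stream$rate)
    })
    return(list(t = stream$t, envelope = as.matrix(env)))
  }
  bl <- blank_artifacts(stream, cfg)
  pulse_idx <- findInterval(stream$pulse_times - 1e-9, stream$t) + 1L
  env <- matrix(0, n, nch)
  for (ch in seq_len(nch)) {
    segs <- bl$segments[[ch]]
    y <- numeric(n)
    for (pi in seq_along(segs)) {
      if (pi == 1L || is.null(segs[[pi]]) || is.null(segs[[pi - 1L]])) next
      v <- cfg$comb_gain * comb_filter(segs[[pi]], segs[[pi - 1L]])
      # stretch the comb output over the full inter-pulse window (including
      # the blanked samples) so the envelope sees no zero gaps
      i0 <- pulse_idx[pi]
      i1 <- if (pi < length(pulse_idx)) pulse_idx[pi + 1L] - 1L else
        min(i0 + length(v) +
              max(1L, round(cfg$blanking_ms / 1000 * stream$rate)), n)
      span <- i1 - i0 + 1L
      # sample-and-hold resampling preserves the amplitude distribution of
      # the noise-like volitional signal (linear interpolation would bias
      # the rectified mean low)
      vf <- stats::approx(seq_along(v), v, method = "constant",
                          xout = seq(1, length(v), length.out = span))$y
      idx <- i0:min(i1, n)
      y[idx] <- vf[seq_along(idx)]
    }
    env[, ch] <- lowpass_reconstruct(y, cfg, stream$rate)
  }
  list(t = stream$t, envelope = env)
}

#' Volitional joint torque from reconstructed envelopes
#'
#' Assembles a two-channel window (TA, soleus) from the envelope tails and
#' delegates to the trained CNN torque model.
#'
#' @param envelope_TA,envelope_sol reconstructed volitional envelopes,
#'   aligned, at the model's sampling rate; at least `window_len` samples
#'   (shorter inputs are left-padded with their first value).
#' @param model a trained `cnn_model`.
#' @return volitional torque, Nm (plantar flexion positive).
#' @export
volitional_torque <- function(envelope_TA, envelope_sol, model) {
  stopifnot(length(envelope_TA) == length(envelope_sol))
  L <- model$config$window_len
  tail_pad <- function(x) {
    n <- length(x)
    if (n >= L) x[(n - L + 1L):n] else c(rep(x[1], L - n), x)
  }
  w <- cbind(tail_pad(envelope_TA), tail_pad(envelope_sol))
  estimate_torque(model, w)
}
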