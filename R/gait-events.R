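# Gait-phase and speed estimation from foot-switch (FSR) traces.
#
# Four force-sensitive resistors (heel medial/lateral, toe medial/lateral)
# give ground-contact information. Contacts are detected per channel with a
# Schmitt-trigger threshold (hysteresis band suppresses chatter), OR-combined
# per region. The gait cycle is defined heel strike to heel strike
# (0% = heel strike); stance is roughly 0-60% of the cycle.

# Vectorised Schmitt trigger: ON above thr*(1+h), OFF below thr*(1-h),
# initial state OFF, band values hold the previous state.
schmitt <- function(x, threshold, hysteresis) {
  hi <- threshold * (1 + hysteresis)
  lo <- threshold * (1 - hysteresis)
  s <- rep(NA_integer_, length(x))
  s[x > hi] <- 1L
  s[x < lo] <- 0L
  # last-observation-carried-forward with initial state 0
  idx <- seq_along(s)
  idx[is.na(s)] <- 0L
  idx <- cummax(idx)
  out <- ifelse(idx == 0L, 0L, s[pmax(idx, 1L)])
  as.logical(out)
}

#' Detect heel and toe ground contact from FSR traces
#'
#' @param frames data frame with columns `t`, `heel_medial`, `heel_lateral`,
#'   `toe_medial`, `toe_lateral` (raw sensor units, `>= 0`); a single row is
#'   accepted.
#' @param thresholds named numeric vector of per-channel thresholds (raw
#'   units, `> 0`), names as the channel columns; a single unnamed value is
#'   recycled to all four channels.
#' @param hysteresis fractional hysteresis band half-width (default 0.1):
#'   a channel turns on above `threshold * (1 + hysteresis)` and off below
#'   `threshold * (1 - hysteresis)`.
#' @return data frame with columns `t`, `heel_contact`, `toe_contact`
#'   (logical; per-region OR of the two channels).
#' @export
detect_contacts <- function(frames, thresholds, hysteresis = 0.1) {
  chans <- c("heel_medial", "heel_lateral", "toe_medial", "toe_lateral")
  stopifnot(all(c("t", chans) %in% names(frames)), all(thresholds > 0),
            hysteresis >= 0, hysteresis < 1)
  if (length(thresholds) == 1L && is.null(names(thresholds))) {
    thresholds <- stats::setNames(rep(thresholds, 4L), chans)
  }
  stopifnot(all(chans %in% names(thresholds)))
  on <- lapply(chans, function(ch) {
    schmitt(frames[[ch]], thresholds[[ch]], hysteresis)
  })
  names(on) <- chans
  data.frame(
    t = frames$t,
    heel_contact = on$heel_medial | on$heel_lateral,
    toe_contact = on$toe_medial | on$toe_lateral
  )
}

#' Heel-strike timestamps from a contact series
#'
#' Rising edges of the heel-contact flag, debounced twice: an edge is a
#' strike only if the heel has been continuously off for at least `min_off`
#' beforehand (a shorter gap is a momentary sensor dropout within stance,
#' not a swing), and an edge closer than `min_interval` to the previously
#' accepted strike is discarded, since two heel strikes of the same foot
#' cannot occur within a fraction of the shortest plausible gait cycle
#' (0.36 s at 5 km/h).
#'
#' @param contacts data frame from [detect_contacts()].
#' @param min_interval refractory interval, seconds (default 0.25).
#' @param min_off minimum preceding off-time, seconds (default 0.05; the
#'   shortest plausible swing is about 0.14 s).
#' @return numeric vector of heel-strike times, seconds.
#' @export
heel_strikes <- function(contacts, min_interval = 0.25, min_off = 0.05) {
  h <- contacts$heel_contact
  n <- length(h)
  t <- contacts$t
  edge <- which(h & !c(FALSE, h[-n]))
  if (length(edge) == 0L) return(numeric(0))
  fall <- which(!h & c(FALSE, h[-n]))
  ok <- vapply(edge, function(e) {
    f <- fall[fall <= e]
    if (length(f) == 0L) TRUE else (t[e] - t[max(f)]) >= min_off
  }, logical(1))
  tt <- t[edge[ok]]
  if (length(tt) < 2L) return(tt)
  keep <- tt[1]
  for (x in tt[-1]) {
    if (x - keep[length(keep)] >= min_interval) keep <- c(keep, x)
  }
  keep
}

#' Gait status at a given time
#'
#' Phase is `100 * (t - last_heel_strike) / cycle_duration`, clamped below
#' 100; the cycle duration is the median of the last three inter-strike
#' intervals (fewer when not yet available). Before the second heel strike
#' the phase is undefined and `defined` is `FALSE`; the caller should hold
#' reference playback until then.
#'
#' @param event_history numeric vector of past heel-strike times (seconds);
#'   strikes after `t` are ignored.
#' @param t current time, seconds.
#' @param speed_calibration optional `c(slope, intercept)` passed to
#'   [estimate_speed()]; when omitted, `speed` is `NA`.
#' @return an object of class `gait_status`: list with `defined`, `phase`
#'   (% of cycle in `[0, 100)`), `cycle_duration` (s), `speed` (km/h),
#'   `in_stance` (phase < 60%).
#' @export
update_gait_phase <- function(event_history, t, speed_calibration = NULL) {
  strikes <- event_history[event_history <= t + 1e-12]
  if (length(strikes) < 2L) {
    return(structure(list(defined = FALSE, phase = NA_real_,
                          cycle_duration = NA_real_, speed = NA_real_,
                          in_stance = NA), class = "gait_status"))
  }
  iv <- diff(strikes)
  cd <- stats::median(utils::tail(iv, 3L))
  phase <- 100 * (t - strikes[length(strikes)]) / cd
  phase <- min(phase, 100 - 1e-9)
  speed <- if (is.null(speed_calibration)) NA_real_ else {
    estimate_speed(cd, speed_calibration)
  }
  structure(list(defined = TRUE, phase = phase, cycle_duration = cd,
                 speed = speed, in_stance = phase < 60),
            class = "gait_status")
}

#' Walking speed from cycle duration
#'
#' Affine cadence-to-speed map `speed = slope / cycle_duration + intercept`,
#' clamped to the 1-5 km/h envelope over which the reference profiles are
#' defined.
#'
#' @param cycle_duration gait-cycle duration, seconds (`> 0`).
#' @param calibration numeric `c(slope, intercept)`; slope in km/h * s.
#' @return walking speed, km/h, in `[1, 5]`.
#' @export
estimate_speed <- function(cycle_duration, calibration = c(1.8, 0)) {
  stopifnot(all(cycle_duration > 0), length(calibration) == 2)
  clamp(calibration[1] / cycle_duration + calibration[2], 1, 5)
}
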