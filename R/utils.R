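# Shared helpers and conventions.

#' Sign bridge between torque and angle conventions
#'
#' Ankle angle is dorsiflexion-positive; joint torque is plantar-flexion
#' positive (soleus positive, tibialis anterior negative). A positive
#' (plantar-flexion) torque therefore drives the angle negative. All plant
#' dynamics are integrated in the angle convention; torques expressed in the
#' torque convention are multiplied by this constant at the boundary.
#'
#' @return `-1`.
#' @export
torque_to_angle_sign <- function() -1

#' Clamp a numeric vector to a range
#'
#' @param x numeric vector.
#' @param lo,hi scalar bounds, `lo <= hi`.
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound.
#' @export
clamp <- function(x, lo, hi) {
  stopifnot(is.numeric(x), lo <= hi)
  pmin(pmax(x, lo), hi)
}

#' Degrees/radians conversion
#'
#' Angles are reported in degrees at all I/O boundaries and kept in radians
#' internally.
#' @param x numeric angle(s).
#' @return converted angle(s).
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

# Centered moving average with edge shrinkage (window w must be odd).
moving_average <- function(x, w = 5L) {
  stopifnot(w >= 1L, w %% 2L == 1L)
  n <- length(x)
  if (w == 1L || n < 2L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Internal: stop with a classed condition so callers can test errors by class.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "hybridgait_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
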