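# Speed-adaptive reference EMG envelopes and reference
# angle/torque/stiffness trajectories over the gait cycle.
#
# Envelope models are truncated Fourier series in gait phase (period 100%),
# fitted independently at five walking-speed nodes (1..5 km/h) and linearly
# interpolated in speed. The packaged defaults are generated from analytic
# raised-cosine templates that place soleus activity in stance (propulsion,
# 20-60% cycle) and tibialis-anterior activity from swing through heel
# strike; users can refit from their own sampled profiles.

fourier_design <- function(phase, order) {
  w <- 2 * pi * phase / 100
  X <- matrix(1, nrow = length(phase), ncol = 2 * order + 1)
  for (m in seq_len(order)) {
    X[, 2 * m] <- cos(m * w)
    X[, 2 * m + 1] <- sin(m * w)
  }
  X
}

#' Speed-adaptive EMG envelope model
#'
#' @param muscle `"TA"` or `"soleus"`.
#' @param speed_nodes strictly increasing walking speeds, km/h.
#' @param coeffs numeric matrix, one row per speed node, `2 * order + 1`
#'   columns: constant, then cos/sin coefficient pairs per harmonic.
#' @param order Fourier order M.
#' @return an object of class `envelope_model`.
#' @export
envelope_model <- function(muscle, speed_nodes, coeffs, order) {
  muscle <- match.arg(muscle, c("TA", "soleus"))
  coeffs <- as.matrix(coeffs)
  stopifnot(all(diff(speed_nodes) > 0),
            nrow(coeffs) == length(speed_nodes),
            ncol(coeffs) == 2 * order + 1)
  structure(list(muscle = muscle, speed_nodes = as.numeric(speed_nodes),
                 coeffs = coeffs, order = order),
            class = "envelope_model")
}

#' Evaluate a reference EMG envelope
#'
#' Evaluates the truncated Fourier series at the two speed nodes bracketing
#' `speed`, interpolates linearly in speed, and clips to `[0, 1]`. The series
#' is periodic in phase with period 100%, so phase 0 and phase 100 agree.
#'
#' @param model an [envelope_model()].
#' @param speed walking speed, km/h, within the node range.
#' @param phase gait phase in percent, `[0, 100]` (vectorised).
#' @return normalized activation in `[0, 1]`.
#' @export
emg_envelope <- function(model, speed, phase) {
  nodes <- model$speed_nodes
  if (length(speed) != 1L || speed < nodes[1] || speed > nodes[length(nodes)]) {
    abort("speed outside the envelope model's node range",
          "hybridgait_range_error")
  }
  if (any(phase < 0 | phase > 100)) {
    abort("phase must lie in [0, 100]", "hybridgait_range_error")
  }
  X <- fourier_design(phase, model$order)
  i <- findInterval(speed, nodes, rightmost.closed = TRUE)
  v_lo <- X %*% model$coeffs[i, ]
  if (speed == nodes[i]) {
    v <- v_lo
  } else {
    w <- (speed - nodes[i]) / (nodes[i + 1] - nodes[i])
    v_hi <- X %*% model$coeffs[i + 1, ]
    v <- (1 - w) * v_lo + w * v_hi
  }
  clamp(as.numeric(v), 0, 1)
}

#' Fit an envelope model to sampled per-speed profiles
#'
#' Least-squares truncated-Fourier fit at each speed node.
#'
#' @param profiles list with one element per speed node, each a data frame
#'   (or list) with `phase` (percent, uniform grid) and `value` (in
#'   `[0, 1]`).
#' @param speed_nodes walking speeds of the profiles, km/h.
#' @param order Fourier order M (default 6).
#' @param muscle muscle label for the resulting model.
#' @return an [envelope_model()] with attribute `rmse`: per-node
#'   reconstruction root-mean-square error.
#' @export
fit_envelope <- function(profiles, speed_nodes, order = 6, muscle = "soleus") {
  stopifnot(length(profiles) == length(speed_nodes))
  coeffs <- matrix(NA_real_, nrow = length(profiles), ncol = 2 * order + 1)
  rmse <- numeric(length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (length(p$phase) < 2 * order + 1) {
      abort("profile grid has fewer points than 2M+1: fit is ill-conditioned",
            "hybridgait_fit_error")
    }
    X <- fourier_design(p$phase, order)
    cf <- stats::lsfit(X, p$value, intercept = FALSE)$coefficients
    coeffs[i, ] <- cf
    rmse[i] <- sqrt(mean((X %*% cf - p$value)^2))
  }
  m <- envelope_model(muscle, speed_nodes, coeffs, order)
  attr(m, "rmse") <- rmse
  m
}

# Periodic raised-cosine bump centred at `c` with half-width `w` (percent),
# amplitude `A`; zero outside the support, wraps around the cycle.
raised_cosine <- function(phase, centre, halfwidth, amplitude) {
  d <- (phase - centre) %% 100
  d <- ifelse(d > 50, d - 100, d)
  ifelse(abs(d) <= halfwidth,
         amplitude * 0.5 * (1 + cos(pi * d / halfwidth)),
         0)
}

# Analytic activation templates used to generate the packaged defaults.
# Soleus: stance propulsion bump; TA: swing-to-heel-strike bump plus a
# smaller early-swing toe-clearance bump. Amplitude grows and the soleus
# bump shifts slightly earlier with speed.
envelope_template <- function(muscle, speed, phase) {
  s <- speed - 1
  if (muscle == "soleus") {
    raised_cosine(phase, centre = 44 - 0.5 * s, halfwidth = 17,
                  amplitude = 0.55 + 0.1 * s)
  } else {
    raised_cosine(phase, centre = 0, halfwidth = 17,
                  amplitude = 0.28 + 0.05 * s) +
      raised_cosine(phase, centre = 70, halfwidth = 9,
                    amplitude = 0.14 + 0.02 * s)
  }
}

#' Packaged default envelope model
#'
#' Generated by fitting the analytic raised-cosine templates at the five
#' speed nodes 1-5 km/h with Fourier order 6.
#'
#' @param muscle `"TA"` or `"soleus"`.
#' @param order Fourier order (default 6).
#' @param n_phase number of phase samples used for the fit (default 201).
#' @return an [envelope_model()].
#' @export
default_envelope_model <- function(muscle = c("TA", "soleus"), order = 6,
                                   n_phase = 201) {
  muscle <- match.arg(muscle)
  nodes <- 1:5
  phase <- seq(0, 100, length.out = n_phase)
  profiles <- lapply(nodes, function(v) {
    list(phase = phase, value = envelope_template(muscle, v, phase))
  })
  fit_envelope(profiles, nodes, order = order, muscle = muscle)
}

#' Reference trajectory table over the gait cycle
#'
#' @param phase_grid uniform phase grid in percent over `[0, 100]`.
#' @param theta_ref reference ankle angle, radians (dorsiflexion positive).
#' @param tau_ref reference joint torque, Nm (plantar flexion positive).
#' @param k_ref reference joint stiffness, Nm/rad (`>= 0`).
#' @return an object of class `reference_table` (a data frame).
#' @export
reference_table <- function(phase_grid, theta_ref, tau_ref, k_ref) {
  stopifnot(length(phase_grid) == length(theta_ref),
            length(phase_grid) == length(tau_ref),
            length(phase_grid) == length(k_ref),
            all(k_ref >= 0))
  structure(data.frame(phase = phase_grid, theta_ref = theta_ref,
                       tau_ref = tau_ref, k_ref = k_ref),
            class = c("reference_table", "data.frame"))
}

# Reference angle template, degrees: controlled plantar flexion after heel
# strike, dorsiflexion peaking near 40% (midstance), plantar flexion at
# push-off/toe-off (~65%), dorsiflexion for toe clearance in swing.
reference_angle_template_deg <- function(phase) {
  raised_cosine(phase, 8, 10, -6) +
    raised_cosine(phase, 40, 22, 12) +
    raised_cosine(phase, 65, 11, -11) +
    raised_cosine(phase, 87, 11, 5)
}

#' Packaged default reference table
#'
#' The angle trajectory is an analytic gait template (range of motion about
#' -10 to +15 degrees). The torque is constructed by integrating
#' `d tau = k(phase) d theta` along the cycle, with `k(phase)` a two-peak
#' stance-stiffness profile (loading-response peak near 30% cycle, push-off
#' peak near 50%) on a constant baseline; the second peak's amplitude is
#' balanced so the torque closes the cycle exactly. By construction the
#' moment-angle slope of the table equals `k(phase)`.
#'
#' @param n_phase number of grid points over `[0, 100]` (default 201).
#' @return a [reference_table()].
#' @export
default_reference_table <- function(n_phase = 201) {
  phase <- seq(0, 100, length.out = n_phase)
  theta <- deg2rad(reference_angle_template_deg(phase))
  k_base <- 25
  b1 <- raised_cosine(phase, 30, 8, 1)
  b2 <- raised_cosine(phase, 50, 8, 1)
  # midpoint d theta per grid cell (periodic)
  dtheta <- c(diff(theta), theta[1] - theta[length(theta)])
  A1 <- 120
  i1 <- sum(0.5 * (b1 + c(b1[-1], b1[1])) * dtheta)
  i2 <- sum(0.5 * (b2 + c(b2[-1], b2[1])) * dtheta)
  A2 <- -A1 * i1 / i2
  k <- k_base + A1 * b1 + A2 * b2
  kmid <- 0.5 * (k + c(k[-1], k[1]))
  tau <- -2 + cumsum(c(0, (kmid * dtheta)[-n_phase]))
  reference_table(phase, theta, tau, k)
}

#' Interpolate a reference table at arbitrary phases
#'
#' Periodic linear interpolation of the three reference columns.
#'
#' @param table a [reference_table()].
#' @param phase gait phase in percent (any real; wrapped modulo 100).
#' @return data frame with `theta_ref`, `tau_ref`, `k_ref` at `phase`.
#' @export
lookup_reference <- function(table, phase) {
  ph <- phase %% 100
  out <- lapply(c("theta_ref", "tau_ref", "k_ref"), function(col) {
    stats::approx(table$phase, table[[col]], xout = ph, rule = 2)$y
  })
  names(out) <- c("theta_ref", "tau_ref", "k_ref")
  as.data.frame(out)
}

#' Joint stiffness from the moment-angle curve
#'
#' Estimates the reference stiffness as the slope of the moment-angle curve
#' along the gait cycle, `k_ref = d tau_ref / d theta_ref`, using centred
#' finite differences, then rectifies to `>= 0` (impedance control requires
#' nonnegative stiffness) and smooths with a centred moving average.
#' Where `|d theta| < eps` the slope is carried over from the nearest
#' well-defined neighbour.
#'
#' @param theta_ref reference angle series, radians, aligned on the phase
#'   grid.
#' @param tau_ref reference torque series, Nm, same grid.
#' @param eps angle-increment guard, radians (default 1e-6).
#' @param smooth_window moving-average window, samples (odd, default 5).
#' @return stiffness series, Nm/rad, `>= 0`.
#' @export
stiffness_from_moment_angle <- function(theta_ref, tau_ref, eps = 1e-6,
                                        smooth_window = 5L) {
  n <- length(theta_ref)
  stopifnot(length(tau_ref) == n, n >= 3)
  ip <- c(2:n, n); im <- c(1, 1:(n - 1))  # one-sided at the ends
  dth <- theta_ref[ip] - theta_ref[im]
  dta <- tau_ref[ip] - tau_ref[im]
  k <- ifelse(abs(dth) < eps, NA_real_, dta / dth)
  if (all(is.na(k))) {
    abort("moment-angle curve is degenerate: no usable angle increments",
          "hybridgait_domain_error")
  }
  # carry slope over from the nearest defined neighbour (forward then back)
  idx <- seq_len(n); idx[is.na(k)] <- 0L; idx <- cummax(idx)
  k[idx > 0L] <- k[idx[idx > 0L]]
  if (any(is.na(k))) k[is.na(k)] <- k[which(!is.na(k))[1]]
  k <- pmax(k, 0)
  moving_average(k, smooth_window)
}

#' Read/write reference tables as CSV
#'
#' Angles are written in degrees at the file boundary (`theta_ref_deg`)
#' and converted back to radians on read.
#'
#' @param table a [reference_table()].
#' @param path CSV file path.
#' @return `read_reference_table()` returns a [reference_table()];
#'   `write_reference_table()` returns `path` invisibly.
#' @export
write_reference_table <- function(table, path) {
  out <- data.frame(phase = table$phase,
                    theta_ref_deg = rad2deg(table$theta_ref),
                    tau_ref = table$tau_ref,
                    k_ref = table$k_ref)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  d <- utils::read.csv(path)
  reference_table(d$phase, deg2rad(d$theta_ref_deg), d$tau_ref, d$k_ref)
}

#' Read/write envelope models as JSON
#'
#' @param model an [envelope_model()].
#' @param path JSON file path.
#' @return `read_envelope_model()` returns an [envelope_model()];
#'   `write_envelope_model()` returns `path` invisibly.
#' @export
write_envelope_model <- function(model, path) {
  jsonlite::write_json(
    list(muscle = model$muscle, speed_nodes = model$speed_nodes,
         order = model$order, coeffs = model$coeffs),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_envelope_model
#' @export
read_envelope_model <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  envelope_model(d$muscle, d$speed_nodes, d$coeffs, d$order)
}
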