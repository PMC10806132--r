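# Impedance, admittance and PD control of the PAFO.

#' Impedance setpoint
#'
#' Virtual spring-damper rendered between the measured and reference ankle
#' angle.
#'
#' @param theta_ref reference ankle angle, radians.
#' @param k_d desired stiffness, Nm/rad (`>= 0`).
#' @param c_d desired damping, Nm s/rad (`>= 0`).
#' @return an object of class `impedance_setpoint`.
#' @export
impedance_setpoint <- function(theta_ref, k_d, c_d) {
  stopifnot(is.numeric(theta_ref), k_d >= 0, c_d >= 0)
  structure(list(theta_ref = theta_ref, k_d = k_d, c_d = c_d),
            class = "impedance_setpoint")
}

#' PD gains and joint inertia
#'
#' @param K_P proportional gain (control-signal units per rad, `> 0`).
#' @param K_D derivative gain (per rad/s, `>= 0`).
#' @param I moment of inertia of the foot + orthosis about the ankle,
#'   kg m^2 (`> 0`).
#' @return an object of class `pd_gains`.
#' @export
pd_gains <- function(K_P = 400, K_D = 20, I = 0.05) {
  stopifnot(K_P > 0, K_D >= 0, I > 0)
  structure(list(K_P = K_P, K_D = K_D, I = I), class = "pd_gains")
}

#' Impedance-control torque
#'
#' `tau_c = -(k_d e + c_d e_dot)` with `e = theta - theta_ref`: a restoring
#' spring-damper torque in the angle convention.
#'
#' @param e angle error, radians.
#' @param e_dot angle error rate, rad/s.
#' @param setpoint an [impedance_setpoint()].
#' @return impedance torque, Nm.
#' @export
impedance_torque <- function(e, e_dot, setpoint) {
  -(setpoint$k_d * e + setpoint$c_d * e_dot)
}

#' Actuator torque command
#'
#' `tau_A = tau_c - tau_g_hat`: the commanded control torque minus the
#' gravity-compensation estimate.
#'
#' @param tau_c control torque, Nm.
#' @param tau_g_hat estimated gravity torque, Nm.
#' @return actuator torque, Nm.
#' @export
actuator_torque <- function(tau_c, tau_g_hat) {
  tau_c - tau_g_hat
}

#' One admittance step of the desired-angle dynamics
#'
#' Integrates the desired-trajectory model
#' `I * theta_d_ddot = -(k_d e + c_d e_dot) + tau_ext`
#' one step with semi-implicit Euler, treating the damping term implicitly:
#' the rendered damping `c_d` can be orders of magnitude larger than `I/dt`
#' (the admittance model is deliberately overdamped), which an explicit
#' update cannot integrate stably at any practical control rate. By default
#' the impedance error is formed on the desired trajectory itself
#' (`e = theta_d - theta_ref`, `e_dot = theta_d_dot`), which makes the
#' model self-contained; passing `theta_meas`/`theta_meas_dot` switches the
#' error to the measured angle.
#'
#' @param theta_d,theta_d_dot current desired angle (rad) and rate (rad/s).
#' @param setpoint an [impedance_setpoint()].
#' @param tau_ext external torque from the load cell, Nm (angle convention).
#' @param gains a [pd_gains()] (only the inertia `I` is used here).
#' @param dt integration step, seconds (`0 < dt <= 0.01`).
#' @param theta_meas,theta_meas_dot optional measured angle/rate for the
#'   measured-error variant.
#' @return list with `theta_d` and `theta_d_dot` advanced by `dt`.
#' @export
desired_angle_step <- function(theta_d, theta_d_dot, setpoint, tau_ext,
                               gains, dt,
                               theta_meas = NULL, theta_meas_dot = NULL) {
  stopifnot(dt > 0, dt <= 0.01)
  if (is.null(theta_meas)) {
    e <- theta_d - setpoint$theta_ref
    # damping acts on theta_d_dot: folded into the implicit velocity update
    acc <- (-setpoint$k_d * e + tau_ext) / gains$I
    v <- (theta_d_dot + dt * acc) / (1 + dt * setpoint$c_d / gains$I)
  } else {
    e <- theta_meas - setpoint$theta_ref
    e_dot <- if (is.null(theta_meas_dot)) 0 else theta_meas_dot
    acc <- (impedance_torque(e, e_dot, setpoint) + tau_ext) / gains$I
    v <- theta_d_dot + dt * acc
  }
  x <- theta_d + dt * v
  if (!is.finite(x) || abs(x) > 10) {
    abort("desired-angle integration diverged (|theta_d| > 10 rad)",
          "hybridgait_instability_error")
  }
  list(theta_d = x, theta_d_dot = v)
}

#' PD tracking control law
#'
#' `u = K_P e_d + K_D e_d_dot` with `e_d = theta - theta_d`. The control
#' signal is interpreted as a motor torque command by the simulator.
#'
#' @param e_d desired-angle tracking error, radians.
#' @param e_d_dot tracking error rate, rad/s.
#' @param gains a [pd_gains()].
#' @return control signal `u`.
#' @export
pd_control <- function(e_d, e_d_dot, gains) {
  gains$K_P * e_d + gains$K_D * e_d_dot
}
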