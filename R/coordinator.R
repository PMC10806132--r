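# Assist-as-needed torque sharing between FES, PAFO and volitional muscle
# activity.
#
# Sign conventions: joint torque is plantar-flexion positive. The soleus
# (plantar flexor) is driven by positive reference torque, the tibialis
# anterior (dorsiflexor) by negative reference torque; the two channels are
# never stimulated above their minimum simultaneously (no co-contraction).

#' Subject calibration for FES and volitional torque
#'
#' Personalized stimulation bounds come from a sensitivity test locating the
#' onset (first visible contraction) and pain threshold of each channel; the
#' working amplitude range must lie inside `[onset, pain]`.
#'
#' @param A_TA_min,A_TA_max tibialis-anterior amplitude bounds, mA.
#' @param A_Sol_min,A_Sol_max soleus amplitude bounds, mA.
#' @param tau_ref_max_neg maximum magnitude of negative (dorsiflexion)
#'   reference torque, Nm (`> 0`).
#' @param tau_ref_max_pos maximum positive (plantar flexion) reference
#'   torque, Nm (`> 0`).
#' @param tau_v_max maximum volitional torque magnitude, Nm (`> 0`).
#' @param onset_TA,onset_Sol onset thresholds, mA.
#' @param pain_TA,pain_Sol pain thresholds, mA.
#' @return an object of class `subject_calibration`.
#' @export
subject_calibration <- function(A_TA_min = 12, A_TA_max = 36,
                                A_Sol_min = 12, A_Sol_max = 42,
                                tau_ref_max_neg = 9, tau_ref_max_pos = 16,
                                tau_v_max = 30,
                                onset_TA = 10, onset_Sol = 10,
                                pain_TA = 50, pain_Sol = 55) {
  stopifnot(A_TA_min < A_TA_max, A_Sol_min < A_Sol_max,
            tau_ref_max_neg > 0, tau_ref_max_pos > 0, tau_v_max > 0,
            A_TA_min >= onset_TA, A_TA_max <= pain_TA,
            A_Sol_min >= onset_Sol, A_Sol_max <= pain_Sol)
  structure(list(A_TA_min = A_TA_min, A_TA_max = A_TA_max,
                 A_Sol_min = A_Sol_min, A_Sol_max = A_Sol_max,
                 tau_ref_max_neg = tau_ref_max_neg,
                 tau_ref_max_pos = tau_ref_max_pos,
                 tau_v_max = tau_v_max,
                 onset_TA = onset_TA, onset_Sol = onset_Sol,
                 pain_TA = pain_TA, pain_Sol = pain_Sol),
            class = "subject_calibration")
}

# Volitional torque only offsets stimulation demand in its own direction;
# antagonist volitional torque counts as zero offset.
directional_offset <- function(tau_ref, tau_v) {
  if (tau_ref < 0) {
    if (tau_v < 0) abs(tau_v) else 0
  } else if (tau_ref > 0) {
    if (tau_v > 0) tau_v else 0
  } else 0
}

#' FES amplitudes for TA and soleus
#'
#' The active channel (TA for negative reference torque, soleus for
#' positive) receives
#' `A = (A_max - A_min) * clamp((|tau_ref| - offset) / tau_ref_max, 0, 1)
#'    + A_min`,
#' where `offset` is the volitional torque magnitude in the demanded
#' direction; the antagonist stays at its minimum. When the volitional
#' torque meets or exceeds the demand the active channel drops to its
#' minimum; with zero volitional torque the amplitude follows the reference
#' torque profile.
#'
#' @param tau_ref reference joint torque, Nm.
#' @param tau_v estimated volitional torque, Nm.
#' @param calib a [subject_calibration()].
#' @return list with `A_TA` and `A_Sol`, mA, within the calibrated bounds.
#' @export
fes_amplitudes <- function(tau_ref, tau_v, calib) {
  off <- directional_offset(tau_ref, tau_v)
  A_TA <- calib$A_TA_min
  A_Sol <- calib$A_Sol_min
  if (tau_ref < 0) {
    frac <- clamp((abs(tau_ref) - off) / calib$tau_ref_max_neg, 0, 1)
    A_TA <- (calib$A_TA_max - calib$A_TA_min) * frac + calib$A_TA_min
  } else if (tau_ref > 0) {
    frac <- clamp((tau_ref - off) / calib$tau_ref_max_pos, 0, 1)
    A_Sol <- (calib$A_Sol_max - calib$A_Sol_min) * frac + calib$A_Sol_min
  }
  if (A_TA > calib$pain_TA || A_Sol > calib$pain_Sol) {
    abort("computed amplitude exceeds the pain threshold",
          "hybridgait_calibration_error")
  }
  list(A_TA = A_TA, A_Sol = A_Sol)
}

#' Activation ratio of volitional muscle activity
#'
#' Normalized share of joint torque attributable to the subject's own
#' effort. When the volitional torque magnitude exceeds the reference
#' demand, `r_v = clamp(max(|tau_ref|, |tau_v|) / tau_v_max, 0, 1)`;
#' otherwise (the subject cannot meet the demand) `r_v = 0` so the gait is
#' fully assisted by PAFO and FES. `r_v = 1` marks the maximum volitional
#' contribution, `r_v = 0` full device assistance.
#'
#' @param tau_ref reference joint torque, Nm.
#' @param tau_v estimated volitional torque, Nm.
#' @param tau_v_max maximum volitional torque, Nm (`> 0`).
#' @return activation ratio in `[0, 1]`.
#' @export
activation_ratio <- function(tau_ref, tau_v, tau_v_max) {
  stopifnot(tau_v_max > 0)
  if (abs(tau_v) > abs(tau_ref)) {
    clamp(max(abs(tau_ref), abs(tau_v)) / tau_v_max, 0, 1)
  } else {
    0
  }
}

#' Desired PAFO joint stiffness
#'
#' `k_d = clamp(k_max * (k_ref - r_v * k_ref_max) / k_ref_max + k_min,
#'              k_min, k_max)`:
#' stiffness follows the reference profile, reduced by the volitional
#' activation ratio, and is kept between `k_min` and `k_max` to avoid
#' excessive movement of the orthosis.
#'
#' @param k_ref reference stiffness, Nm/rad (`>= 0`).
#' @param r_v activation ratio in `[0, 1]`.
#' @param k_min,k_max stiffness bounds, Nm/rad.
#' @param k_ref_max maximum of the reference stiffness profile, Nm/rad.
#' @return desired stiffness, Nm/rad, in `[k_min, k_max]`.
#' @export
desired_stiffness <- function(k_ref, r_v, k_min = 5, k_max = 150,
                              k_ref_max = 150) {
  stopifnot(r_v >= 0, r_v <= 1, k_ref >= 0, k_ref_max > 0, k_min <= k_max)
  clamp(k_max * (k_ref - r_v * k_ref_max) / k_ref_max + k_min, k_min, k_max)
}

#' Desired PAFO damping
#'
#' Default (`mode = "literal"`): `c_d = 2 * zeta * k_d`, as a direct scaling
#' of the desired stiffness by the damping ratio. `mode = "critical"` uses
#' the dimensionally consistent second-order form
#' `c_d = 2 * zeta * sqrt(I * k_d)`.
#'
#' @param k_d desired stiffness, Nm/rad (`>= 0`).
#' @param zeta damping ratio (`>= 0`, default 0.7).
#' @param mode `"literal"` or `"critical"`.
#' @param I joint inertia, kg m^2 (used by `"critical"`).
#' @return desired damping, Nm s/rad.
#' @export
desired_damping <- function(k_d, zeta = 0.7, mode = c("literal", "critical"),
                            I = 0.05) {
  mode <- match.arg(mode)
  stopifnot(k_d >= 0, zeta >= 0)
  if (mode == "literal") 2 * zeta * k_d else 2 * zeta * sqrt(I * k_d)
}

#' One coordination step
#'
#' Combines the torque-sharing laws into the per-control-step output:
#' FES amplitudes, activation ratio and desired impedance.
#'
#' @param tau_ref reference joint torque, Nm.
#' @param tau_v estimated volitional torque, Nm.
#' @param k_ref reference stiffness, Nm/rad.
#' @param calib a [subject_calibration()].
#' @param k_min,k_max,k_ref_max stiffness bounds and reference maximum,
#'   Nm/rad.
#' @param zeta damping ratio.
#' @param damping_mode `"literal"` or `"critical"`.
#' @param I joint inertia for `"critical"` damping.
#' @return an object of class `coordination_output`: list with `A_TA`,
#'   `A_Sol` (mA), `r_v`, `k_d` (Nm/rad), `c_d` (Nm s/rad).
#' @export
coordinate <- function(tau_ref, tau_v, k_ref, calib,
                       k_min = 5, k_max = 150, k_ref_max = 150,
                       zeta = 0.7, damping_mode = "literal", I = 0.05) {
  amps <- fes_amplitudes(tau_ref, tau_v, calib)
  r_v <- activation_ratio(tau_ref, tau_v, calib$tau_v_max)
  k_d <- desired_stiffness(k_ref, r_v, k_min, k_max, k_ref_max)
  c_d <- desired_damping(k_d, zeta, damping_mode, I)
  structure(list(A_TA = amps$A_TA, A_Sol = amps$A_Sol, r_v = r_v,
                 k_d = k_d, c_d = c_d),
            class = "coordination_output")
}
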