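# Closed-loop simulator coupling a synthetic human ankle plant with the
# PAFO controller, FES recruitment and the coordination laws.
#
# The plant is a 1-DOF torque balance about the ankle,
#   I * theta_dd = tau_pafo + tau_passive + tau_ground + tau_env
#                  + tau_gravity + S * (tau_fes + tau_vol)
# in the dorsiflexion-positive angle convention (S = torque_to_angle_sign()
# converts the plantar-flexion-positive muscle/FES torques). During stance
# the foot is planted and the shank's rotation over it is kinematically
# imposed by body progression: the ground term is a stiff moving anchor
# following the gait angle path through stance (engaged by a smooth stance
# gate), so surplus muscle torque does work into the anchor (transferred to
# propulsion) while deficits are dragged along by it. A small viscous
# environment load acts throughout the cycle.
#
# Control modes: PF ignores volitional effort (the controller assumes
# tau_v = 0, FES follows the reference torque profile); PFV estimates the
# volitional torque online from stimulation-contaminated EMG through the
# blanking/comb/low-pass cascade and the CNN, and reduces FES amplitudes
# and PAFO stiffness accordingly. In both modes the plant's muscles fire
# according to the participation factor alpha.

#' Synthetic ankle plant parameters
#'
#' @param I_ankle combined foot + orthosis inertia about the ankle, kg m^2.
#' @param passive_k,passive_c passive joint stiffness (Nm/rad) and damping
#'   (Nm s/rad).
#' @param fes_gain_TA,fes_gain_Sol FES recruitment gains, Nm per mA above
#'   onset (linear recruitment).
#' @param onset_TA,onset_Sol recruitment onset amplitudes, mA.
#' @param participation_alpha volitional capacity factor in `[0, 1]`.
#' @param ground_gain overall scale of the stance ground interaction
#'   (default 1; 0 disables it).
#' @param ground_k,ground_c stance ground impedance, Nm/rad and Nm s/rad:
#'   with the foot planted, the shank's rotation over it is kinematically
#'   imposed by body progression, modeled as a stiff moving anchor that
#'   follows the gait angle path through stance. Work done against the
#'   anchor is transferred to body propulsion.
#' @param env_damping viscous environment load, Nm s/rad (default 1):
#'   lumped losses (shoe, soft tissue, air) acting throughout the cycle.
#' @param foot_mass,com_distance gravity model: point mass (kg) at distance
#'   (m) from the ankle.
#' @param gravity_offset foot-segment angle from vertical at neutral ankle
#'   angle, radians.
#' @param activation_noise band-limited noise added to the volitional
#'   activation envelopes (standard deviation, activation units).
#' @param emd_ms electromechanical delay between muscle excitation and
#'   torque, milliseconds (default 50; applies to the volitional torque).
#' @param seed integer seed for the plant's stochastic components.
#' @return an object of class `plant_params`.
#' @export
plant_params <- function(I_ankle = 0.05, passive_k = 3, passive_c = 0.3,
                         fes_gain_TA = 0.25, fes_gain_Sol = 0.45,
                         onset_TA = 10, onset_Sol = 10,
                         participation_alpha = 0.5,
                         ground_gain = 1, ground_k = 300, ground_c = 10,
                         env_damping = 1,
                         foot_mass = 1.2, com_distance = 0.12,
                         gravity_offset = pi / 2,
                         activation_noise = 0.02,
                         emd_ms = 50,
                         seed = 1L) {
  stopifnot(I_ankle > 0, fes_gain_TA >= 0, fes_gain_Sol >= 0,
            env_damping >= 0, ground_k >= 0, ground_c >= 0,
            participation_alpha >= 0, participation_alpha <= 1)
  structure(list(I_ankle = I_ankle, passive_k = passive_k,
                 passive_c = passive_c,
                 fes_gain_TA = fes_gain_TA, fes_gain_Sol = fes_gain_Sol,
                 onset_TA = onset_TA, onset_Sol = onset_Sol,
                 participation_alpha = participation_alpha,
                 ground_gain = ground_gain, ground_k = ground_k,
                 ground_c = ground_c, env_damping = env_damping,
                 foot_mass = foot_mass, com_distance = com_distance,
                 gravity_offset = gravity_offset,
                 activation_noise = activation_noise,
                 emd_ms = emd_ms,
                 seed = as.integer(seed)),
            class = "plant_params")
}

#' Controller configuration for the simulator
#'
#' Bundles the reference data, torque model and controller tuning used by
#' [simulate_gait()].
#'
#' @param geom a [linkage_geometry()].
#' @param gains a [pd_gains()].
#' @param calib a [subject_calibration()].
#' @param cnn_model a trained `cnn_model` (PFV mode and reference-torque
#'   generation).
#' @param ref_table a [reference_table()].
#' @param env_TA,env_sol [envelope_model()]s for the two muscles.
#' @param filter_cfg a [filter_config()].
#' @param k_min,k_max PAFO stiffness bounds, Nm/rad.
#' @param zeta damping ratio.
#' @param damping_mode `"literal"` or `"critical"` (see
#'   [desired_damping()]).
#' @param fes_rate FES pulse rate, Hz.
#' @param amp_slew_rate maximum rate of increase of the applied FES
#'   amplitudes, mA/s (default 60): intensity ramps up gradually for
#'   comfort, which also keeps consecutive M-waves similar for the comb
#'   filter.
#' @param amp_release_rate maximum rate of decrease of the applied FES
#'   amplitudes, mA/s (default 400): releasing stimulation has no comfort
#'   constraint and must be fast enough to clear the plantar-flexion
#'   channel by toe-off.
#' @param speed_calibration cadence-speed map `c(slope, intercept)`.
#' @param emg_params an [emg_synthesis_params()].
#' @return an object of class `sim_controller`.
#' @export
sim_controller <- function(cnn_model,
                           geom = linkage_geometry(),
                           gains = pd_gains(),
                           calib = subject_calibration(),
                           ref_table = default_reference_table(),
                           env_TA = default_envelope_model("TA"),
                           env_sol = default_envelope_model("soleus"),
                           filter_cfg = filter_config(),
                           k_min = 5, k_max = 150,
                           zeta = 0.7, damping_mode = "critical",
                           fes_rate = 40,
                           amp_slew_rate = 60, amp_release_rate = 400,
                           speed_calibration = c(1.8, 0),
                           emg_params = emg_synthesis_params()) {
  stopifnot(inherits(cnn_model, "cnn_model"), fes_rate > 0)
  structure(list(cnn_model = cnn_model, geom = geom, gains = gains,
                 calib = calib, ref_table = ref_table,
                 env_TA = env_TA, env_sol = env_sol,
                 filter_cfg = filter_cfg, k_min = k_min, k_max = k_max,
                 zeta = zeta, damping_mode = damping_mode,
                 fes_rate = fes_rate, amp_slew_rate = amp_slew_rate,
                 amp_release_rate = amp_release_rate,
                 speed_calibration = speed_calibration,
                 emg_params = emg_params),
            class = "sim_controller")
}

# Smooth stance gate over gait phase (percent): full foot support through
# mid-stance, released around toe-off (~60% cycle), zero in swing, with
# short cosine ramps at contact and release.
stance_gate <- function(phase) {
  ramp_in <- clamp(phase / 4, 0, 1)
  ramp_out <- clamp((65 - phase) / 10, 0, 1)
  u_in <- 0.5 * (1 - cos(pi * ramp_in))
  u_out <- 0.5 * (1 - cos(pi * ramp_out))
  pmin(u_in, u_out)
}

# Causally-available gait phase series: for each time, the phase computed
# from the heel strikes observed so far (same rule as update_gait_phase).
gait_phase_series <- function(strikes, t) {
  n <- length(t)
  phase <- rep(NA_real_, n)
  cd <- rep(NA_real_, n)
  if (length(strikes) >= 2) {
    iv <- diff(strikes)
    cd_per_strike <- vapply(seq_along(strikes), function(k) {
      if (k < 2) NA_real_ else stats::median(utils::tail(iv[seq_len(k - 1)], 3))
    }, numeric(1))
    li <- findInterval(t + 1e-12, strikes)
    ok <- li >= 2
    phase[ok] <- pmin(100 * (t[ok] - strikes[li[ok]]) / cd_per_strike[li[ok]],
                      100 - 1e-9)
    cd[ok] <- cd_per_strike[li[ok]]
  }
  list(phase = phase, cycle_duration = cd)
}

# Reference torque over a phase grid: the CNN applied to trailing windows of
# the reference EMG envelopes (converted to measured-envelope units by the
# rectified-Gaussian factor), mirroring how the volitional torque is
# estimated.
reference_torque_grid <- function(ctrl, speed, cycle_duration, dt,
                                  phase_grid = seq(0, 100, length.out = 101)) {
  L <- ctrl$cnn_model$config$window_len
  dphi <- dt / cycle_duration * 100
  rc <- rectified_gaussian_mean()
  offs <- rev(seq_len(L) - 1L) * dphi
  nwin <- length(phase_grid)
  W <- array(0, dim = c(nwin, L, 2L))
  for (i in seq_len(nwin)) {
    ph <- (phase_grid[i] - offs) %% 100
    W[i, , 1] <- rc * emg_envelope(ctrl$env_TA, speed, ph)
    W[i, , 2] <- rc * emg_envelope(ctrl$env_sol, speed, ph)
  }
  list(phase = phase_grid, tau_ref = estimate_torque(ctrl$cnn_model, W))
}

# Trailing-window RMS, matching the CNN's effective smoothing of envelope
# inputs: sqrt of the moving average of x^2 over the past `L` samples.
trailing_rms <- function(x, L) {
  cs <- cumsum(c(0, x^2))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - L + 1L, 1L)
  sqrt((cs[i + 1L] - cs[lo]) / (i - lo + 1L))
}

#' Simulate closed-loop hybrid gait
#'
#' Runs the full stack for `n_cycles` gait cycles at a fixed treadmill
#' speed: synthetic FSR traces drive gait-phase estimation; reference
#' angle/stiffness/torque are looked up per phase; in PFV mode synthetic
#' stimulated EMG is generated, filtered and converted to a volitional
#' torque estimate at every FES pulse; the coordination laws set FES
#' amplitudes and PAFO impedance; the admittance model and PD loop drive
#' the orthosis; the plant is integrated with semi-implicit Euler. The
#' first gait cycle is treated as cold start and excluded from per-cycle
#' aggregates.
#'
#' @param mode `"PF"` (volition ignored by the controller) or `"PFV"`
#'   (volition estimated and considered).
#' @param n_cycles number of gait cycles (`>= 2`).
#' @param speed treadmill speed, km/h, in `[1, 5]`.
#' @param plant a [plant_params()].
#' @param ctrl a [sim_controller()].
#' @param dt control/integration step, s (default 1 ms).
#' @param seed integer seed (overrides `plant$seed` when given).
#' @return an object of class `sim_result`: list with `series` (per-sample
#'   data frame), `cycles` (per-cycle energies, J, first cycle excluded),
#'   and the run configuration.
#' @export
simulate_gait <- function(mode = c("PF", "PFV"), n_cycles, speed, plant,
                          ctrl, dt = 0.001, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_cycles >= 2, speed >= 1, speed <= 5, dt > 0, dt <= 0.01)
  if (!is.null(seed)) plant$seed <- as.integer(seed)
  S <- torque_to_angle_sign()
  rate <- round(1 / dt)

  ## --- synthetic inputs -------------------------------------------------
  fsr <- gen_fsr_traces(speed, n_cycles, seed = plant$seed, rate = rate,
                        speed_calibration = ctrl$speed_calibration)
  contacts <- detect_contacts(fsr$frames, thresholds = 0.2)
  strikes <- heel_strikes(contacts)
  t <- fsr$frames$t
  n <- length(t)
  gp <- gait_phase_series(strikes, t)
  cd_nom <- fsr$cycle_duration

  ## reference lookups on the estimated phase (held at 0 during cold start)
  phase_c <- ifelse(is.na(gp$phase), 0, gp$phase)
  ref <- lookup_reference(ctrl$ref_table, phase_c)
  k_ref_max <- max(ctrl$ref_table$k_ref)
  tg <- reference_torque_grid(ctrl, speed, cd_nom, dt)
  tau_ref <- stats::approx(tg$phase, tg$tau_ref, xout = phase_c, rule = 2)$y
  tau_ref[is.na(gp$phase)] <- 0

  ## plant volitional activation (true phase), band-limited noise
  set.seed(plant$seed + 1L)
  rc <- rectified_gaussian_mean()
  alpha <- plant$participation_alpha
  bw <- signal::butter(2, 3 / (rate / 2))
  noise <- function() {
    if (plant$activation_noise <= 0) return(numeric(n))
    x <- signal::filter(bw, stats::rnorm(n))
    s <- stats::sd(x)
    if (s > 0) plant$activation_noise * x / s else x
  }
  a_ta <- clamp(alpha * emg_envelope(ctrl$env_TA, speed, fsr$phase) +
                  noise(), 0, 1)
  a_sol <- clamp(alpha * emg_envelope(ctrl$env_sol, speed, fsr$phase) +
                   noise(), 0, 1)
  L_win <- ctrl$cnn_model$config$window_len
  gain_map <- 30   # Nm per unit envelope RMS, the recruitment scale of the
                   # packaged torque model's training mapping
  mem_len <- 120L  # torque memory, samples, matching the training targets
  tau_v_true <- gain_map * rc * (trailing_rms(a_sol, mem_len) -
                                   trailing_rms(a_ta, mem_len))
  ## electromechanical delay: torque follows excitation after emd_ms
  d_emd <- round(plant$emd_ms / 1000 * rate)
  if (d_emd > 0) {
    tau_v_true <- c(rep(tau_v_true[1], d_emd),
                    tau_v_true[seq_len(n - d_emd)])
  }

  ## volitional EMG carriers (PFV estimation path)
  if (mode == "PFV") {
    emg_ta <- gen_volitional_emg(ctrl$emg_params, a_ta,
                                 seed = plant$seed + 11L)$emg
    emg_sol <- gen_volitional_emg(ctrl$emg_params, a_sol,
                                  seed = plant$seed + 12L)$emg
  }

  ## ground interaction (true phase): during stance the foot is planted and
  ## the shank's rotation over it is kinematically imposed by body
  ## progression, so the environment behaves as a stiff moving anchor
  ## following the gait angle path, engaged through a smooth stance gate.
  ## Surplus muscle torque squeezed into the anchor is work transferred to
  ## body propulsion, i.e. it leaves the joint. In swing the foot is free.
  env_tab <- default_reference_table()
  gnd_anchor <- lookup_reference(env_tab, fsr$phase)$theta_ref
  gnd_anchor_dot <- c(0, diff(gnd_anchor)) / dt
  gnd_w <- plant$ground_gain * stance_gate(fsr$phase)

  ## FES pulse schedule
  pulse_step <- max(1L, round(rate / ctrl$fes_rate))
  pulse_idx <- seq(1L, n, by = pulse_step)
  blank_n <- max(1L, round(ctrl$filter_cfg$blanking_ms / 1000 * rate))
  mw <- mwave_template(ctrl$emg_params)
  bf_env <- signal::butter(ctrl$filter_cfg$lowpass_order,
                           ctrl$filter_cfg$lowpass_cutoff_hz / (rate / 2))

  ## --- state ------------------------------------------------------------
  theta <- 0; theta_dot <- 0
  theta_d <- 0; theta_d_dot <- 0
  tau_v_hat <- 0
  comb_ta <- numeric(n); comb_sol <- numeric(n)  # rectify later
  mix_ta <- if (mode == "PFV") emg_ta else NULL
  mix_sol <- if (mode == "PFV") emg_sol else NULL
  amp_applied <- c(TA = ctrl$calib$A_TA_min, Sol = ctrl$calib$A_Sol_min)
  last_cmd <- amp_applied
  amp_step_up <- ctrl$amp_slew_rate / ctrl$fes_rate  # max mA rise per pulse
  amp_step_dn <- ctrl$amp_release_rate / ctrl$fes_rate
  amp_gate <- amp_step_up + 0.5  # comb segments with a larger
                                 # pulse-to-pulse amplitude step are unusable
  amp_hist <- matrix(ctrl$calib$A_TA_min, length(pulse_idx), 2L)
  amp_hist[, 2L] <- ctrl$calib$A_Sol_min
  env_hist_len <- max(1000L, L_win)

  out <- data.frame(t = t)
  o_theta <- numeric(n); o_theta_d <- numeric(n)
  o_tau_pafo <- numeric(n); o_tau_fes <- numeric(n)
  o_A_TA <- numeric(n); o_A_Sol <- numeric(n)
  o_r_v <- numeric(n); o_k_d <- numeric(n); o_tau_v_hat <- numeric(n)

  mgl <- plant$foot_mass * 9.81 * plant$com_distance
  calib <- ctrl$calib
  gains <- ctrl$gains
  pulse_ptr <- 1L

  for (i in seq_len(n)) {
    defined <- !is.na(gp$phase[i])

    ## pulse event: slew the applied amplitudes toward the command, inject
    ## M-wave/artifact, advance the volitional estimate
    if (pulse_ptr <= length(pulse_idx) && i == pulse_idx[pulse_ptr]) {
      amp_applied <- amp_applied +
        clamp(last_cmd - amp_applied, -amp_step_dn, amp_step_up)
      amp_hist[pulse_ptr, ] <- amp_applied
      if (mode == "PFV") {
        a_eff_ta <- max(0, amp_applied[["TA"]] - plant$onset_TA)
        a_eff_sol <- max(0, amp_applied[["Sol"]] - plant$onset_Sol)
        # artifact spike + scaled M-wave, time-locked to the pulse
        mix_ta[i] <- mix_ta[i] + ctrl$emg_params$artifact_amplitude
        mix_sol[i] <- mix_sol[i] + ctrl$emg_params$artifact_amplitude
        j0 <- i + 1L
        idx <- j0:min(j0 + length(mw) - 1L, n)
        mix_ta[idx] <- mix_ta[idx] +
          ctrl$emg_params$mwave_amp_per_mA * a_eff_ta * mw[seq_along(idx)]
        mix_sol[idx] <- mix_sol[idx] +
          ctrl$emg_params$mwave_amp_per_mA * a_eff_sol * mw[seq_along(idx)]
        ## process the two completed segments before this pulse
        if (pulse_ptr >= 3L) {
          p2 <- pulse_idx[pulse_ptr - 1L]; p1 <- pulse_idx[pulse_ptr - 2L]
          seg_cur_ta <- mix_ta[(p2 + blank_n + 1L):(i - 1L)]
          seg_prv_ta <- mix_ta[(p1 + blank_n + 1L):(p2 - 1L)]
          seg_cur_sol <- mix_sol[(p2 + blank_n + 1L):(i - 1L)]
          seg_prv_sol <- mix_sol[(p1 + blank_n + 1L):(p2 - 1L)]
          g <- ctrl$filter_cfg$comb_gain
          v_ta <- g * comb_filter(seg_cur_ta, seg_prv_ta)
          v_sol <- g * comb_filter(seg_cur_sol, seg_prv_sol)
          # stretch over the full inter-pulse window so the envelope sees
          # no blanking gaps
          span <- (i - 1L) - p2 + 1L
          stretch <- function(v) {
            stats::approx(seq_along(v), v, method = "constant",
                          xout = seq(1, length(v), length.out = span))$y
          }
          ## a stimulation-amplitude step between consecutive pulses breaks
          ## the M-wave periodicity the comb relies on: discard those
          ## segments and hold the last clean envelope value instead
          ok_ch <- abs(amp_hist[pulse_ptr - 1L, ] -
                         amp_hist[pulse_ptr - 2L, ]) <= amp_gate
          comb_ta[p2:(i - 1L)] <-
            if (ok_ch[1L]) stretch(v_ta) else comb_ta[p2 - 1L]
          comb_sol[p2:(i - 1L)] <-
            if (ok_ch[2L]) stretch(v_sol) else comb_sol[p2 - 1L]
          ## zero-phase envelope on the trailing history, CNN estimate;
          ## mirror-pad the right edge so the forward-backward filter has
          ## no end transient inside the CNN window
          h0 <- max(1L, i - env_hist_len + 1L)
          npad <- min(400L, i - h0)
          fpad <- function(x) {
            m <- length(x)
            y <- signal::filtfilt(bf_env, c(x, x[m:(m - npad + 1L)]))
            y[seq_len(m)]
          }
          e_ta <- fpad(abs(comb_ta[h0:i]))
          e_sol <- fpad(abs(comb_sol[h0:i]))
          tp <- function(x) {
            m <- length(x)
            if (m >= L_win) x[(m - L_win + 1L):m] else c(rep(x[1], L_win - m), x)
          }
          w <- cbind(pmax(tp(e_ta), 0), pmax(tp(e_sol), 0))
          tau_v_hat <- estimate_torque(ctrl$cnn_model, w)
        }
      }
      pulse_ptr <- pulse_ptr + 1L
    }

    ## coordination (controller's view of the volitional torque)
    tau_v_ctrl <- if (mode == "PFV" && defined) tau_v_hat else 0
    if (defined) {
      co <- coordinate(tau_ref[i], tau_v_ctrl, ref$k_ref[i], calib,
                       k_min = ctrl$k_min, k_max = ctrl$k_max,
                       k_ref_max = k_ref_max, zeta = ctrl$zeta,
                       damping_mode = ctrl$damping_mode, I = gains$I)
    } else {
      co <- list(A_TA = calib$A_TA_min, A_Sol = calib$A_Sol_min, r_v = 0,
                 k_d = ctrl$k_min,
                 c_d = desired_damping(ctrl$k_min, ctrl$zeta,
                                       ctrl$damping_mode, gains$I))
    }
    ## foot-switch gating of the propulsion channel: soleus stimulation is
    ## meaningful only while the foot bears load, so the command drops to
    ## its minimum once the estimated phase passes toe-off (~60%)
    a_sol_cmd <- if (defined && gp$phase[i] >= 60) calib$A_Sol_min else co$A_Sol
    last_cmd <- c(TA = co$A_TA, Sol = a_sol_cmd)

    ## plant torques (angle convention); FES follows the applied (slewed,
    ## per-pulse) amplitudes
    tau_fes_conv <-
      plant$fes_gain_Sol * max(0, amp_applied[["Sol"]] - plant$onset_Sol) -
      plant$fes_gain_TA * max(0, amp_applied[["TA"]] - plant$onset_TA)
    tau_muscle <- S * (tau_fes_conv + tau_v_true[i])
    tau_passive <- -plant$passive_k * theta - plant$passive_c * theta_dot
    tau_grav <- -mgl * sin(theta + plant$gravity_offset)
    tau_env <- -plant$env_damping * theta_dot
    tau_ground <- gnd_w[i] *
      (plant$ground_k * (gnd_anchor[i] - theta) +
         plant$ground_c * (gnd_anchor_dot[i] - theta_dot))
    tau_ext <- tau_muscle + tau_passive + tau_ground + tau_env

    ## admittance: desired angle from the impedance model + load cell
    sp <- impedance_setpoint(if (defined) ref$theta_ref[i] else 0,
                             co$k_d, co$c_d)
    ad <- desired_angle_step(theta_d, theta_d_dot, sp, tau_ext, gains, dt)
    theta_d <- ad$theta_d; theta_d_dot <- ad$theta_d_dot

    ## inner PD loop -> motor torque, with gravity compensation
    u <- pd_control(theta - theta_d, theta_dot - theta_d_dot, gains)
    tau_g_hat <- -mgl * sin(theta + plant$gravity_offset)
    tau_pafo <- actuator_torque(-u, tau_g_hat)

    ## integrate the plant
    acc <- (tau_pafo + tau_ext + tau_grav) / plant$I_ankle
    theta_dot <- theta_dot + dt * acc
    theta <- theta + dt * theta_dot
    if (!is.finite(theta) || abs(theta) > 10) {
      abort("plant integration diverged", "hybridgait_instability_error")
    }

    o_theta[i] <- theta; o_theta_d[i] <- theta_d
    o_tau_pafo[i] <- tau_pafo; o_tau_fes[i] <- tau_fes_conv
    o_A_TA[i] <- amp_applied[["TA"]]; o_A_Sol[i] <- amp_applied[["Sol"]]
    o_r_v[i] <- co$r_v; o_k_d[i] <- co$k_d; o_tau_v_hat[i] <- tau_v_ctrl
  }

  theta_dot_series <- c(0, diff(o_theta)) / dt
  series <- data.frame(
    t = t, phase = gp$phase, theta = o_theta, theta_d = o_theta_d,
    theta_dot = theta_dot_series,
    tau_pafo = S * o_tau_pafo,          # report in torque convention
    tau_fes = o_tau_fes,
    tau_vol = tau_v_true,
    tau_v_hat = o_tau_v_hat,
    tau_ref = tau_ref,
    A_TA = o_A_TA, A_Sol = o_A_Sol, r_v = o_r_v, k_d = o_k_d
  )

  ## per-cycle energies (first full cycle excluded as cold start)
  p_pafo <- joint_power(o_tau_pafo, theta_dot_series)   # angle convention
  p_fes <- joint_power(S * series$tau_fes, theta_dot_series)
  p_vol <- joint_power(S * series$tau_vol, theta_dot_series)
  bounds <- strikes[strikes >= strikes[min(2L, length(strikes))]]
  cyc <- data.frame()
  if (length(bounds) >= 2) {
    e_pafo <- cycle_energy(p_pafo, t, bounds)
    e_fes <- cycle_energy(p_fes, t, bounds)
    e_vol <- cycle_energy(p_vol, t, bounds)
    e_total <- if (mode == "PFV") e_pafo + e_fes + e_vol else e_pafo + e_fes
    cyc <- data.frame(cycle = seq_along(e_pafo),
                      t_start = bounds[-length(bounds)],
                      t_end = bounds[-1],
                      energy_pafo = e_pafo, energy_fes = e_fes,
                      energy_vol = e_vol, energy_total = e_total)
  }
  structure(list(series = series, cycles = cyc, mode = mode, speed = speed,
                 n_cycles = n_cycles, dt = dt,
                 alpha = plant$participation_alpha, seed = plant$seed,
                 strikes = strikes),
            class = "sim_result")
}

#' Joint power from torque and angular velocity
#'
#' Elementwise product of aligned torque and angular-velocity series (use a
#' consistent sign convention for both).
#'
#' @param tau torque series, Nm.
#' @param theta_dot angular velocity series, rad/s.
#' @return power series, W.
#' @export
joint_power <- function(tau, theta_dot) {
  stopifnot(length(tau) == length(theta_dot))
  tau * theta_dot
}

#' Per-cycle energy from a power series
#'
#' Trapezoidal time integral of the power over each cycle delimited by
#' consecutive boundary times.
#'
#' @param power power series, W.
#' @param t sample times, s, aligned with `power`.
#' @param boundaries increasing cycle boundary times within `t`'s range;
#'   `k+1` boundaries give `k` cycles.
#' @return numeric vector of per-cycle energies, J.
#' @export
cycle_energy <- function(power, t, boundaries) {
  stopifnot(length(power) == length(t), length(boundaries) >= 2,
            all(diff(boundaries) > 0),
            boundaries[1] >= t[1] - 1e-9,
            boundaries[length(boundaries)] <= t[length(t)] + 1e-9)
  cum <- c(0, cumsum(0.5 * (power[-1] + power[-length(power)]) * diff(t)))
  at <- stats::approx(t, cum, xout = boundaries, rule = 2)$y
  diff(at)
}

#' Compare PF and PFV simulation results
#'
#' Aggregates per-cycle energies per source for matched runs of the two
#' modes and tests the paired per-seed differences (two-sided paired
#' t-test). Identical inputs give zero differences and p = 1.
#'
#' @param results_pf,results_pfv a single `sim_result` or a list of
#'   matched-seed `sim_result`s, one per seed, same speeds and cycle counts.
#' @return an object of class `mode_comparison`: data frame with one row
#'   per energy source (`pafo`, `fes`, `device` = pafo + fes, `vol`,
#'   `total`): mean and sd of per-run mean per-cycle energy in each mode,
#'   the paired mean difference (PF - PFV) and p-value.
#' @export
compare_modes <- function(results_pf, results_pfv) {
  as_list <- function(x) if (inherits(x, "sim_result")) list(x) else x
  pf <- as_list(results_pf); pfv <- as_list(results_pfv)
  stopifnot(length(pf) == length(pfv), length(pf) >= 1)
  for (k in seq_along(pf)) {
    if (pf[[k]]$mode != "PF" || pfv[[k]]$mode != "PFV" ||
        pf[[k]]$speed != pfv[[k]]$speed ||
        pf[[k]]$n_cycles != pfv[[k]]$n_cycles ||
        pf[[k]]$seed != pfv[[k]]$seed) {
      abort("PF/PFV runs are not matched (mode, speed, cycles, seed)",
            "hybridgait_mismatch_error")
    }
  }
  src_mean <- function(res, what) {
    vapply(res, function(r) {
      cyc <- r$cycles
      switch(what,
             pafo = mean(cyc$energy_pafo),
             fes = mean(cyc$energy_fes),
             device = mean(cyc$energy_pafo + cyc$energy_fes),
             vol = mean(cyc$energy_vol),
             total = mean(cyc$energy_pafo + cyc$energy_fes + cyc$energy_vol))
    }, numeric(1))
  }
  rows <- lapply(c("pafo", "fes", "device", "vol", "total"), function(s) {
    a <- src_mean(pf, s); b <- src_mean(pfv, s)
    d <- a - b
    p <- if (all(abs(d - d[1]) < 1e-15)) {
      # degenerate: all differences equal, the t statistic is undefined
      if (abs(d[1]) < 1e-15) 1 else if (length(d) < 2) NA_real_ else 0
    } else {
      stats::t.test(a, b, paired = TRUE)$p.value
    }
    data.frame(source = s, mean_pf = mean(a), sd_pf = stats::sd(a),
               mean_pfv = mean(b), sd_pfv = stats::sd(b),
               mean_diff = mean(d), p_value = p)
  })
  structure(do.call(rbind, rows), class = c("mode_comparison", "data.frame"))
}
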