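short_run <- function(mode, alpha = 0.8, seed = 1, n_cycles = 3, ...) {
  cnn <- get_trained_cnn()
  ctrl <- sim_controller(cnn$model)
  plant <- plant_params(participation_alpha = alpha, seed = seed, ...)
  simulate_gait(mode, n_cycles = n_cycles, speed = 1.8, plant, ctrl)
}

test_that("simulation results are deterministic and well-formed", {
  r1 <- short_run("PFV")
  r2 <- short_run("PFV")
  expect_identical(r1$series, r2$series)
  expect_identical(r1$cycles, r2$cycles)
  expect_s3_class(r1, "sim_result")
  expect_true(all(c("t", "phase", "theta", "theta_d", "theta_dot",
                    "tau_pafo", "tau_fes", "tau_vol", "tau_v_hat",
                    "tau_ref", "A_TA", "A_Sol", "r_v", "k_d")
                  %in% names(r1$series)))
  # first cycle excluded: with 3 cycles at most 2 aggregated
  expect_lte(nrow(r1$cycles), 2)
  expect_gte(nrow(r1$cycles), 1)
})

test_that("simulated kinematics stay in a physiological range of motion", {
  for (mode in c("PF", "PFV")) {
    r <- short_run(mode)
    rng <- rad2deg(range(r$series$theta))
    expect_gt(rng[1], -25)
    expect_lt(rng[2], 18)
    # tracks the reference loosely (RMS error under 10 degrees)
    ref <- lookup_reference(default_reference_table(),
                            ifelse(is.na(r$series$phase), 0, r$series$phase))
    rmse <- sqrt(mean((r$series$theta - ref$theta_ref)^2))
    expect_lt(rad2deg(rmse), 10)
  }
})

test_that("per-cycle energies reconstruct from the reported series", {
  r <- short_run("PFV", seed = 2)
  S <- torque_to_angle_sign()
  s <- r$series
  bounds <- r$strikes[r$strikes >= r$strikes[2]]
  e_pafo <- cycle_energy(joint_power(S * s$tau_pafo, s$theta_dot), s$t, bounds)
  e_fes <- cycle_energy(joint_power(S * s$tau_fes, s$theta_dot), s$t, bounds)
  e_vol <- cycle_energy(joint_power(S * s$tau_vol, s$theta_dot), s$t, bounds)
  expect_equal(e_pafo, r$cycles$energy_pafo, tolerance = 1e-9)
  expect_equal(e_fes, r$cycles$energy_fes, tolerance = 1e-9)
  expect_equal(e_vol, r$cycles$energy_vol, tolerance = 1e-9)
  # accounting identity: total is exactly the sum of the sources
  expect_equal(r$cycles$energy_total,
               r$cycles$energy_pafo + r$cycles$energy_fes +
                 r$cycles$energy_vol,
               tolerance = 1e-12)
})

test_that("PF mode ignores the volitional estimate", {
  r <- short_run("PF")
  expect_true(all(r$series$tau_v_hat == 0))
  expect_true(all(r$series$r_v == 0))
})

test_that("FES amplitudes respect calibration bounds and the slew limits", {
  cnn <- get_trained_cnn()
  ctrl <- sim_controller(cnn$model)
  r <- short_run("PFV")
  cal <- ctrl$calib
  expect_true(all(r$series$A_TA >= cal$A_TA_min - 1e-9))
  expect_true(all(r$series$A_TA <= cal$A_TA_max + 1e-9))
  expect_true(all(r$series$A_Sol >= cal$A_Sol_min - 1e-9))
  expect_true(all(r$series$A_Sol <= cal$A_Sol_max + 1e-9))
  # per-pulse steps bounded by the asymmetric slew limits
  up <- ctrl$amp_slew_rate / ctrl$fes_rate
  dn <- ctrl$amp_release_rate / ctrl$fes_rate
  d_sol <- diff(r$series$A_Sol)
  expect_lte(max(d_sol), up + 1e-9)
  expect_gte(min(d_sol), -dn - 1e-9)
})

test_that("joint power and cycle energy integrate correctly", {
  expect_equal(joint_power(c(1, 2), c(3, -1)), c(3, -2))
  expect_error(joint_power(1:3, 1:2))
  # analytic check: power = sin over [0, pi] integrates to 2
  t <- seq(0, pi, length.out = 10001)
  e <- cycle_energy(sin(t), t, c(0, pi / 2, pi))
  expect_equal(sum(e), 2, tolerance = 1e-6)
  expect_equal(e[1], 1 - cos(pi / 2), tolerance = 1e-6)
  expect_error(cycle_energy(sin(t), t, c(-1, 1)))
})

test_that("mode comparison aggregates and degenerate cases behave", {
  fake <- function(mode, seed, e) {
    structure(list(cycles = data.frame(energy_pafo = e, energy_fes = e / 2,
                                       energy_vol = e / 4,
                                       energy_total = 1.75 * e),
                   mode = mode, speed = 1.8, n_cycles = 3, seed = seed),
              class = "sim_result")
  }
  # identical energies -> zero difference, p = 1
  cmp <- compare_modes(list(fake("PF", 1, c(1, 1)), fake("PF", 2, c(2, 2))) |>
                         lapply(function(x) { x$mode <- "PF"; x }),
                       list(fake("PFV", 1, c(1, 1)), fake("PFV", 2, c(2, 2))))
  expect_s3_class(cmp, "mode_comparison")
  expect_equal(cmp$mean_diff, rep(0, 5))
  expect_equal(cmp$p_value, rep(1, 5))
  # single non-identical pair: t-test undefined -> NA
  cmp2 <- compare_modes(fake("PF", 1, c(2, 2)), fake("PFV", 1, c(1, 1)))
  expect_equal(cmp2$mean_diff[cmp2$source == "pafo"], 1)
  expect_true(is.na(cmp2$p_value[cmp2$source == "pafo"]))
  # mismatched runs are refused
  expect_error(compare_modes(fake("PF", 1, 1), fake("PFV", 2, 1)),
               class = "hybridgait_mismatch_error")
  bad_speed <- fake("PFV", 1, 1); bad_speed$speed <- 2.5
  expect_error(compare_modes(fake("PF", 1, 1), bad_speed),
               class = "hybridgait_mismatch_error")
})

test_that("simulation validates its inputs", {
  cnn <- get_trained_cnn()
  ctrl <- sim_controller(cnn$model)
  plant <- plant_params()
  expect_error(simulate_gait("PF", 1, 1.8, plant, ctrl))     # < 2 cycles
  expect_error(simulate_gait("PF", 3, 0.5, plant, ctrl))     # speed range
  expect_error(simulate_gait("XX", 3, 1.8, plant, ctrl))     # unknown mode
  expect_error(plant_params(participation_alpha = 1.5))
})
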