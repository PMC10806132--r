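make_contacts <- function(h, dt = 0.001) {
  data.frame(t = (seq_along(h) - 1) * dt, heel_contact = h,
             toe_contact = rep(FALSE, length(h)))
}

test_that("contact detection uses a hysteresis band", {
  n <- 200
  t <- (seq_len(n) - 1) / 1000
  base <- rep(0, n); base[51:150] <- 1
  frames <- data.frame(t = t, heel_medial = base, heel_lateral = 0,
                       toe_medial = 0, toe_lateral = 0)
  # values inside the band hold the previous state
  frames$heel_medial[60] <- 0.21  # inside (0.18, 0.22) band for thr 0.2
  cont <- detect_contacts(frames, thresholds = 0.2, hysteresis = 0.1)
  expect_true(all(cont$heel_contact[51:150]))
  expect_false(any(cont$heel_contact[1:50]))
  expect_false(any(cont$toe_contact))
})

test_that("single unnamed threshold is recycled; named thresholds required otherwise", {
  frames <- data.frame(t = 0, heel_medial = 1, heel_lateral = 0,
                       toe_medial = 1, toe_lateral = 0)
  cont <- detect_contacts(frames, thresholds = 0.2)
  expect_true(cont$heel_contact)
  expect_true(cont$toe_contact)
  expect_error(detect_contacts(frames, thresholds = c(a = 0.2, b = 0.3)))
})

test_that("heel strikes are rising edges with a refractory interval", {
  h <- rep(FALSE, 3000)
  h[101:600] <- TRUE
  h[1101:1600] <- TRUE
  h[2101:2600] <- TRUE
  s <- heel_strikes(make_contacts(h))
  expect_equal(s, c(0.1, 1.1, 2.1))
  # a second edge within the refractory interval is discarded
  h2 <- rep(FALSE, 1000)
  h2[101:200] <- TRUE
  h2[281:400] <- TRUE  # off for 80 ms (> min_off) but only 180 ms after
  s2 <- heel_strikes(make_contacts(h2), min_interval = 0.25)
  expect_equal(s2, 0.1)
})

test_that("momentary sensor dropouts inside stance are not strikes", {
  h <- rep(FALSE, 3000)
  h[101:600] <- TRUE
  h[621:900] <- TRUE    # 20 ms dropout mid-stance: not a new strike
  h[1101:1600] <- TRUE
  s <- heel_strikes(make_contacts(h), min_off = 0.05)
  expect_equal(s, c(0.1, 1.1))
  # the same gap counts as a strike when min_off allows it
  s2 <- heel_strikes(make_contacts(h), min_interval = 0.25, min_off = 0.01)
  expect_equal(s2, c(0.1, 0.62, 1.1))
})

test_that("heel strike edge cases", {
  expect_equal(heel_strikes(make_contacts(rep(FALSE, 100))), numeric(0))
  h <- rep(FALSE, 100); h[11:90] <- TRUE
  expect_equal(heel_strikes(make_contacts(h)), 0.01)
})

test_that("gait phase is undefined before two strikes and correct after", {
  st <- c(0, 1, 2, 3)
  g0 <- update_gait_phase(st, 0.5)
  expect_false(g0$defined)
  expect_true(is.na(g0$phase))
  g <- update_gait_phase(st, 2.5)
  expect_true(g$defined)
  expect_equal(g$phase, 50)
  expect_equal(g$cycle_duration, 1)
  expect_true(g$in_stance)
  g2 <- update_gait_phase(st, 3.7)
  expect_equal(g2$phase, 70)
  expect_false(g2$in_stance)
  # phase saturates just below 100 when a strike is overdue
  g3 <- update_gait_phase(st, 4.5)
  expect_lt(g3$phase, 100)
})

test_that("cycle duration is the median of the last three intervals", {
  st <- c(0, 1, 2.2, 3.1)  # intervals 1, 1.2, 0.9
  g <- update_gait_phase(st, 3.2)
  expect_equal(g$cycle_duration, 1)
})

test_that("speed estimation is affine in cadence and clamped to 1-5 km/h", {
  expect_equal(estimate_speed(1.8, c(1.8, 0)), 1)
  expect_equal(estimate_speed(0.9, c(1.8, 0)), 2)
  expect_equal(estimate_speed(10, c(1.8, 0)), 1)   # clamped low
  expect_equal(estimate_speed(0.1, c(1.8, 0)), 5)  # clamped high
  expect_error(estimate_speed(0, c(1.8, 0)))
})

test_that("noise-free FSR traces give strikes exactly at cycle boundaries", {
  fsr <- gen_fsr_traces(speed = 2, n_cycles = 5, noise = 0, seed = 1)
  cont <- detect_contacts(fsr$frames, thresholds = 0.2)
  s <- heel_strikes(cont)
  expect_equal(length(s), 5)
  expect_equal(s, fsr$strikes, tolerance = 0.01)
})

test_that("with default noise the estimated phase tracks truth within 5% cycle", {
  fsr <- gen_fsr_traces(speed = 2, n_cycles = 8, seed = 2)
  cont <- detect_contacts(fsr$frames, thresholds = 0.2)
  s <- heel_strikes(cont)
  t_probe <- seq(s[2] + 0.05, max(fsr$frames$t), by = 0.05)
  err <- vapply(t_probe, function(tt) {
    g <- update_gait_phase(s, tt)
    truth <- fsr$phase[which.min(abs(fsr$frames$t - tt))]
    d <- abs(g$phase - truth)
    min(d, 100 - d)  # circular distance
  }, numeric(1))
  expect_lt(max(err), 5)
})
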