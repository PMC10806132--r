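test_that("envelope evaluation is periodic, bounded and speed-interpolated", {
  m <- default_envelope_model("soleus")
  ph <- seq(0, 100, by = 0.5)
  v <- emg_envelope(m, 3, ph)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(emg_envelope(m, 3, 0), emg_envelope(m, 3, 100),
               tolerance = 1e-10)
  # linear interpolation between nodes: value at 2.5 km/h lies between the
  # node values (evaluated at the activity peak)
  peak <- ph[which.max(v)]
  v2 <- emg_envelope(m, 2, peak); v3 <- emg_envelope(m, 3, peak)
  v25 <- emg_envelope(m, 2.5, peak)
  expect_gte(v25, min(v2, v3) - 1e-12)
  expect_lte(v25, max(v2, v3) + 1e-12)
})

test_that("envelope evaluation rejects out-of-range speed and phase", {
  m <- default_envelope_model("TA")
  expect_error(emg_envelope(m, 0.5, 10), class = "hybridgait_range_error")
  expect_error(emg_envelope(m, 6, 10), class = "hybridgait_range_error")
  expect_error(emg_envelope(m, 3, c(10, 130)),
               class = "hybridgait_range_error")
})

test_that("fitting recovers smooth per-speed profiles accurately", {
  m <- default_envelope_model("soleus")
  expect_true(all(attr(m, "rmse") < 0.05))
  m_ta <- default_envelope_model("TA")
  expect_true(all(attr(m_ta, "rmse") < 0.05))
  # ill-conditioned fit: fewer grid points than coefficients
  expect_error(
    fit_envelope(list(list(phase = c(0, 50, 100), value = c(0, 1, 0))),
                 speed_nodes = 1, order = 6),
    class = "hybridgait_fit_error")
})

test_that("soleus activity sits in stance and TA spans swing to heel strike", {
  sol <- emg_envelope(default_envelope_model("soleus"), 3, 0:100)
  ta <- emg_envelope(default_envelope_model("TA"), 3, 0:100)
  expect_true(which.max(sol) - 1 >= 20 && which.max(sol) - 1 <= 60)
  expect_gt(ta[1], 0.1)          # active at heel strike
  expect_lt(max(ta[30:55]), 0.1) # quiet through late stance
})

test_that("the default reference table is periodic and self-consistent", {
  tab <- default_reference_table()
  expect_s3_class(tab, "reference_table")
  expect_true(all(tab$k_ref >= 0))
  # torque closes the cycle (its construction integrates k dtheta around it)
  expect_equal(tab$tau_ref[1], tab$tau_ref[nrow(tab)], tolerance = 1e-9)
  expect_equal(tab$theta_ref[1], tab$theta_ref[nrow(tab)], tolerance = 1e-9)
  # angle range of motion is physiological
  rng <- rad2deg(range(tab$theta_ref))
  expect_gt(rng[1], -15)
  expect_lt(rng[2], 20)
})

test_that("lookup interpolates periodically", {
  tab <- default_reference_table()
  r <- lookup_reference(tab, c(0, 100, 250, -50))
  expect_equal(r$theta_ref[1], r$theta_ref[2], tolerance = 1e-12)
  expect_equal(r$theta_ref[3], lookup_reference(tab, 50)$theta_ref,
               tolerance = 1e-12)
  expect_equal(r$theta_ref[4], lookup_reference(tab, 50)$theta_ref,
               tolerance = 1e-12)
})

test_that("moment-angle slope recovers the two stance stiffness peaks", {
  tab <- default_reference_table()
  k <- stiffness_from_moment_angle(tab$theta_ref, tab$tau_ref)
  expect_true(all(k >= 0))
  # locate prominent local maxima (prominence >= 1 Nm/rad over neighbours)
  n <- length(k)
  peaks <- which(k[2:(n - 1)] > k[1:(n - 2)] + 1e-12 &
                   k[2:(n - 1)] > k[3:n] + 1e-12) + 1
  prom <- vapply(peaks, function(p) {
    lo <- max(1, p - 10); hi <- min(n, p + 10)
    k[p] - max(min(k[lo:p]), min(k[p:hi]))
  }, numeric(1))
  big <- tab$phase[peaks[prom >= 1]]
  expect_length(big, 2)
  expect_lt(abs(big[1] - 30), 3)
  expect_lt(abs(big[2] - 50), 3)
})

test_that("degenerate moment-angle curves are rejected", {
  expect_error(stiffness_from_moment_angle(rep(0.1, 10), 1:10),
               class = "hybridgait_domain_error")
})

test_that("reference tables and envelope models round-trip through disk", {
  tab <- default_reference_table()
  f <- tempfile(fileext = ".csv")
  write_reference_table(tab, f)
  tab2 <- read_reference_table(f)
  expect_equal(tab2$theta_ref, tab$theta_ref, tolerance = 1e-9)
  expect_equal(tab2$tau_ref, tab$tau_ref, tolerance = 1e-9)
  expect_equal(tab2$k_ref, tab$k_ref, tolerance = 1e-9)

  m <- default_envelope_model("TA")
  fj <- tempfile(fileext = ".json")
  write_envelope_model(m, fj)
  m2 <- read_envelope_model(fj)
  expect_equal(m2$coeffs, m$coeffs, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(emg_envelope(m2, 2.3, 0:100), emg_envelope(m, 2.3, 0:100),
               tolerance = 1e-9)
  unlink(c(f, fj))
})
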