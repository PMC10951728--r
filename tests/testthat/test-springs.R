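# Spring stiffness profiles: parametric laws, energetics, hysteresis and
# the body-mass stiffness prescription.

test_that("parametric profiles obey the secant constraint and ordering", {
  f_ref <- 844
  dg <- spring_profile("degressive", f_ref)
  ln <- spring_profile("linear", f_ref)
  pg <- spring_profile("progressive", f_ref)
  # identical force at the reference displacement, to machine precision
  expect_identical(spring_force(dg, 0.10), f_ref)
  expect_identical(spring_force(ln, 0.10), f_ref)
  expect_identical(spring_force(pg, 0.10), f_ref)
  # linear proportionality and clamping at zero
  expect_equal(spring_force(ln, 0.05), 422)
  expect_identical(spring_force(ln, 0), 0)
  expect_identical(spring_force(ln, -0.02), 0)
  # independent arithmetic for the nonlinear laws at half compression
  expect_equal(spring_force(dg, 0.05), 844 * 0.5^0.47, tolerance = 1e-12)
  expect_equal(spring_force(dg, 0.05), 609.3, tolerance = 1e-3)
  expect_equal(spring_force(pg, 0.05), 844 * 0.5^3.21, tolerance = 1e-12)
  expect_equal(spring_force(pg, 0.05), 91.2, tolerance = 1e-3)
  # strict DG > LN > PG ordering inside the reference interval
  d <- seq(0.005, 0.095, by = 0.005)
  expect_true(all(spring_force(dg, d) > spring_force(ln, d)))
  expect_true(all(spring_force(ln, d) > spring_force(pg, d)))
  # monotone non-decreasing force on [0, d_ref]
  for (pr in list(dg, ln, pg))
    expect_true(all(diff(spring_force(pr, seq(0, 0.1, length.out = 200))) >= 0))
})

test_that("profile construction rejects inconsistent shapes", {
  expect_error(spring_profile("degressive", 844, exponent = 1.2),
               "inconsistent")
  expect_error(spring_profile("progressive", 844, exponent = 0.5),
               "inconsistent")
  expect_error(spring_profile("linear", 844, exponent = 2), "inconsistent")
  expect_error(spring_profile("linear", -10), "positive")
  expect_error(spring_profile("linear", 844, hysteresis_fraction = 1), "\\[0, 1\\)")
})

test_that("stored energy matches the closed form and the hysteresis budget", {
  f_ref <- 844
  for (q in c(0.47, 1, 3.21)) {
    kind <- if (q < 1) "degressive" else if (q == 1) "linear" else "progressive"
    pr <- spring_profile(kind, f_ref, exponent = q)
    e_quad <- stored_energy(pr, 0.10, n_nodes = 10001)
    e_closed <- f_ref * 0.10 / (q + 1)
    expect_lt(abs(e_quad - e_closed) / e_closed, 1e-4)
  }
  expect_equal(stored_energy(spring_profile("linear", 844), 0.10), 42.2,
               tolerance = 1e-6)
  expect_error(stored_energy(spring_profile("linear", 844), -0.01), ">= 0")
  # loading work - unloading work = hysteresis_fraction * loading work
  h <- 0.25
  pr <- spring_profile("degressive", f_ref, hysteresis_fraction = h)
  e_load <- stored_energy(pr, 0.10)
  e_unload <- stored_energy(pr, 0.10, branch = "unloading")
  expect_lt(abs((e_load - e_unload) - h * e_load) / (h * e_load), 1e-3)
  # lossless limit: unloading force equals loading force at every d
  pr0 <- spring_profile("progressive", f_ref, hysteresis_fraction = 0)
  d <- seq(0, 0.1, length.out = 50)
  expect_identical(spring_force(pr0, d, "unloading"),
                   spring_force(pr0, d, "loading"))
})

test_that("exponent calibration inverts the equal-secant energy ratio", {
  expect_identical(calibrate_exponent(1), 1)
  expect_equal(calibrate_exponent(1.36), 2 / 1.36 - 1, tolerance = 1e-12)
  expect_equal(calibrate_exponent(1.36), 0.4706, tolerance = 1e-4)
  expect_equal(calibrate_exponent(2 / 4.21), 3.21, tolerance = 1e-12)
  expect_error(calibrate_exponent(2), "non-positive exponent")
  expect_error(calibrate_exponent(-1), "positive")
  # round trip: the calibrated exponent reproduces the requested ratio
  for (r in c(0.5, 0.9, 1.2, 1.8)) {
    q <- calibrate_exponent(r)
    expect_equal(2 / (q + 1), r, tolerance = 1e-12)
  }
})

test_that("tabulated profiles interpolate and refuse to extrapolate", {
  d <- seq(0, 0.12, by = 0.01)
  tab <- data.frame(displacement_m = d, force_N = 8440 * d)
  pr <- spring_profile_table(tab)
  expect_equal(spring_force(pr, 0.055), 8440 * 0.055, tolerance = 1e-9)
  expect_error(spring_force(pr, 0.2), "extrapolate")
  expect_error(spring_profile_table(
    data.frame(displacement_m = c(0, 0.01, 0.01), force_N = c(0, 1, 2))),
    "ties|strictly increasing")
  expect_error(spring_profile_table(
    data.frame(displacement_m = c(0.01, 0.02), force_N = c(1, 2))),
    "start at displacement 0")
  # CSV round trip through the file reader
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  pr2 <- read_spring_table(path)
  expect_equal(spring_force(pr2, 0.07), spring_force(pr, 0.07))
})

test_that("mass prescription is proportional and matches reference rows", {
  expect_equal(prescribe_stiffness(58.9), 7.84)
  expect_equal(prescribe_stiffness(77.7), 10.34)
  m <- prescription_model(rounding = 10)
  expect_equal(prescribe_stiffness(120, m), 2 * prescribe_stiffness(60, m),
               tolerance = 1e-9)
  expect_error(prescribe_stiffness(-5), "positive")
  expect_gt(prescription_model()$constant, 0)
})
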