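# Joint angle conventions, range of motion and spatiotemporal summaries.

static_markers <- function(hip, knee, ankle, toe, n = 5) {
  lapply(list(hip = hip, knee = knee, ankle = ankle, toe = toe),
         function(p) matrix(p, nrow = n, ncol = 2, byrow = TRUE))
}

test_that("angle conventions: straight knee 180, anatomical ankle 90", {
  # collinear hip-knee-ankle, foot perpendicular to a vertical shank
  mk <- static_markers(hip = c(0, 0.9), knee = c(0, 0.5), ankle = c(0, 0.1),
                       toe = c(0.15, 0.1))
  ja <- joint_angles(mk, 200)
  expect_equal(ja$angle_knee[1], 180)
  expect_equal(ja$angle_ankle[1], 90)
  expect_equal(ja$angle_hip[1], 180)
  # foot tilted 20 degrees toes-down: plantarflexion increases the angle
  mk2 <- static_markers(hip = c(0, 0.9), knee = c(0, 0.5), ankle = c(0, 0.1),
                        toe = c(0, 0.1) + 0.15 * c(cos(-20 * pi / 180),
                                                   sin(-20 * pi / 180)))
  expect_equal(joint_angles(mk2, 200)$angle_ankle[1], 110, tolerance = 1e-9)
  # thigh flexed 25 degrees forward reduces the hip angle below 180
  mk3 <- static_markers(hip = c(0, 0.9),
                        knee = c(0, 0.9) + 0.4 * c(sin(25 * pi / 180),
                                                   -cos(25 * pi / 180)),
                        ankle = c(0, 0.1), toe = c(0.15, 0.1))
  expect_equal(joint_angles(mk3, 200)$angle_hip[1], 155, tolerance = 1e-9)
  expect_error(joint_angles(mk[c("hip", "knee", "ankle")], 200),
               "missing required marker 'toe'")
})

test_that("range of motion and peak flexion summarize per-cycle extremes", {
  rate <- 200
  t <- (0:799) / rate
  cycles <- make_cycles(start = c(1L, 401L), end = c(400L, 800L),
                        toeoff = c(250L, 650L), rate = rate)
  angles <- data.frame(
    time = t,
    angle_ankle = rep(120, 800),                      # constant: ROM 0
    angle_knee = 150 + 15 * sin(2 * pi * t / 2),      # amplitude 15: ROM 30
    angle_hip = 170 - 10 * abs(sin(pi * t / 2)))
  rp <- rom_and_peaks(angles, cycles)
  expect_equal(rp$rom_deg[rp$joint == "ankle"], 0)
  expect_equal(rp$rom_deg[rp$joint == "knee"], 30, tolerance = 1e-3)
  expect_equal(rp$peak_flexion_deg[rp$joint == "ankle"], 120)
  expect_equal(rp$peak_flexion_deg[rp$joint == "hip"], 160, tolerance = 1e-3)
})

test_that("generator joint-angle extremes are recovered on noiseless data", {
  sim <- nh_sim()
  an <- nh_analysis()
  ja <- joint_angles(sim$trial$markers$L, 200)   # unfiltered angles
  rp <- rom_and_peaks(ja, an$cycles)
  cyc <- an$cycles$cycles
  for (j in c("ankle", "knee", "hip")) {
    tr <- sim$truth[[paste0("angle_", j)]]
    roms <- mapply(function(s, e) diff(range(tr[s:e])), cyc$start, cyc$end)
    expect_equal(rp$rom_deg[rp$joint == j], mean(roms), tolerance = 0.1)
  }
})

test_that("spatiotemporal summary matches closed-form hopping mechanics", {
  # sharp half-sine pulse: detected events sit within ~1 ms of the true
  # contact boundaries, so frequency, contact time and the two hop-height
  # routes can be checked against the generator's closed forms
  an <- g1_analysis()
  st <- an$spatiotemporal
  expect_equal(st$hop_frequency_hz, 2.4, tolerance = 0.005 / 2.4)
  expect_lt(abs(st$contact_time_s - 0.26), 0.015)
  # force-integration (Cavagna) height vs ballistic flight-time height
  t_air <- mean(an$cycles_grf$cycles$aerial_time_s)
  expect_equal(st$hop_height_cm, 9.81 * t_air^2 / 8 * 100, tolerance = 0.05)
  expect_equal(st$hop_height_cm, 9.81 * (1 / 2.4 - 0.26)^2 / 8 * 100,
               tolerance = 0.4)
  expect_error(spatiotemporal(rep(100, 100), an$cycles_grf, mass = 0),
               "positive")
})
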