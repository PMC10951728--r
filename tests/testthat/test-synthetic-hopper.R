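# Synthetic hopping trials: impulse balance, closed-form pulse peaks,
# realistic default ranges, exoskeleton ground-truth consistency and
# reproducibility.

test_that("mean summed vGRF over integer cycles balances body weight", {
  for (sim in list(nh_sim(), g1_sim())) {
    fsum <- sim$trial$grf$L$fz + sim$trial$grf$R$fz
    m <- sim$trial$participant$mass
    expect_lt(abs(mean(fsum) - m * 9.81) / (m * 9.81), 1e-3)
  }
})

test_that("half-sine pulse peak matches the closed-form impulse balance", {
  # gamma = 1, 66 kg, 2.4 Hz, 0.26 s contact: F_peak = (pi/2) m g T / t_c
  sim <- g1_sim()
  fsum <- sim$trial$grf$L$fz + sim$trial$grf$R$fz
  expected <- (pi / 2) * 66 * 9.81 * (1 / 2.4) / 0.26
  expect_equal(max(fsum), expected, tolerance = 1e-3)
})

test_that("default trial lands in the study's kinetic envelope", {
  sim <- nh_sim()
  fsum <- sim$trial$grf$L$fz + sim$trial$grf$R$fz
  expect_gt(max(fsum), 2000)
  expect_lt(max(fsum), 2600)
  tr <- sim$truth
  disp <- max(tr$com_y) - min(tr$com_y[tr$contact])
  # aerial rise is above the standing height; contact-phase drop from the
  # contact-onset height is what the 8-12 cm envelope describes
  onset_h <- max(tr$com_y[tr$contact])
  drop <- onset_h - min(tr$com_y[tr$contact])
  expect_gt(drop, 0.08)
  expect_lt(drop, 0.12)
})

test_that("marker-derived joint angles reproduce the generating waveforms", {
  sim <- nh_sim()
  ja <- joint_angles(sim$trial$markers$L, sim$trial$markers$rate)
  for (j in c("ankle", "knee", "hip"))
    expect_equal(ja[[paste0("angle_", j)]], sim$truth[[paste0("angle_", j)]],
                 tolerance = 1e-9)
})

test_that("ground-truth exoskeleton force equals the spring law exactly", {
  sim <- dg_sim()
  mk <- sim$trial$markers$L
  dist <- sqrt(rowSums((mk$exo_hip - mk$exo_foot)^2))
  d <- pmax(0, sim$trial$exo$rest_length - dist)
  f <- spring_force(sim$trial$exo$profile, d)
  expect_equal(sim$truth$force_n, f, tolerance = 1e-12)
  # no force whenever the trial is airborne
  expect_true(all(sim$truth$force_n[!sim$truth$contact] == 0))
  expect_true(all(sim$truth$disp_m[!sim$truth$contact] == 0))
})

test_that("trials are byte-identical under a fixed seed", {
  p <- hopper_params(n_hops = 3, seed = 99, marker_noise_sd = 0.002,
                     exo = prescribed_exo("LN", 70))
  s1 <- simulate_trial(p)
  s2 <- simulate_trial(p)
  expect_identical(s1, s2)
  s3 <- simulate_trial(hopper_params(n_hops = 3, seed = 100,
                                     marker_noise_sd = 0.002))
  expect_false(identical(s1$trial$markers$L$hip, s3$trial$markers$L$hip))
})

test_that("parameter validation catches infeasible configurations", {
  expect_error(hopper_params(contact_time = 0.5), "shorter than the hop period")
  expect_error(hopper_params(joint_amplitude_weights =
                               c(ankle = 0.5, knee = 0.5, hip = 0.5)),
               "summing to 1")
  expect_error(hopper_params(joint_amplitude_weights =
                               c(ankle = 0.1, knee = 0.8, hip = 0.1)),
               "infeasible")
  expect_error(hopper_params(grf_rate = 999), "integer multiple")
  # a hop requiring more shortening than the chain can fold
  expect_error(simulate_trial(hopper_params(hop_frequency = 1.2,
                                            contact_time = 0.7)),
               "infeasible geometry")
})

test_that("cohorts enumerate participants x conditions deterministically", {
  tpl <- hopper_params(n_hops = 2)
  co <- emit_cohort(3, conditions = c("NH", "DG"), params_template = tpl,
                    seed = 4)
  expect_length(co, 6)
  man <- attr(co, "manifest")
  expect_equal(nrow(man), 6)
  expect_setequal(unique(man$condition), c("NH", "DG"))
  co2 <- emit_cohort(3, conditions = c("NH", "DG"), params_template = tpl,
                     seed = 4)
  expect_identical(co[[2]]$trial$markers$L$hip, co2[[2]]$trial$markers$L$hip)
  expect_error(emit_cohort(1), ">= 2")
  expect_error(emit_cohort(3, conditions = character(0)), "non-empty")
  # outcome tables: complete crossed design with the requested effects
  out <- emit_cohort(5, outcomes_only = TRUE, seed = 2,
                     effects = c(NH = 0, DG = -10, LN = 0, PG = 0),
                     within_sd = 0.1)
  expect_equal(nrow(out), 20)
  dg_shift <- mean(out$value[out$condition == "DG"]) -
    mean(out$value[out$condition == "NH"])
  expect_equal(dg_shift, -10, tolerance = 0.5)
})
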