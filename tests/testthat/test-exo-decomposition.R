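# Exoskeleton geometry, moment arms and sign logic, the decomposition
# identity, hysteresis bookkeeping and the spring-power consistency check.

line_geometry <- function(hip, foot, n = 10, rest_length = NULL) {
  exo_geometry(matrix(hip, n, 2, byrow = TRUE),
               matrix(foot, n, 2, byrow = TRUE), rest_length = rest_length)
}

test_that("spring displacement clamps at the rest length", {
  g <- line_geometry(c(0, 0.9), c(0, 0), rest_length = 0.9)
  expect_equal(spring_displacement(g), rep(0, 10))
  g2 <- line_geometry(c(0, 0.8), c(0, 0), rest_length = 0.9)
  expect_equal(spring_displacement(g2), rep(0.1, 10))
  g3 <- line_geometry(c(0, 1.0), c(0, 0), rest_length = 0.9)
  expect_equal(spring_displacement(g3), rep(0, 10))
  expect_error(line_geometry(c(0, 0.9), c(0, 0), rest_length = -1),
               "positive")
  expect_error(line_geometry(c(0, 0.5), c(0, 0.5)), "degenerate")
})

test_that("moment arm is the point-to-line distance with a side indicator", {
  g <- line_geometry(c(0, 1), c(0, 0))   # vertical line x = 0, force down
  on_line <- moment_arm(c(0, 0.4), g)
  expect_equal(on_line$arm_m, rep(0, 10))
  anterior <- moment_arm(c(0.05, 0.4), g)
  posterior <- moment_arm(c(-0.03, 0.4), g)
  expect_equal(anterior$arm_m, rep(0.05, 10))
  expect_equal(posterior$arm_m, rep(0.03, 10))
  expect_true(all(anterior$side != posterior$side))
})

test_that("moment signs follow the extensor/plantarflexor convention", {
  # vertical line of action through the toe; spring force 844 N
  n <- 4
  geom <- line_geometry(c(0, 1.0), c(0, 0), n = n, rest_length = 1.1)
  prof <- spring_profile("linear", 844)
  omega <- data.frame(omega_ankle = rep(1, n), omega_knee = 1, omega_hip = 1)
  joints <- list(ankle = matrix(c(-0.05, 0.1), n, 2, byrow = TRUE),
                 knee = matrix(c(0.04, 0.5), n, 2, byrow = TRUE),
                 hip = matrix(c(0.03, 1.0), n, 2, byrow = TRUE))
  ek <- exo_joint_kinetics(geom, prof, joints, omega)
  expect_equal(ek$disp_m, rep(0.1, n))
  expect_equal(ek$force_n, rep(844, n))
  # line anterior to the ankle: plantarflexor-assisting, +F * arm
  expect_equal(ek$m_exo_ankle, rep(844 * 0.05, n))
  # line anterior to the knee: extensor-assisting
  expect_gt(ek$m_exo_knee[1], 0)
  expect_equal(abs(ek$m_exo_knee[1]), 844 * 0.04)
  # line posterior to the hip centre: flexor-signed hip moment
  expect_lt(ek$m_exo_hip[1], 0)
  expect_equal(abs(ek$m_exo_hip[1]), 844 * 0.03)
  # P = M * omega at every sample
  expect_equal(ek$p_exo_ankle, ek$m_exo_ankle * omega$omega_ankle)
})

test_that("moment arms and exo moments recover ground truth exactly", {
  sim <- dg_sim()
  mk <- sim$trial$markers$L                 # noiseless markers
  geom <- exo_geometry(mk$exo_hip, mk$exo_foot,
                       rest_length = sim$trial$exo$rest_length)
  for (j in c("ankle", "knee", "hip"))
    expect_equal(moment_arm(mk[[j]], geom)$arm_m,
                 sim$truth[[paste0("arm_", j)]], tolerance = 1e-10)
  omega <- joint_angles(mk, 200)
  ek <- exo_joint_kinetics(geom, sim$trial$exo$profile,
                           joints = mk[c("ankle", "knee", "hip")],
                           omega = omega)
  for (j in c("ankle", "knee", "hip"))
    expect_equal(ek[[paste0("m_exo_", j)]],
                 sim$truth[[paste0("m_exo_", j)]], tolerance = 1e-9)
})

test_that("loading/unloading branches key on the displacement rate", {
  d <- c(0, 0.02, 0.05, 0.08, 0.08, 0.05, 0.02, 0)
  br <- hopexo:::displacement_branches(d)
  expect_equal(br[2:4], rep("loading", 3))
  expect_equal(br[6:8], rep("unloading", 3))
})

test_that("decomposition identity and the no-exoskeleton degenerate case", {
  overall <- data.frame(time = 1:5 / 200,
                        m_ankle = c(2, 1, 0, -1, 3), m_knee = 1,
                        m_hip = -0.5,
                        omega_ankle = 1, omega_knee = 2, omega_hip = 0,
                        p_ankle = c(2, 1, 0, -1, 3), p_knee = 2, p_hip = 0)
  d0 <- decompose(overall, NULL)
  expect_equal(d0$m_mtu_ankle, overall$m_ankle)
  expect_equal(d0$m_exo_ankle, rep(0, 5))
  exo <- data.frame(m_exo_ankle = 0.5, m_exo_knee = 0.25, m_exo_hip = -0.1,
                    p_exo_ankle = 0.5, p_exo_knee = 0.5, p_exo_hip = 0)[rep(1, 5), ]
  d1 <- decompose(overall, exo)
  expect_equal(d1$m_mtu_ankle, overall$m_ankle - 0.5)
  expect_identical(d1$m_mtu_ankle + d1$m_exo_ankle, d1$m_overall_ankle)
  expect_error(decompose(overall, exo[1:3, ]), "misaligned")
})

test_that("per-cycle energy returned equals (1 - hysteresis) x stored", {
  an <- ln_hyst_analysis()
  k <- an$exo$L
  cyc <- an$cycles$cycles
  for (ci in 2:(nrow(cyc) - 1)) {
    i <- cyc$start[ci]:cyc$end[ci]
    dd <- diff(k$disp_m[i])
    fmid <- (k$force_n[i][-1] + k$force_n[i][-length(i)]) / 2
    stored <- sum((fmid * dd)[dd > 0])
    returned <- -sum((fmid * dd)[dd < 0])
    expect_equal(returned / stored, 0.8, tolerance = 0.01)
  }
  # with hysteresis, positive exo power strictly exceeds the magnitude of
  # negative exo power returned, at the spring level
  rate_len <- hopexo:::central_diff(an$geometry$L$dist, 1 / 200)
  p_spring <- k$force_n * rate_len
  expect_gt(-sum(p_spring[p_spring < 0]), sum(p_spring[p_spring > 0]))
})

test_that("summed exo joint power never exceeds spring-delivered power", {
  for (an in list(dg_analysis(), ln_hyst_analysis(), pg_analysis())) {
    expect_true(an$exo_check$pass)
    expect_lte(an$exo_check$joint_power_w,
               an$exo_check$spring_power_w * 1.02 + 1e-9)
  }
  nh <- nh_analysis()
  expect_true(nh$exo_check$pass)
  expect_identical(nh$exo_check$joint_power_w, 0)
  expect_identical(nh$exo_check$spring_power_w, 0)
  # constructed violation: doubling the moment arms must fail the check
  an <- dg_analysis()
  k2 <- an$exo$L
  for (j in c("ankle", "knee", "hip")) {
    k2[[paste0("m_exo_", j)]] <- 2 * k2[[paste0("m_exo_", j)]]
    k2[[paste0("p_exo_", j)]] <- 2 * k2[[paste0("p_exo_", j)]]
  }
  expect_false(exo_power_check(k2, an$geometry$L, an$cycles, 200)$pass)
})
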