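# Link-segment inverse dynamics: anthropometrics, statics oracles and
# consistency with the point-mass generator.

# independent statics oracle: moment about each joint from the GRF and the
# weights of the segments distal to it, under the extensor-positive sign
# convention (no inertial terms)
statics_moments <- function(mk, grf, params) {
  g <- 9.81
  segs <- params$segments
  seg_com <- function(seg, prox, dist)
    prox + segs$com_fraction[segs$segment == seg] * (dist - prox)
  seg_mass <- function(seg) segs$mass_kg[segs$segment == seg]
  cross2 <- function(r, f) r[, 1] * f[, 2] - r[, 2] * f[, 1]
  coms <- list(foot = seg_com("foot", mk$ankle, mk$toe),
               shank = seg_com("shank", mk$knee, mk$ankle),
               thigh = seg_com("thigh", mk$hip, mk$knee))
  fgrf <- cbind(grf$fx, grf$fz)
  cop <- cbind(grf$copx, 0)
  distal <- list(ankle = "foot", knee = c("foot", "shank"),
                 hip = c("foot", "shank", "thigh"))
  sgn <- c(ankle = -1, knee = 1, hip = -1)
  out <- list()
  for (j in names(distal)) {
    jc <- mk[[j]]
    mz <- cross2(cop - jc, fgrf)
    for (s in distal[[j]]) {
      w <- cbind(0 * fgrf[, 1], rep(-seg_mass(s) * g, nrow(fgrf)))
      mz <- mz + cross2(coms[[s]] - jc, w)
    }
    out[[j]] <- -sgn[[j]] * mz
  }
  out
}

test_that("segment parameters follow the anthropometric table", {
  sp <- segment_parameters(66, c(foot = 0.10, shank = 0.41, thigh = 0.42))
  tab <- data.frame(segment = c("foot", "shank", "thigh"),
                    fraction = c(0.0145, 0.0465, 0.1000))
  expect_equal(sp$segments$mass_kg, tab$fraction * 66)
  expect_equal(sum(sp$segments$mass_kg) / 66, sum(tab$fraction))
  expect_lt(sum(sp$segments$mass_kg), 66)
  # zero exoskeleton mass leaves the parameters untouched
  sp0 <- segment_parameters(66, c(foot = 0.10, shank = 0.41, thigh = 0.42),
                            exo_leg_mass = 0)
  expect_equal(sp0$segments, sp$segments)
  expect_equal(sp0$exo_point_mass_foot, 0)
  expect_error(segment_parameters(66, c(foot = 0.1, shank = 0.41,
                                        thigh = 0.42), table_id = "nope"),
               "unknown anthropometric table")
  expect_error(segment_parameters(-1, c(foot = 0.1, shank = 0.41,
                                        thigh = 0.42)), "positive")
})

test_that("static toe-stand reduces to force times moment arm", {
  # static pose, near-massless segments, vertical force F at a horizontal
  # distance r anterior of the ankle: ankle moment = F * r (plantarflexor
  # positive); all powers vanish with zero angular velocity
  n <- 50
  mk <- lapply(list(hip = c(-0.05, 0.90), knee = c(0.05, 0.48),
                    ankle = c(-0.07, 0.07), toe = c(0, 0)),
               function(p) matrix(p, n, 2, byrow = TRUE))
  f <- 600; r <- 0.07
  grf <- data.frame(fz = rep(f, n), fx = 0, copx = 0)
  params <- segment_parameters(1e-9, c(foot = 0.1, shank = 0.42,
                                       thigh = 0.43))
  id <- inverse_dynamics(mk, grf, params, rate = 200)
  expect_equal(id$m_ankle[25], f * r, tolerance = 1e-6)
  expect_equal(max(abs(id$p_ankle)), 0, tolerance = 1e-9)
  expect_equal(max(abs(id$p_knee)), 0, tolerance = 1e-9)
})

test_that("zero GRF and zero acceleration leave gravitational moments", {
  n <- 50
  mk <- lapply(list(hip = c(-0.05, 0.90), knee = c(0.05, 0.48),
                    ankle = c(-0.07, 0.07), toe = c(0, 0)),
               function(p) matrix(p, n, 2, byrow = TRUE))
  grf <- data.frame(fz = rep(0, n), fx = 0, copx = 0)
  params <- segment_parameters(66, c(foot = 0.1, shank = 0.42, thigh = 0.43))
  id <- inverse_dynamics(mk, grf, params, rate = 200,
                         contact = rep(FALSE, n))
  oracle <- statics_moments(mk, grf, params)
  for (j in c("ankle", "knee", "hip"))
    expect_equal(id[[paste0("m_", j)]][25], oracle[[j]][25],
                 tolerance = 1e-9)
})

test_that("quasi-static trials match the statics oracle within 2%", {
  # time-dilate a standard trial 10x by reinterpreting the sampling rate:
  # identical poses, accelerations scaled by 1/100
  sim <- nh_sim()
  cfg <- analysis_config()
  mk <- lapply(sim$trial$markers$L, lowpass, rate = 200, cutoff_hz = 20)
  dec <- seq(1, by = 5, length.out = length(sim$trial$markers$time))
  grf <- data.frame(
    fz = lowpass(sim$trial$grf$L$fz, 1000, 20)[dec],
    fx = lowpass(sim$trial$grf$L$fx, 1000, 20)[dec],
    copx = sim$trial$grf$L$copx[dec])
  params <- segment_parameters(66, c(foot = 0.10, shank = 0.41,
                                     thigh = 0.42))
  id_slow <- inverse_dynamics(mk, grf, params, rate = 20)
  oracle <- statics_moments(mk, grf, params)
  use <- 100:(nrow(grf) - 100)
  for (j in c("ankle", "knee", "hip")) {
    err <- id_slow[[paste0("m_", j)]][use] - oracle[[j]][use]
    expect_lt(sqrt(mean(err^2)) / max(abs(oracle[[j]])), 0.02)
  }
})

test_that("summed ankle moment tracks the point-mass prediction within 5%", {
  sim <- nh_sim()
  an <- nh_analysis()
  # point-mass-consistent prediction: GRF moment about the ankle only
  mk <- lapply(sim$trial$markers$L, lowpass, rate = 200, cutoff_hz = 20)
  dec <- seq(1, by = 5, length.out = length(sim$trial$markers$time))
  fz <- lowpass(sim$trial$grf$L$fz, 1000, 20)[dec]
  # plantarflexor-positive moment of a vertical GRF at the toe about the
  # ankle, per leg: fz * (cop_x - ankle_x); both legs summed
  pred <- 2 * fz * (0 - mk$ankle[, 1])
  idx <- interior_cycle_samples(an)
  idx <- idx[an$contact[idx]]
  err <- an$kinetics$sum$m_overall_ankle[idx] - pred[idx]
  expect_lt(sqrt(mean(err^2)) / max(abs(pred[idx])), 0.05)
})

test_that("centre of pressure outside the foot warns but does not fail", {
  n <- 50
  mk <- lapply(list(hip = c(-0.05, 0.90), knee = c(0.05, 0.48),
                    ankle = c(-0.07, 0.07), toe = c(0, 0)),
               function(p) matrix(p, n, 2, byrow = TRUE))
  grf <- data.frame(fz = rep(500, n), fx = 0, copx = 0.8)
  params <- segment_parameters(66, c(foot = 0.1, shank = 0.42, thigh = 0.43))
  expect_warning(inverse_dynamics(mk, grf, params, rate = 200),
                 "centre of pressure")
})
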