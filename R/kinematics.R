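# Sagittal-plane joint kinematics and spatiotemporal summaries.
# Convention: joint angles are inter-segment angles in degrees, where an
# increase is extension (knee, hip) or plantarflexion (ankle); a 90-degree
# ankle angle is the anatomical reference position (foot perpendicular to
# shank) and a straight knee is 180 degrees. The pelvis is taken as
# vertical above the hip joint centre.

#' Sagittal-plane joint angles and angular velocities for one leg
#'
#' Hip, knee and ankle angles from single-point joint centres: the hip angle
#' is the pelvis--thigh inter-segment angle (pelvis vertical), the knee the
#' thigh--shank angle, and the ankle the shank--foot angle (which carries
#' the 90-degree anatomical offset by construction). Angular velocities are
#' central differences of the angles, in rad/s, positive in extension /
#' plantarflexion.
#'
#' @param leg_markers Named list of `n x 2` sagittal-plane trajectories (m)
#'   with at least `hip`, `knee`, `ankle`, `toe`.
#' @param rate Sampling rate (Hz).
#' @return Data frame with columns `time`, `angle_ankle`, `angle_knee`,
#'   `angle_hip` (degrees) and `omega_ankle`, `omega_knee`, `omega_hip`
#'   (rad/s).
#' @export
joint_angles <- function(leg_markers, rate) {
  for (m in c("hip", "knee", "ankle", "toe"))
    if (is.null(leg_markers[[m]]))
      stop(sprintf("missing required marker '%s'.", m))
  hip <- leg_markers$hip; knee <- leg_markers$knee
  ankle <- leg_markers$ankle; toe <- leg_markers$toe
  n <- nrow(hip)
  vec_angle <- function(u, v) {
    cu <- sqrt(rowSums(u^2)); cv <- sqrt(rowSums(v^2))
    acos(pmin(1, pmax(-1, rowSums(u * v) / (cu * cv)))) * 180 / pi
  }
  a_ankle <- vec_angle(knee - ankle, toe - ankle)
  a_knee <- vec_angle(hip - knee, ankle - knee)
  # signed thigh tilt from vertical, anterior positive; hip angle is 180
  # minus the tilt so extension past vertical exceeds 180 degrees
  tilt <- atan2(knee[, 1] - hip[, 1], hip[, 2] - knee[, 2]) * 180 / pi
  a_hip <- 180 - tilt
  dt <- 1 / rate
  out <- data.frame(time = (seq_len(n) - 1L) * dt,
                    angle_ankle = a_ankle, angle_knee = a_knee,
                    angle_hip = a_hip)
  for (j in c("ankle", "knee", "hip"))
    out[[paste0("omega_", j)]] <-
      central_diff(out[[paste0("angle_", j)]], dt) * pi / 180
  out
}

# first derivative by central differences; one-sided at the ends
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n < 2L) return(d)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# second derivative by central differences; endpoints copy neighbours
central_diff2 <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n < 3L) return(d)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d[1] <- d[2]
  d[n] <- d[n - 1]
  d
}

#' Range of motion and peak flexion per joint
#'
#' ROM is the difference between the maximum and minimum joint angle within
#' each hop cycle, averaged over cycles; peak flexion is the per-cycle
#' minimum angle (flexion decreases the angle under this convention),
#' averaged over cycles.
#'
#' @param angles Output of [joint_angles()] (or a leg-averaged equivalent).
#' @param cycles A `hop_cycles` object on the same sampling grid.
#' @return Data frame with columns `joint`, `rom_deg`, `peak_flexion_deg`.
#' @export
rom_and_peaks <- function(angles, cycles) {
  stopifnot(inherits(cycles, "hop_cycles"))
  cyc <- cycles$cycles
  if (nrow(cyc) < 1L) stop("need at least one complete hop cycle.")
  out <- lapply(c("ankle", "knee", "hip"), function(j) {
    a <- angles[[paste0("angle_", j)]]
    roms <- mapply(function(s, e) diff(range(a[s:e])), cyc$start, cyc$end)
    mins <- mapply(function(s, e) min(a[s:e]), cyc$start, cyc$end)
    data.frame(joint = j, rom_deg = mean(roms),
               peak_flexion_deg = mean(mins))
  })
  do.call(rbind, out)
}

#' Spatiotemporal hopping summary
#'
#' Hop frequency from mean cycle duration, contact time from the contact
#' events, peak summed vertical GRF per cycle (cycle-averaged), and hop
#' height from the takeoff vertical velocity of the centre of mass obtained
#' by integrating net vertical force over the cycle (the
#' force-integration route): `h = v_to^2 / (2 g)`.
#'
#' @param vgrf Summed (both legs) vertical GRF (N) on the grid `cycles` was
#'   detected on.
#' @param cycles A `hop_cycles` object.
#' @param mass Body (plus carried) mass (kg).
#' @return One-row data frame: `hop_frequency_hz`, `contact_time_s`,
#'   `peak_vgrf_n`, `hop_height_cm`.
#' @export
spatiotemporal <- function(vgrf, cycles, mass) {
  stopifnot(inherits(cycles, "hop_cycles"))
  if (mass <= 0) stop("`mass` must be positive.")
  cyc <- cycles$cycles
  if (nrow(cyc) < 2L) stop("need at least two complete hop cycles.")
  rate <- cycles$rate
  g <- 9.81
  dur <- (cyc$end - cyc$start + 1L) / rate
  peak <- mapply(function(s, e) max(vgrf[s:e]), cyc$start, cyc$end)
  hh <- mapply(function(s, e, toff) {
    idx <- s:e
    t <- (idx - idx[1]) / rate
    a <- vgrf[idx] / mass - g
    v <- pracma::cumtrapz(t, a)[, 1]
    v <- v - mean(v)          # stationary hopping: cycle-mean velocity is 0
    vto <- v[toff - s + 1L]
    vto^2 / (2 * g) * 100
  }, cyc$start, cyc$end, cyc$toeoff)
  data.frame(hop_frequency_hz = 1 / mean(dur),
             contact_time_s = mean(cyc$contact_time_s),
             peak_vgrf_n = mean(peak),
             hop_height_cm = mean(hh))
}
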