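# Planar link-segment inverse dynamics: bottom-up Newton-Euler over
# foot -> shank -> thigh in the sagittal plane (x forward, y up), yielding
# overall joint moments at the ankle, knee and hip. Moments are reported as
# scalars under the extensor/plantarflexor-positive convention; in 2D the
# resolution "in the proximal segment's coordinate system" reduces to this
# single sagittal component.

#' Anthropometric segment parameters
#'
#' Per-segment mass, centre-of-mass position and radius of gyration as
#' fractions of body mass and segment length, from a Winter-style
#' anthropometric table (per-leg values; `com_fraction` is measured from
#' the proximal end). The exoskeleton's 'leg' mass, when worn, is carried as
#' a point mass at the foot attachment (its hip-attachment share rides on
#' the waist harness, proximal to every joint analysed, and therefore does
#' not enter the bottom-up recursion).
#'
#' @param mass Body mass (kg).
#' @param segment_lengths Named lengths (m): `foot` (ankle--toe), `shank`,
#'   `thigh`.
#' @param table_id Anthropometric table identifier; `"winter"` is provided.
#' @param exo_leg_mass Mass of one exoskeleton leg (kg), default 0.
#' @param exo_mass_split Fractions of `exo_leg_mass` assigned to the foot
#'   and hip attachments (named `foot`, `hip`), default 50/50.
#' @return Object of class `segment_params`.
#' @export
segment_parameters <- function(mass, segment_lengths,
                               table_id = "winter", exo_leg_mass = 0,
                               exo_mass_split = c(foot = 0.5, hip = 0.5)) {
  if (mass <= 0) stop("`mass` must be positive.")
  tab <- anthropometric_table(table_id)
  req <- c("foot", "shank", "thigh")
  if (!all(req %in% names(segment_lengths)))
    stop("`segment_lengths` must be named foot/shank/thigh.")
  segs <- data.frame(
    segment = tab$segment,
    length_m = as.numeric(segment_lengths[tab$segment]),
    mass_kg = tab$mass_fraction * mass,
    com_fraction = tab$com_fraction,
    rog_fraction = tab$rog_fraction)
  structure(list(table_id = table_id, body_mass = mass, segments = segs,
                 exo_point_mass_foot = exo_leg_mass * exo_mass_split[["foot"]],
                 exo_point_mass_hip = exo_leg_mass * exo_mass_split[["hip"]]),
            class = "segment_params")
}

anthropometric_table <- function(table_id = "winter") {
  if (!identical(table_id, "winter"))
    stop(sprintf("unknown anthropometric table '%s' (available: 'winter').",
                 table_id))
  data.frame(
    segment = c("foot", "shank", "thigh"),
    mass_fraction = c(0.0145, 0.0465, 0.1000),
    com_fraction = c(0.500, 0.433, 0.433),
    rog_fraction = c(0.475, 0.302, 0.323))
}

#' Planar inverse dynamics for one leg
#'
#' Bottom-up Newton-Euler recursion over the foot, shank and thigh using
#' filtered marker trajectories and the leg's ground reaction force on a
#' common analysis grid. Segment linear accelerations come from double
#' central differences of the segment centres of mass, angular
#' accelerations from the segment orientation angle. Joint powers are the
#' product of the conventional joint moment and the joint angular velocity,
#' so `P = M * omega` holds at every sample by construction.
#'
#' @param leg_markers Named list of filtered `n x 2` trajectories (m):
#'   `hip`, `knee`, `ankle`, `toe`, and `exo_foot` when an exoskeleton
#'   point mass is carried.
#' @param grf Data frame with `fz`, `fx` (N) and `copx` (m) on the same
#'   grid.
#' @param params A [segment_parameters()].
#' @param rate Sampling rate (Hz).
#' @param contact Optional logical vector: samples with ground contact.
#'   When omitted, samples with `fz > 0` are treated as contact.
#' @return Data frame with per-sample conventional joint moments
#'   `m_ankle`, `m_knee`, `m_hip` (N m, extensor/plantarflexor positive),
#'   powers `p_ankle`, `p_knee`, `p_hip` (W), and the joint angular
#'   velocities used.
#' @export
inverse_dynamics <- function(leg_markers, grf, params, rate,
                             contact = NULL) {
  stopifnot(inherits(params, "segment_params"))
  n <- nrow(leg_markers$hip)
  if (nrow(grf) != n)
    stop("markers and GRF must share the analysis grid (equal lengths).")
  if (is.null(contact)) contact <- grf$fz > 0
  dt <- 1 / rate
  g <- 9.81
  ja <- joint_angles(leg_markers, rate)

  fgrf <- cbind(grf$fx, grf$fz)
  cop <- cbind(grf$copx, 0)
  # flag (but tolerate) centre of pressure outside the foot segment
  if (any(contact)) {
    xr <- range(c(leg_markers$ankle[contact, 1], leg_markers$toe[contact, 1]))
    bad <- contact & (grf$copx < xr[1] - 0.05 | grf$copx > xr[2] + 0.05)
    if (any(bad))
      warning(sprintf(
        "centre of pressure falls outside the foot segment on %d contact samples.",
        sum(bad)))
  }

  segs <- params$segments
  seg_row <- function(s) segs[segs$segment == s, ]
  pt_foot <- params$exo_point_mass_foot
  att <- if (pt_foot > 0) {
    if (is.null(leg_markers$exo_foot))
      stop("exoskeleton point mass requested but marker 'exo_foot' is missing.")
    leg_markers$exo_foot
  } else NULL

  segment_state <- function(prox, dist, row, point_mass = 0, point_at = NULL) {
    com_seg <- prox + row$com_fraction * (dist - prox)
    m_seg <- row$mass_kg
    i_seg <- m_seg * (row$rog_fraction * row$length_m)^2
    if (point_mass > 0) {
      m_tot <- m_seg + point_mass
      com <- (m_seg * com_seg + point_mass * point_at) / m_tot
      i_tot <- i_seg + m_seg * rowSums((com_seg - com)^2) +
        point_mass * rowSums((point_at - com)^2)
    } else {
      m_tot <- m_seg; com <- com_seg; i_tot <- i_seg
    }
    theta <- unwrap_angle(atan2(dist[, 2] - prox[, 2], dist[, 1] - prox[, 1]))
    list(m = m_tot, com = com, inertia = i_tot,
         acc = cbind(central_diff2(com[, 1], dt), central_diff2(com[, 2], dt)),
         alpha = central_diff2(theta, dt))
  }

  cross2 <- function(r, f) r[, 1] * f[, 2] - r[, 2] * f[, 1]

  foot <- segment_state(leg_markers$ankle, leg_markers$toe, seg_row("foot"),
                        point_mass = pt_foot, point_at = att)
  shank <- segment_state(leg_markers$knee, leg_markers$ankle, seg_row("shank"))
  thigh <- segment_state(leg_markers$hip, leg_markers$knee, seg_row("thigh"))

  weight <- function(seg) cbind(rep(0, n), rep(-seg$m * g, n))
  # foot: GRF + weight + ankle reaction = m a ; I alpha = M + moments
  r_ankle_f <- foot$m * foot$acc - weight(foot) - fgrf
  m_ankle_z <- foot$inertia * foot$alpha -
    cross2(cop - foot$com, fgrf) -
    cross2(leg_markers$ankle - foot$com, r_ankle_f)
  # shank: reactions at ankle are equal and opposite
  r_knee_f <- shank$m * shank$acc - weight(shank) + r_ankle_f
  m_knee_z <- shank$inertia * shank$alpha + m_ankle_z -
    cross2(leg_markers$ankle - shank$com, -r_ankle_f) -
    cross2(leg_markers$knee - shank$com, r_knee_f)
  # thigh
  r_hip_f <- thigh$m * thigh$acc - weight(thigh) + r_knee_f
  m_hip_z <- thigh$inertia * thigh$alpha + m_knee_z -
    cross2(leg_markers$knee - thigh$com, -r_knee_f) -
    cross2(leg_markers$hip - thigh$com, r_hip_f)

  out <- data.frame(
    time = ja$time,
    m_ankle = joint_sign("ankle") * m_ankle_z,
    m_knee = joint_sign("knee") * m_knee_z,
    m_hip = joint_sign("hip") * m_hip_z,
    omega_ankle = ja$omega_ankle, omega_knee = ja$omega_knee,
    omega_hip = ja$omega_hip)
  for (j in c("ankle", "knee", "hip"))
    out[[paste0("p_", j)]] <- out[[paste0("m_", j)]] * out[[paste0("omega_", j)]]
  out
}

# unwrap a phase angle series so differentiation is continuous
unwrap_angle <- function(theta) {
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta - 2 * pi * jumps
}
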