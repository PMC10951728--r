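# Decomposition of overall joint kinetics into exoskeleton and
# muscle-tendon-unit (MTU) contributions. The exoskeleton force is treated
# as purely axial between its hip and foot attachments (low-friction pin
# joints), its line of action defined by the attachment markers; the
# contribution to each joint is the moment of that force about the joint
# centre, treated independently per joint, and the MTU contribution is the
# residual: M_mtu = M_overall - M_exo and P_mtu = P_overall - P_exo.

#' Exoskeleton attachment geometry
#'
#' @param hip_attach,foot_attach `n x 2` sagittal-plane trajectories (m) of
#'   the exoskeleton hip and foot attachment markers.
#' @param rest_length Spring rest length (m). `NULL` estimates it as the
#'   maximum attachment distance observed (the extended, unloaded pose).
#' @return Object of class `exo_geometry` with the per-sample attachment
#'   distance and line of action.
#' @export
exo_geometry <- function(hip_attach, foot_attach, rest_length = NULL) {
  stopifnot(is.matrix(hip_attach), is.matrix(foot_attach),
            ncol(hip_attach) == 2L, ncol(foot_attach) == 2L,
            nrow(hip_attach) == nrow(foot_attach))
  dist <- sqrt(rowSums((hip_attach - foot_attach)^2))
  if (any(dist < 1e-9))
    stop("degenerate exoskeleton geometry: coincident attachment markers.")
  if (is.null(rest_length)) rest_length <- max(dist)
  if (rest_length <= 0) stop("`rest_length` must be positive.")
  u <- (foot_attach - hip_attach) / dist
  structure(list(hip = hip_attach, foot = foot_attach, dist = dist,
                 u = u, rest_length = rest_length),
            class = "exo_geometry")
}

#' Instantaneous spring displacement from attachment geometry
#'
#' `d(t) = max(0, rest_length - |hip_attach - foot_attach|)`: the spring
#' plates only compress, so the displacement is clamped at zero when the
#' attachment distance exceeds the rest length.
#'
#' @param geometry An [exo_geometry()].
#' @return Displacement series (m).
#' @export
spring_displacement <- function(geometry) {
  stopifnot(inherits(geometry, "exo_geometry"))
  pmax(0, geometry$rest_length - geometry$dist)
}

# loading/unloading branch per sample, keyed on the sign of the
# displacement rate; zero-rate samples hold the previous branch
displacement_branches <- function(disp) {
  n <- length(disp)
  if (n < 2L) return(rep("loading", n))
  rate <- central_diff(disp, 1)
  s <- sign(rate)
  for (i in seq_len(n)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 1
  ifelse(s > 0, "loading", "unloading")
}

#' Exoskeleton moment arm about a joint centre
#'
#' Unsigned perpendicular distance from the joint centre to the
#' exoskeleton's line of action, plus a side indicator (`+1` / `-1`, the
#' sign of the planar cross product of the joint-to-line geometry with the
#' force direction) that fixes the moment sign.
#'
#' @param joint_centre `n x 2` joint-centre trajectory (m), or a length-2
#'   point.
#' @param geometry An [exo_geometry()].
#' @return Data frame with columns `arm_m` and `side`.
#' @export
moment_arm <- function(joint_centre, geometry) {
  stopifnot(inherits(geometry, "exo_geometry"))
  if (is.null(dim(joint_centre)))
    joint_centre <- matrix(joint_centre, nrow = nrow(geometry$u),
                           ncol = 2, byrow = TRUE)
  u <- geometry$u
  r <- joint_centre - geometry$hip
  cr <- r[, 1] * u[, 2] - r[, 2] * u[, 1]
  data.frame(arm_m = abs(cr), side = ifelse(cr >= 0, 1, -1))
}

#' Exoskeleton contribution to joint moments and powers
#'
#' The spring force acts along the line of action; its magnitude comes from
#' the spring law evaluated at the instantaneous displacement, on the
#' loading or unloading branch according to the sign of the displacement
#' rate. The moment about each joint is the planar cross product of the
#' joint-to-attachment vector with the force on the distal attachment,
#' mapped to the extensor/plantarflexor-positive convention; powers multiply
#' by the joint angular velocity. Aerial-phase moments are zero because the
#' clamped spring displacement (and hence force) vanishes whenever the
#' attachment distance reaches the rest length, which the exoskeleton's
#' sizing ties to the instant of ground contact.
#'
#' @param geometry An [exo_geometry()].
#' @param profile The per-leg [spring_profile()].
#' @param joints Named list (`ankle`, `knee`, `hip`) of `n x 2`
#'   joint-centre trajectories (m).
#' @param omega Data frame with `omega_ankle`, `omega_knee`, `omega_hip`
#'   (rad/s) on the same grid.
#' @return Data frame with `disp_m`, `force_n`, `branch`, and per joint
#'   `m_exo_<joint>` (N m), `p_exo_<joint>` (W), `arm_<joint>` (m).
#' @export
exo_joint_kinetics <- function(geometry, profile, joints, omega) {
  stopifnot(inherits(geometry, "exo_geometry"),
            inherits(profile, "spring_profile"))
  disp <- spring_displacement(geometry)
  branch <- displacement_branches(disp)
  force <- spring_force(profile, disp, branch)
  u <- geometry$u
  out <- data.frame(disp_m = disp, force_n = force, branch = branch)
  for (j in c("ankle", "knee", "hip")) {
    r <- geometry$foot - joints[[j]]
    mz <- (r[, 1] * u[, 2] - r[, 2] * u[, 1]) * force
    m_conv <- joint_sign(j) * mz
    out[[paste0("arm_", j)]] <- moment_arm(joints[[j]], geometry)$arm_m
    out[[paste0("m_exo_", j)]] <- m_conv
    out[[paste0("p_exo_", j)]] <- m_conv * omega[[paste0("omega_", j)]]
  }
  out
}

#' Decompose overall joint kinetics into exoskeleton and MTU contributions
#'
#' Per-sample subtraction: `M_mtu = M_overall - M_exo` and
#' `P_mtu = P_overall - P_exo` for each joint, so the reconstruction
#' `MTU + exo = overall` holds to machine precision.
#'
#' @param overall Output of [inverse_dynamics()].
#' @param exo Output of [exo_joint_kinetics()], or `NULL` for a
#'   no-exoskeleton condition (all exo terms zero).
#' @return Data frame of class `kinetics_decomposition` with columns
#'   `m_overall_*`, `m_exo_*`, `m_mtu_*`, `p_overall_*`, `p_exo_*`,
#'   `p_mtu_*` for each joint, plus `time`.
#' @export
decompose <- function(overall, exo = NULL) {
  n <- nrow(overall)
  if (!is.null(exo) && nrow(exo) != n)
    stop("overall and exoskeleton series are misaligned (different lengths).")
  out <- data.frame(time = overall$time)
  for (j in c("ankle", "knee", "hip")) {
    mo <- overall[[paste0("m_", j)]]
    po <- overall[[paste0("p_", j)]]
    me <- if (is.null(exo)) numeric(n) else exo[[paste0("m_exo_", j)]]
    pe <- if (is.null(exo)) numeric(n) else exo[[paste0("p_exo_", j)]]
    out[[paste0("m_overall_", j)]] <- mo
    out[[paste0("m_exo_", j)]] <- me
    out[[paste0("m_mtu_", j)]] <- mo - me
    out[[paste0("p_overall_", j)]] <- po
    out[[paste0("p_exo_", j)]] <- pe
    out[[paste0("p_mtu_", j)]] <- po - pe
    out[[paste0("omega_", j)]] <- overall[[paste0("omega_", j)]]
  }
  class(out) <- c("kinetics_decomposition", "data.frame")
  out
}

#' Consistency check: summed exoskeleton joint power vs spring power
#'
#' Verifies that the exoskeleton's average positive power summed across the
#' ankle, knee and hip does not exceed the average positive power the spring
#' itself delivers (force times the rate of spring length change, positive
#' part), cycle-averaged. For exact attachment geometry the two agree
#' identically; a small relative tolerance absorbs discretization and
#' filtering. Estimated moment arms that are too large (for instance,
#' doubled) inflate the joint-power sum well beyond the spring's delivery
#' and fail the check.
#'
#' @param exo_kinetics Output of [exo_joint_kinetics()] (per leg), or
#'   `NULL` for a no-exoskeleton trial.
#' @param geometry The matching [exo_geometry()], or `NULL`.
#' @param cycles A `hop_cycles` object on the same grid.
#' @param rate Sampling rate (Hz).
#' @param tol_rel Relative tolerance, default 0.02.
#' @return List with `joint_power_w`, `spring_power_w`, `ratio`, `pass`.
#' @export
exo_power_check <- function(exo_kinetics, geometry, cycles, rate,
                            tol_rel = 0.02) {
  if (is.null(exo_kinetics) || is.null(geometry))
    return(list(joint_power_w = 0, spring_power_w = 0, ratio = NA_real_,
                pass = TRUE))
  cyc <- cycles$cycles
  if (nrow(cyc) < 1L) stop("need at least one complete hop cycle.")
  t <- (seq_along(geometry$dist) - 1L) / rate
  # power delivered by the spring to the body: F times the rate of spring
  # length change (positive while re-extending)
  p_spring <- exo_kinetics$force_n * central_diff(geometry$dist, 1 / rate)
  per_cycle <- function(series) {
    mean(mapply(function(s, e) average_positive_power(series[s:e], t[s:e]),
                cyc$start, cyc$end))
  }
  joint_sum <- sum(vapply(c("ankle", "knee", "hip"), function(j)
    per_cycle(exo_kinetics[[paste0("p_exo_", j)]]), numeric(1)))
  spring_pos <- per_cycle(p_spring)
  ratio <- if (spring_pos > 0) joint_sum / spring_pos else NA_real_
  list(joint_power_w = joint_sum, spring_power_w = spring_pos,
       ratio = ratio,
       pass = joint_sum <= spring_pos * (1 + tol_rel) + 1e-9)
}
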