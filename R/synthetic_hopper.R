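# Synthetic hopping trial generator. Produces dynamically consistent
# marker + ground-reaction-force data for stationary bilateral hopping with
# an optional parallel-elastic full-leg exoskeleton, together with analytic
# ground truth (spring displacement, exoskeleton force, moment arms and
# joint moments) for parameter-recovery testing.
#
# Construction: the summed vertical GRF during contact is a sin^gamma pulse
# whose peak is set by impulse balance (mean force over a full cycle equals
# body weight); the centre of mass follows from twice-integrating net force
# on a point mass; the planar ankle-knee-hip chain is posed each sample so
# the hip tracks the centre of mass, with the required leg shortening
# distributed over the joints by configurable angular-excursion weights.
# Contact is on the forefoot: the toe is the fixed contact point and the
# centre of pressure.

GRAV <- 9.81

#' Parameters for a synthetic hopping trial
#'
#' Defaults emulate stationary bilateral hopping at 2.4 Hz with a 0.26 s
#' contact time by a 66 kg hopper: with the default ground-reaction pulse
#' shape exponent (2.7) the peak summed vertical GRF is about 2.3 kN and the
#' contact-phase centre-of-mass displacement about 11 cm.
#'
#' @param mass Body mass (kg).
#' @param leg_length Greater trochanter to floor (m); informational.
#' @param segment_lengths Named lengths (m) of `foot` (toe to ankle),
#'   `shank`, `thigh`.
#' @param hop_frequency Hop frequency (Hz), default 2.4.
#' @param contact_time Ground contact time per hop (s), default 0.26; must
#'   be shorter than the hop period.
#' @param n_hops Number of hop cycles generated, default 20.
#' @param grf_shape_exponent Exponent `gamma >= 1` of the `sin^gamma`
#'   contact pulse; larger values give narrower, taller pulses.
#' @param joint_amplitude_weights Named fractions (`ankle`, `knee`, `hip`,
#'   summing to 1) of the total joint angular flexion excursion allotted to
#'   each joint.
#' @param marker_noise_sd Isotropic Gaussian marker noise s.d. (m), default 0.
#' @param marker_rate Marker sampling rate (Hz), default 200.
#' @param grf_rate Force sampling rate (Hz), default 1000; must be an
#'   integer multiple of `marker_rate`.
#' @param base_tilts_deg Segment tilts from vertical (degrees,
#'   `foot`, `shank`, `thigh`) in the extended, on-toes pose at contact
#'   onset.
#' @param seed Integer seed; the trial is reproducible for a fixed seed.
#' @param exo `NULL` for no-exoskeleton (NH) trials, else an [exo_spec()].
#' @return An object of class `hopper_params`.
#' @export
hopper_params <- function(mass = 66, leg_length = 0.90,
                          segment_lengths = c(foot = 0.10, shank = 0.41,
                                              thigh = 0.42),
                          hop_frequency = 2.4, contact_time = 0.26,
                          n_hops = 20L, grf_shape_exponent = 2.7,
                          joint_amplitude_weights = c(ankle = 0.4,
                                                      knee = 0.4, hip = 0.2),
                          marker_noise_sd = 0, marker_rate = 200,
                          grf_rate = 1000,
                          base_tilts_deg = c(foot = 45, shank = 12, thigh = 12),
                          seed = 1L, exo = NULL) {
  stopifnot(mass > 0, leg_length > 0, hop_frequency > 0, n_hops >= 1)
  if (contact_time <= 0 || contact_time >= 1 / hop_frequency)
    stop("`contact_time` must be positive and shorter than the hop period 1/hop_frequency.")
  req <- c("foot", "shank", "thigh")
  if (!all(req %in% names(segment_lengths)) || any(segment_lengths <= 0))
    stop("`segment_lengths` must be positive and named foot/shank/thigh.")
  w <- joint_amplitude_weights
  if (!all(c("ankle", "knee", "hip") %in% names(w)) ||
      abs(sum(w) - 1) > 1e-8 || any(w < 0))
    stop("`joint_amplitude_weights` must be named ankle/knee/hip, non-negative, summing to 1.")
  # segment-tilt rates implied by the weights must be non-negative for the
  # chain to fold monotonically toward the ground
  cf <- w[["ankle"]] - w[["knee"]] + w[["hip"]]
  cs <- w[["knee"]] - w[["hip"]]
  if (cf < 0 || cs < 0)
    stop("`joint_amplitude_weights` infeasible: need knee >= hip and ankle + hip >= knee.")
  if (grf_shape_exponent < 1) stop("`grf_shape_exponent` must be >= 1.")
  if (grf_rate %% marker_rate != 0)
    stop("`grf_rate` must be an integer multiple of `marker_rate`.")
  if (marker_noise_sd < 0) stop("`marker_noise_sd` must be >= 0.")
  if (!is.null(exo) && !inherits(exo, "exo_spec"))
    stop("`exo` must be NULL or an exo_spec().")
  structure(list(mass = mass, leg_length = leg_length,
                 segment_lengths = segment_lengths,
                 hop_frequency = hop_frequency, contact_time = contact_time,
                 n_hops = as.integer(n_hops),
                 grf_shape_exponent = grf_shape_exponent,
                 joint_amplitude_weights = w,
                 marker_noise_sd = marker_noise_sd,
                 marker_rate = marker_rate, grf_rate = grf_rate,
                 base_tilts_deg = base_tilts_deg,
                 seed = as.integer(seed), exo = exo),
            class = "hopper_params")
}

#' Exoskeleton specification for a synthetic trial
#'
#' @param profile Per-leg [spring_profile()] (one exoskeleton 'leg').
#' @param rest_length Spring rest length (m); `NULL` sizes the exoskeleton
#'   to the extended on-toes pose so compression begins at the instant of
#'   ground contact.
#' @param hip_offset,foot_offset Sagittal-plane offsets (m, `c(x, y)`) of
#'   the exoskeleton attachment markers from the hip joint centre and toe
#'   marker. Defaults are zero: attachments at the hip centre and
#'   metatarsal contact point.
#' @param leg_mass Mass of one exoskeleton 'leg' (kg), default 1.
#' @return An object of class `exo_spec`.
#' @export
exo_spec <- function(profile, rest_length = NULL,
                     hip_offset = c(0, 0), foot_offset = c(0, 0),
                     leg_mass = 1) {
  stopifnot(inherits(profile, "spring_profile"),
            length(hip_offset) == 2L, length(foot_offset) == 2L,
            leg_mass >= 0)
  if (!is.null(rest_length) && rest_length <= 0)
    stop("`rest_length` must be positive.")
  structure(list(profile = profile, rest_length = rest_length,
                 hip_offset = as.numeric(hip_offset),
                 foot_offset = as.numeric(foot_offset),
                 leg_mass = leg_mass),
            class = "exo_spec")
}

#' Build an exoskeleton spec for a condition from the mass prescription
#'
#' Convenience wrapper: prescribes the total (both-legs) stiffness from body
#' mass, splits it over the two exoskeleton legs, and builds the per-leg
#' spring profile of the requested stiffness-profile kind.
#'
#' @param condition One of `"DG"`, `"LN"`, `"PG"`.
#' @param mass Body mass (kg).
#' @param model A [prescription_model()].
#' @param reference_displacement Reference compression (m), default 0.10.
#' @param hysteresis_fraction Passed to [spring_profile()].
#' @param ... Passed to [exo_spec()].
#' @return An `exo_spec`.
#' @export
prescribed_exo <- function(condition = c("DG", "LN", "PG"), mass,
                           model = prescription_model(),
                           reference_displacement = 0.10,
                           hysteresis_fraction = 0, ...) {
  condition <- match.arg(condition)
  kind <- switch(condition, DG = "degressive", LN = "linear",
                 PG = "progressive")
  k_total <- prescribe_stiffness(mass, model)       # kN/m, both legs
  f_ref <- k_total / 2 * 1000 * reference_displacement
  exo_spec(spring_profile(kind, reference_force = f_ref,
                          reference_displacement = reference_displacement,
                          hysteresis_fraction = hysteresis_fraction), ...)
}

# mean of sin^gamma(pi*u) on [0, 1]
pulse_shape_mean <- function(gamma) {
  stats::integrate(function(u) sin(pi * u)^gamma, 0, 1,
                   rel.tol = 1e-12)$value
}

# peak of the summed contact pulse from impulse balance over one cycle
pulse_peak_force <- function(mass, hop_frequency, contact_time, gamma) {
  period <- 1 / hop_frequency
  mass * GRAV * (period / contact_time) / pulse_shape_mean(gamma)
}

# one-cycle centre-of-mass template: returns interpolating functions of the
# cycle phase (0 = contact onset) for vertical displacement relative to the
# contact-onset height
com_template <- function(mass, hop_frequency, contact_time, gamma,
                         dt = 2e-5) {
  period <- 1 / hop_frequency
  t_air <- period - contact_time
  fpk <- pulse_peak_force(mass, hop_frequency, contact_time, gamma)
  tg <- seq(0, contact_time, by = dt)
  if (tg[length(tg)] < contact_time) tg <- c(tg, contact_time)
  acc <- fpk * sin(pi * tg / contact_time)^gamma / mass - GRAV
  v0 <- -GRAV * t_air / 2
  v <- v0 + pracma::cumtrapz(tg, acc)[, 1]
  y <- pracma::cumtrapz(tg, v)[, 1]
  y_tc <- y[length(y)]
  v_tc <- v[length(v)]
  list(
    y = function(tphase) {
      out <- numeric(length(tphase))
      inc <- tphase < contact_time
      out[inc] <- stats::approx(tg, y, xout = tphase[inc])$y
      ta <- tphase[!inc] - contact_time
      out[!inc] <- y_tc + v_tc * ta - GRAV * ta^2 / 2
      out
    },
    fsum = function(tphase) {
      ifelse(tphase < contact_time,
             fpk * sin(pi * pmin(tphase, contact_time) / contact_time)^gamma,
             0)
    },
    peak_force = fpk, takeoff_velocity = v_tc, t_air = t_air)
}

# pose of the planar chain for a flexion parameter phi (radians >= 0).
# Tilts from vertical: tau = tau0 + c * phi with c derived from the joint
# amplitude weights. Returns joint positions for toe at the origin.
chain_pose <- function(phi, seg, tau0, coefs) {
  tf <- tau0[1] + coefs[1] * phi
  ts <- tau0[2] + coefs[2] * phi
  tt <- tau0[3] + coefs[3] * phi
  ankle <- cbind(-seg[1] * sin(tf), seg[1] * cos(tf))
  knee <- ankle + cbind(seg[2] * sin(ts), seg[2] * cos(ts))
  hip <- knee + cbind(-seg[3] * sin(tt), seg[3] * cos(tt))
  list(ankle = ankle, knee = knee, hip = hip,
       tilts = cbind(foot = tf, shank = ts, thigh = tt))
}

hip_height <- function(phi, seg, tau0, coefs) {
  seg[1] * cos(tau0[1] + coefs[1] * phi) +
    seg[2] * cos(tau0[2] + coefs[2] * phi) +
    seg[3] * cos(tau0[3] + coefs[3] * phi)
}

#' Simulate a synthetic hopping trial
#'
#' @param params A [hopper_params()].
#' @return A list with elements `trial` (class `hop_trial`: markers at the
#'   marker rate, per-leg GRFs at the force rate, participant metadata,
#'   condition, and the exoskeleton spec if any) and `truth` (class
#'   `ground_truth`: per-sample spring displacement, exoskeleton force,
#'   line of action, per-joint moment arms and exoskeleton moments under the
#'   extensor/plantarflexor-positive convention, joint angles, and the
#'   centre-of-mass trajectory). Legs are mirrored; ground truth applies to
#'   either leg.
#' @export
simulate_trial <- function(params) {
  stopifnot(inherits(params, "hopper_params"))
  set.seed(params$seed)
  p <- params
  period <- 1 / p$hop_frequency
  t_air <- period - p$contact_time
  seg <- unname(p$segment_lengths[c("foot", "shank", "thigh")])
  tau0 <- unname(p$base_tilts_deg[c("foot", "shank", "thigh")]) * pi / 180
  w <- p$joint_amplitude_weights
  coefs <- c(w[["ankle"]] - w[["knee"]] + w[["hip"]],
             w[["knee"]] - w[["hip"]],
             w[["hip"]])
  tmpl <- com_template(p$mass, p$hop_frequency, p$contact_time,
                       p$grf_shape_exponent)
  h0 <- hip_height(0, seg, tau0, coefs)
  # flexion cap: keep every tilt below 89 degrees so folding stays monotone
  cap <- (89 * pi / 180 - tau0) / ifelse(coefs > 0, coefs, Inf)
  phi_max <- min(cap[coefs > 0], pi)

  dur <- p$n_hops * period
  n_m <- as.integer(round(dur * p$marker_rate))
  t_m <- (seq_len(n_m) - 1L) / p$marker_rate
  # trial starts mid-aerial so the first contact onset is interior
  tphase <- (t_m - t_air / 2) %% period
  contact <- tphase < p$contact_time
  y <- tmpl$y(tphase)

  drop_req <- pmax(0, -y)
  drop_req[!contact] <- 0
  max_drop <- h0 - hip_height(phi_max, seg, tau0, coefs)
  if (max(drop_req) > max_drop)
    stop(sprintf(
      "infeasible geometry: required leg shortening %.3f m exceeds the %.3f m the chain can fold.",
      max(drop_req), max_drop))
  phi <- numeric(n_m)
  phi[contact] <- vapply(drop_req[contact], function(dr) {
    if (dr <= 0) return(0)
    stats::uniroot(function(q) (h0 - hip_height(q, seg, tau0, coefs)) - dr,
                   c(0, phi_max), tol = 1e-13)$root
  }, numeric(1))
  # aerial phase: the leg extends smoothly beyond the base pose (push-off
  # through the toes) and flexes back before landing; the quadratic dip is
  # slope-matched to the contact-phase flexion rate at both events so the
  # marker trajectories have continuous velocities across transitions
  hp0 <- -(seg[1] * coefs[1] * sin(tau0[1]) +
             seg[2] * coefs[2] * sin(tau0[2]) +
             seg[3] * coefs[3] * sin(tau0[3]))
  v_td <- GRAV * t_air / 2
  s_phi <- v_td / abs(hp0)
  tau_air <- tphase - p$contact_time
  phi[!contact] <- -s_phi * tau_air[!contact] *
    (t_air - tau_air[!contact]) / t_air
  tilt_floor <- min((tau0 / ifelse(coefs > 0, coefs, Inf))[coefs > 0])
  if (s_phi * t_air / 4 > tilt_floor)
    stop("infeasible geometry: the aerial extension dip would drive a segment tilt through vertical; increase base_tilts_deg or hop faster.")

  pose <- chain_pose(phi, seg, tau0, coefs)
  h_phi <- hip_height(phi, seg, tau0, coefs)
  # toe height: zero during contact (by construction of phi), ballistic
  # residual after the pose extension in the air
  lift <- y - (h_phi - h0)
  toe <- cbind(0, lift)
  heel_len <- 0.06
  tf <- pose$tilts[, "foot"]
  markers <- list(
    toe = toe,
    heel = toe + pose$ankle - heel_len * cbind(cos(tf), sin(tf)),
    ankle = toe + pose$ankle,
    knee = toe + pose$knee,
    hip = toe + pose$hip)

  truth <- data.frame(
    time = t_m, tphase = tphase, contact = contact,
    com_y = h0 + y,
    angle_ankle = 180 - (pose$tilts[, "shank"] + pose$tilts[, "foot"]) * 180 / pi,
    angle_knee = 180 - (pose$tilts[, "thigh"] + pose$tilts[, "shank"]) * 180 / pi,
    angle_hip = 180 - pose$tilts[, "thigh"] * 180 / pi)

  exo <- p$exo
  if (!is.null(exo)) {
    hip_att <- markers$hip + rep(exo$hip_offset, each = n_m)
    foot_att <- markers$toe + rep(exo$foot_offset, each = n_m)
    markers$exo_hip <- hip_att
    markers$exo_foot <- foot_att
    dist <- sqrt(rowSums((hip_att - foot_att)^2))
    ext_pose <- chain_pose(0, seg, tau0, coefs)
    l0 <- if (!is.null(exo$rest_length)) exo$rest_length else
      sqrt(sum((ext_pose$hip[1, ] + exo$hip_offset -
                  c(0, 0) - exo$foot_offset)^2))
    disp <- pmax(0, l0 - dist)
    branch <- displacement_branches(disp)
    force <- spring_force(exo$profile, disp, branch)
    u <- (foot_att - hip_att) / dist
    jm <- lapply(c(ankle = "ankle", knee = "knee", hip = "hip"), function(j)
      exo_moment_about(markers[[j]], hip_att, foot_att, u, force, j))
    truth$disp_m <- disp
    truth$force_n <- force
    truth$branch <- branch
    truth$ux <- u[, 1]; truth$uy <- u[, 2]
    truth$arm_ankle <- jm$ankle$arm
    truth$arm_knee <- jm$knee$arm
    truth$arm_hip <- jm$hip$arm
    truth$m_exo_ankle <- jm$ankle$moment
    truth$m_exo_knee <- jm$knee$moment
    truth$m_exo_hip <- jm$hip$moment
    truth$rest_length <- l0
  }

  add_noise <- function(m) {
    if (p$marker_noise_sd <= 0) return(m)
    m + matrix(stats::rnorm(length(m), sd = p$marker_noise_sd), ncol = 2)
  }
  legs <- list(L = lapply(markers, add_noise),
               R = lapply(markers, add_noise))

  n_g <- as.integer(round(dur * p$grf_rate))
  t_g <- (seq_len(n_g) - 1L) / p$grf_rate
  tphase_g <- (t_g - t_air / 2) %% period
  fsum <- tmpl$fsum(tphase_g)
  grf_leg <- data.frame(time = t_g, fz = fsum / 2, fx = 0,
                        copx = 0)
  condition <- if (is.null(exo)) "NH" else
    switch(exo$profile$kind, degressive = "DG", linear = "LN",
           progressive = "PG", tabulated = "EXO")

  trial <- structure(
    list(participant = list(mass = p$mass, leg_length = p$leg_length),
         condition = condition,
         markers = list(time = t_m, rate = p$marker_rate, L = legs$L,
                        R = legs$R),
         grf = list(rate = p$grf_rate, L = grf_leg, R = grf_leg),
         exo = if (is.null(exo)) NULL else
           list(profile = exo$profile,
                rest_length = truth$rest_length[1],
                leg_mass = exo$leg_mass),
         params = p),
    class = "hop_trial")
  list(trial = trial,
       truth = structure(truth, class = c("ground_truth", "data.frame")))
}

#' @export
print.hop_trial <- function(x, ...) {
  cat(sprintf(
    "<hop_trial> condition %s, %.0f kg, %d marker samples @ %g Hz, %d GRF samples @ %g Hz\n",
    x$condition, x$participant$mass, length(x$markers$time),
    x$markers$rate, nrow(x$grf$L), x$grf$rate))
  invisible(x)
}

# signed exoskeleton moment about a joint centre, extensor/plantarflexor
# positive, plus the unsigned perpendicular moment arm. The force on the
# distal attachment acts along the line away from the hip attachment.
exo_moment_about <- function(joint, hip_att, foot_att, u, force, joint_name) {
  r <- foot_att - joint
  mz <- (r[, 1] * u[, 2] - r[, 2] * u[, 1]) * force
  arm_vec <- joint - hip_att
  arm <- abs(arm_vec[, 1] * u[, 2] - arm_vec[, 2] * u[, 1])
  list(moment = joint_sign(joint_name) * mz, arm = arm)
}

# maps the planar z-moment on the distal segment to the
# extensor/plantarflexor-positive convention: alternate joints of the
# zig-zag chain flex in alternating rotational senses
joint_sign <- function(joint) {
  switch(joint, ankle = -1, knee = 1, hip = -1,
         stop(sprintf("unknown joint '%s'", joint)))
}

#' Simulate a cohort of synthetic trials (or outcome tables)
#'
#' With `outcomes_only = FALSE`, draws per-participant anthropometry around
#' the template, builds prescribed exoskeletons per condition, and simulates
#' every participant x condition trial. With `outcomes_only = TRUE`, skips
#' trial generation and returns a long-format outcome table drawn from an
#' additive participant-random-effect model, for exercising the
#' condition-level statistics at scale: `value = baseline + b_i + effect_c +
#' noise` with `b_i ~ N(0, between_sd)` and `noise ~ N(0, within_sd)`.
#'
#' @param n_participants Number of participants (`>= 2`).
#' @param conditions Character vector of conditions among NH/DG/LN/PG.
#' @param params_template A [hopper_params()] used as the cohort template.
#' @param seed Integer seed.
#' @param effects Named numeric vector of per-condition offsets (same units
#'   as the outcome for `outcomes_only = TRUE`; seconds of contact time
#'   otherwise). Default zero.
#' @param outcomes_only If `TRUE`, return an outcome data frame instead of
#'   simulated trials.
#' @param baseline,between_sd,within_sd Outcome model parameters
#'   (`outcomes_only = TRUE`).
#' @param mass_sd,leg_sd Between-participant s.d. of mass (kg) and leg
#'   length (m).
#' @return Either a data frame (`participant`, `condition`, `value`) or a
#'   list of `simulate_trial()` results with a `manifest` attribute.
#' @export
emit_cohort <- function(n_participants, conditions = c("NH", "DG", "LN", "PG"),
                        params_template = hopper_params(), seed = 1L,
                        effects = NULL, outcomes_only = FALSE,
                        baseline = 100, between_sd = 10, within_sd = 5,
                        mass_sd = 5.7, leg_sd = 0.04) {
  if (n_participants < 2) stop("`n_participants` must be >= 2.")
  if (length(conditions) == 0) stop("`conditions` must be non-empty.")
  if (is.null(effects)) effects <- stats::setNames(rep(0, length(conditions)),
                                                   conditions)
  set.seed(seed)
  if (outcomes_only) {
    b <- stats::rnorm(n_participants, 0, between_sd)
    out <- expand.grid(participant = seq_len(n_participants),
                       condition = conditions, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    out$value <- baseline + b[out$participant] +
      effects[out$condition] +
      stats::rnorm(nrow(out), 0, within_sd)
    return(out)
  }
  tpl <- params_template
  masses <- pmax(40, stats::rnorm(n_participants, tpl$mass, mass_sd))
  legs <- pmax(0.7, stats::rnorm(n_participants, tpl$leg_length, leg_sd))
  trial_seeds <- sample.int(.Machine$integer.max - 1L,
                            n_participants * length(conditions))
  res <- list()
  manifest <- data.frame()
  k <- 0L
  for (i in seq_len(n_participants)) {
    scale <- legs[i] / tpl$leg_length
    for (cond in conditions) {
      k <- k + 1L
      exo <- if (cond == "NH") NULL else prescribed_exo(cond, masses[i])
      prm <- hopper_params(
        mass = masses[i], leg_length = legs[i],
        segment_lengths = tpl$segment_lengths * scale,
        hop_frequency = tpl$hop_frequency,
        contact_time = tpl$contact_time + unname(effects[cond]),
        n_hops = tpl$n_hops, grf_shape_exponent = tpl$grf_shape_exponent,
        joint_amplitude_weights = tpl$joint_amplitude_weights,
        marker_noise_sd = tpl$marker_noise_sd,
        marker_rate = tpl$marker_rate, grf_rate = tpl$grf_rate,
        base_tilts_deg = tpl$base_tilts_deg,
        seed = trial_seeds[k], exo = exo)
      res[[k]] <- simulate_trial(prm)
      manifest <- rbind(manifest, data.frame(
        participant = i, condition = cond, mass_kg = masses[i],
        leg_length_m = legs[i], seed = trial_seeds[k]))
    }
  }
  attr(res, "manifest") <- manifest
  res
}
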