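# End-to-end analysis of a hopping trial: filtering, contact detection,
# joint kinematics, inverse dynamics, exoskeleton/MTU decomposition and
# power summaries, on a common 200 Hz analysis grid (the marker clock)
# after decimating the force data.

#' Analysis configuration
#'
#' Collects every tunable numerical choice of the pipeline.
#'
#' @param cutoff_hz Low-pass cutoff for markers and GRFs (Hz), default 20.
#' @param filter_order Effective Butterworth order (even), default 4
#'   (applied as two zero-phase passes of order 2).
#' @param contact_threshold_n Vertical-GRF contact threshold (N), default 20.
#' @param debounce_s Contact-event debounce window (s), default 0.010.
#' @param n_points Points for time-normalized cycle curves, default 101.
#' @param n_cycles Trailing complete cycles analysed, default 20.
#' @param anthropometric_table Segment-parameter table id, default
#'   `"winter"`.
#' @param include_exo_mass Carry the exoskeleton leg mass in inverse
#'   dynamics, default `TRUE`.
#' @param exo_mass_split Attachment split of the exoskeleton leg mass,
#'   default 50% foot / 50% hip.
#' @param exo_method How the exoskeleton contribution is estimated:
#'   `"line_of_action"` (default) from the attachment geometry and spring
#'   law, or `"grf_subtraction"`, a comparison mode that subtracts the
#'   axial exoskeleton force from the measured GRF, re-runs inverse
#'   dynamics to obtain the MTU moments directly, and derives the
#'   exoskeleton contribution as the residual.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cutoff_hz = 20, filter_order = 4,
                            contact_threshold_n = 20, debounce_s = 0.010,
                            n_points = 101L, n_cycles = 20L,
                            anthropometric_table = "winter",
                            include_exo_mass = TRUE,
                            exo_mass_split = c(foot = 0.5, hip = 0.5),
                            exo_method = c("line_of_action",
                                           "grf_subtraction")) {
  structure(list(cutoff_hz = cutoff_hz, filter_order = filter_order,
                 contact_threshold_n = contact_threshold_n,
                 debounce_s = debounce_s, n_points = as.integer(n_points),
                 n_cycles = as.integer(n_cycles),
                 anthropometric_table = anthropometric_table,
                 include_exo_mass = include_exo_mass,
                 exo_mass_split = exo_mass_split,
                 exo_method = match.arg(exo_method)),
            class = "analysis_config")
}

#' Analyse one hopping trial end to end
#'
#' Filters markers and forces (zero-phase Butterworth), detects contacts on
#' the summed vertical GRF at the force rate, decimates forces onto the
#' marker clock, computes sagittal joint angles and link-segment inverse
#' dynamics per leg (including the exoskeleton's weight when worn),
#' estimates the exoskeleton's contribution to each joint's moment and
#' power from the attachment geometry and spring law, derives MTU
#' contributions as the residual, and summarizes average positive power
#' and spatiotemporal measures.
#'
#' @param trial A `hop_trial` (from [simulate_trial()] or [read_trial()]).
#' @param config An [analysis_config()].
#' @return Object of class `hop_analysis`: list with elements `condition`,
#'   `angles` (leg-averaged), `angles_legs`, `kinetics` (per-leg and
#'   leg-summed [decompose()] outputs), `exo` (per-leg
#'   [exo_joint_kinetics()] outputs or `NULL`), `power`
#'   ([summarize_power()]), `spatiotemporal`, `rom`, `exo_check`, `cycles`
#'   (analysis grid), `cycles_grf`, `contact`, and `config`.
#' @export
analyze_trial <- function(trial, config = analysis_config()) {
  stopifnot(inherits(trial, "hop_trial"))
  cfg <- config
  mrate <- trial$markers$rate
  grate <- trial$grf$rate
  ratio <- grate / mrate
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("GRF rate must be an integer multiple of the marker rate.")
  ratio <- as.integer(round(ratio))
  n_m <- length(trial$markers$time)

  filt_markers <- lapply(trial$markers[c("L", "R")], function(leg)
    lapply(leg, lowpass, rate = mrate, cutoff_hz = cfg$cutoff_hz,
           order = cfg$filter_order))

  vgrf_raw <- trial$grf$L$fz + trial$grf$R$fz
  vgrf_f <- lowpass(vgrf_raw, grate, cfg$cutoff_hz, cfg$filter_order)
  cycles_g <- detect_contacts(vgrf_f, grate, cfg$contact_threshold_n,
                              cfg$debounce_s)
  if (nrow(cycles_g$cycles) < 1L)
    stop("no complete hop cycles detected in the trial.")
  cycles_m <- cycles_to_rate(cycles_g, mrate)

  dec_idx <- seq(1L, by = ratio, length.out = n_m)
  grf_m <- lapply(trial$grf[c("L", "R")], function(g) {
    data.frame(
      fz = lowpass(g$fz, grate, cfg$cutoff_hz, cfg$filter_order)[dec_idx],
      fx = lowpass(g$fx, grate, cfg$cutoff_hz, cfg$filter_order)[dec_idx],
      copx = g$copx[dec_idx])
  })
  contact_m <- vgrf_f[dec_idx] >= cfg$contact_threshold_n

  angles_legs <- lapply(filt_markers, joint_angles, rate = mrate)
  angles_avg <- angles_legs$L
  for (col in setdiff(names(angles_avg), "time"))
    angles_avg[[col]] <- (angles_legs$L[[col]] + angles_legs$R[[col]]) / 2

  mass <- trial$participant$mass
  exo_mass <- if (!is.null(trial$exo) && cfg$include_exo_mass)
    trial$exo$leg_mass else 0
  seg_len <- vapply(list(
    foot = c("ankle", "toe"), shank = c("knee", "ankle"),
    thigh = c("hip", "knee")), function(pr) {
      mean(sqrt(rowSums((filt_markers$L[[pr[1]]] -
                           filt_markers$L[[pr[2]]])^2)))
    }, numeric(1))
  params <- segment_parameters(mass, seg_len, cfg$anthropometric_table,
                               exo_leg_mass = exo_mass,
                               exo_mass_split = cfg$exo_mass_split)

  geoms <- exo_kin <- list(L = NULL, R = NULL)
  decomp <- list()
  for (leg in c("L", "R")) {
    overall <- inverse_dynamics(filt_markers[[leg]], grf_m[[leg]], params,
                                mrate, contact = contact_m)
    ek <- NULL
    if (!is.null(trial$exo)) {
      fm <- filt_markers[[leg]]
      if (is.null(fm$exo_hip) || is.null(fm$exo_foot))
        stop("exoskeleton condition but attachment markers exo_hip/exo_foot are missing.")
      geom <- exo_geometry(fm$exo_hip, fm$exo_foot,
                           rest_length = trial$exo$rest_length)
      ek <- exo_joint_kinetics(geom, trial$exo$profile,
                               joints = list(ankle = fm$ankle,
                                             knee = fm$knee, hip = fm$hip),
                               omega = angles_legs[[leg]])
      if (cfg$exo_method == "grf_subtraction") {
        # comparison mode: remove the axial exoskeleton force from the
        # measured GRF, redo inverse dynamics for the MTU moments, and
        # report the exoskeleton contribution as the residual
        grf_adj <- grf_m[[leg]]
        grf_adj$fx <- grf_adj$fx + ek$force_n * geom$u[, 1]
        grf_adj$fz <- grf_adj$fz + ek$force_n * geom$u[, 2]
        mtu_id <- inverse_dynamics(fm, grf_adj, params, mrate,
                                   contact = contact_m)
        for (j in c("ankle", "knee", "hip")) {
          ek[[paste0("m_exo_", j)]] <- overall[[paste0("m_", j)]] -
            mtu_id[[paste0("m_", j)]]
          ek[[paste0("p_exo_", j)]] <- ek[[paste0("m_exo_", j)]] *
            angles_legs[[leg]][[paste0("omega_", j)]]
        }
      }
      geoms[[leg]] <- geom
      exo_kin[[leg]] <- ek
    }
    decomp[[leg]] <- decompose(overall, ek)
  }
  dsum <- decomp$L
  for (col in grep("^(m|p)_", names(dsum), value = TRUE))
    dsum[[col]] <- decomp$L[[col]] + decomp$R[[col]]
  for (col in grep("^omega_", names(dsum), value = TRUE))
    dsum[[col]] <- (decomp$L[[col]] + decomp$R[[col]]) / 2
  decomp$sum <- dsum

  power <- summarize_power(decomp[c("L", "R")], cycles_m, mass,
                           n_cycles = cfg$n_cycles)
  spatio <- spatiotemporal(vgrf_f, cycles_g, mass)
  rom <- rom_and_peaks(angles_avg, cycles_m)
  check <- if (is.null(trial$exo)) {
    exo_power_check(NULL, NULL, cycles_m, mrate)
  } else {
    cl <- exo_power_check(exo_kin$L, geoms$L, cycles_m, mrate)
    cr <- exo_power_check(exo_kin$R, geoms$R, cycles_m, mrate)
    list(joint_power_w = cl$joint_power_w + cr$joint_power_w,
         spring_power_w = cl$spring_power_w + cr$spring_power_w,
         ratio = mean(c(cl$ratio, cr$ratio)),
         pass = cl$pass && cr$pass)
  }

  structure(list(condition = trial$condition, mass = mass,
                 angles = angles_avg, angles_legs = angles_legs,
                 kinetics = decomp, exo = exo_kin, geometry = geoms,
                 power = power, spatiotemporal = spatio, rom = rom,
                 exo_check = check, cycles = cycles_m,
                 cycles_grf = cycles_g, contact = contact_m,
                 config = cfg),
            class = "hop_analysis")
}

#' @export
print.hop_analysis <- function(x, ...) {
  cat(sprintf("<hop_analysis> condition %s, %d cycles, P_tot = %.1f W (%.2f W/kg)\n",
              x$condition, nrow(x$cycles$cycles),
              attr(x$power, "p_total_w"), attr(x$power, "p_total_w") / x$mass))
  st <- x$spatiotemporal
  cat(sprintf("  %.2f Hz, contact %.3f s, peak vGRF %.0f N, hop height %.1f cm\n",
              st$hop_frequency_hz, st$contact_time_s, st$peak_vgrf_n,
              st$hop_height_cm))
  if (!is.null(x$exo$L))
    cat(sprintf("  exo power check: joints %.1f W vs spring %.1f W (%s)\n",
                x$exo_check$joint_power_w, x$exo_check$spring_power_w,
                if (x$exo_check$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Time-normalized mean cycle curves
#'
#' Interpolates selected columns of the leg-summed kinetics onto a 0--100%
#' cycle grid and averages across the analysis cycles.
#'
#' @param analysis A `hop_analysis`.
#' @param columns Column names of `analysis$kinetics$sum`; default all
#'   moment and power columns.
#' @return Matrix `n_points x length(columns)` with attribute `percent`.
#' @export
cycle_curves <- function(analysis, columns = NULL) {
  stopifnot(inherits(analysis, "hop_analysis"))
  dsum <- analysis$kinetics$sum
  if (is.null(columns))
    columns <- grep("^(m|p)_", names(dsum), value = TRUE)
  cyc <- analysis$cycles$cycles
  np <- analysis$config$n_points
  acc <- matrix(0, np, length(columns), dimnames = list(NULL, columns))
  for (i in seq_len(nrow(cyc))) {
    idx <- cyc$start[i]:cyc$end[i]
    acc <- acc + time_normalize(as.matrix(dsum[idx, columns, drop = FALSE]),
                                n_points = np)
  }
  out <- acc / nrow(cyc)
  attr(out, "percent") <- seq(0, 100, length.out = np)
  out
}

#' Extract a scalar outcome from an analysis
#'
#' Supported metrics: `"pct_<contributor>_<joint>"` and
#' `"p_<contributor>_<joint>_wkg"` from the power summary
#' (contributor in overall/exo/mtu); `"m_mtu_<joint>_avg_nmkg"` (cycle-mean
#' MTU moment, both legs summed, per kg); `"rom_<joint>_deg"` and
#' `"peak_flexion_<joint>_deg"`; `"p_total_wkg"`; and the spatiotemporal
#' measures `"hop_frequency_hz"`, `"contact_time_s"`, `"peak_vgrf_n"`,
#' `"hop_height_cm"`.
#'
#' @param analysis A `hop_analysis`.
#' @param metric Metric name.
#' @return A scalar.
#' @export
extract_metric <- function(analysis, metric) {
  stopifnot(inherits(analysis, "hop_analysis"))
  pw <- analysis$power
  if (metric == "p_total_wkg")
    return(attr(pw, "p_total_w") / analysis$mass)
  m <- regmatches(metric,
                  regexec("^pct_(overall|exo|mtu)_(ankle|knee|hip)$", metric))[[1]]
  if (length(m) == 3L)
    return(pw$pct[pw$contributor == m[2] & pw$joint == m[3]])
  m <- regmatches(metric,
                  regexec("^p_(overall|exo|mtu)_(ankle|knee|hip)_wkg$", metric))[[1]]
  if (length(m) == 3L)
    return(pw$p_avg_w_per_kg[pw$contributor == m[2] & pw$joint == m[3]])
  m <- regmatches(metric,
                  regexec("^m_mtu_(ankle|knee|hip)_avg_nmkg$", metric))[[1]]
  if (length(m) == 2L) {
    cyc <- analysis$cycles$cycles
    idx <- unlist(mapply(seq, cyc$start, cyc$end, SIMPLIFY = FALSE))
    return(mean(analysis$kinetics$sum[[paste0("m_mtu_", m[2])]][idx]) /
             analysis$mass)
  }
  m <- regmatches(metric, regexec("^rom_(ankle|knee|hip)_deg$", metric))[[1]]
  if (length(m) == 2L)
    return(analysis$rom$rom_deg[analysis$rom$joint == m[2]])
  m <- regmatches(metric,
                  regexec("^peak_flexion_(ankle|knee|hip)_deg$", metric))[[1]]
  if (length(m) == 2L)
    return(analysis$rom$peak_flexion_deg[analysis$rom$joint == m[2]])
  if (metric %in% names(analysis$spatiotemporal))
    return(analysis$spatiotemporal[[metric]])
  stop(sprintf("unknown metric '%s'.", metric))
}

#' Condition-level statistics for an analysed cohort
#'
#' Builds the long-format participant x condition outcome table for a
#' metric and runs the repeated-measures ANOVA with Sidak-corrected post
#' hoc tests.
#'
#' @param cohort Result of [emit_cohort()] (list of simulated trials with a
#'   manifest attribute), or a data frame with columns `participant`,
#'   `condition`, `value`.
#' @param metric Metric name (see [extract_metric()]); ignored when
#'   `cohort` is already an outcome table.
#' @param config Passed to [analyze_trial()].
#' @param ... Passed to [posthoc_sidak()].
#' @return List with `table`, `anova`, `posthoc`.
#' @export
cohort_stats <- function(cohort, metric = "p_mtu_ankle_wkg",
                         config = analysis_config(), ...) {
  if (is.data.frame(cohort)) {
    tab <- cohort
  } else {
    man <- attr(cohort, "manifest")
    if (is.null(man)) stop("`cohort` lacks a manifest; use emit_cohort().")
    vals <- vapply(cohort, function(sim)
      extract_metric(analyze_trial(sim$trial, config), metric), numeric(1))
    tab <- data.frame(participant = man$participant,
                      condition = man$condition, value = vals)
  }
  an <- rm_anova(tab)
  ph <- posthoc_sidak(tab, anova = an, ...)
  list(table = tab, anova = an, posthoc = ph)
}
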