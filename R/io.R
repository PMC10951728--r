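# Readers and writers: TRC marker files, per-leg force CSVs, trial
# round-tripping, and tidy result tables with a JSON run manifest.
# All coordinates in memory are sagittal-plane (x forward, y up, metres);
# TRC files carry a third, mediolateral coordinate that is dropped (with a
# warning if its excursion is large) on read.

trc_marker_order <- c("hip", "knee", "ankle", "toe", "heel",
                      "exo_hip", "exo_foot")

#' Write marker trajectories to a TRC file
#'
#' Labels are `<LEG>_<MARKER>` (e.g. `L_HIP`, `R_EXO_FOOT`); coordinates
#' are written in millimetres with X forward, Y up and Z mediolateral
#' (+/- 0.1 m for the left/right leg).
#'
#' @param markers The `markers` element of a `hop_trial` (list with `time`,
#'   `rate`, and per-leg marker lists `L`, `R`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(markers, path) {
  n <- length(markers$time)
  labels <- character(0)
  cols <- list()
  for (leg in c("L", "R")) {
    zoff <- if (leg == "L") 100 else -100    # mm
    for (m in intersect(trc_marker_order, names(markers[[leg]]))) {
      labels <- c(labels, paste0(leg, "_", toupper(m)))
      xy <- markers[[leg]][[m]] * 1000
      cols[[length(cols) + 1L]] <- cbind(xy[, 1], xy[, 2], rep(zoff, n))
    }
  }
  nm <- length(labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines("DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames", con)
  writeLines(sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d",
                     markers$rate, markers$rate, n, nm, markers$rate, n), con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(labels, "", ""))), collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), nm),
                                    rep(seq_len(nm), each = 3))),
                   collapse = "\t"), con)
  writeLines("", con)
  dat <- do.call(cbind, cols)
  body <- apply(cbind(seq_len(n), markers$time, dat), 1, function(r)
    paste(c(sprintf("%d", r[1]), sprintf("%.8f", r[2]),
            sprintf("%.9f", r[-(1:2)])), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read marker trajectories from a TRC file
#'
#' Honours the header's sampling rate and units (mm are converted to m) and
#' projects onto the sagittal plane by dropping the mediolateral (Z) axis;
#' a warning is issued if the out-of-plane excursion of any marker exceeds
#' 5% of the apparent leg length.
#'
#' @param path TRC file path.
#' @return List with `time`, `rate` and per-leg marker lists `L`, `R`, as
#'   in a `hop_trial`.
#' @export
read_trc <- function(path) {
  if (!file.exists(path)) stop(sprintf("TRC file '%s' not found.", path))
  lines <- readLines(path)
  if (length(lines) < 6L)
    stop(sprintf("malformed TRC '%s': fewer than 6 header+data lines.", path))
  hdr <- strsplit(lines[3], "\t")[[1]]
  rate <- suppressWarnings(as.numeric(hdr[1]))
  units <- hdr[5]
  if (is.na(rate) || rate <= 0)
    stop(sprintf("malformed TRC '%s' line 3: bad DataRate '%s'.", path, hdr[1]))
  scale <- switch(units, mm = 1e-3, m = 1, cm = 1e-2,
                  stop(sprintf("TRC '%s': unsupported units '%s'.", path, units)))
  labels <- strsplit(lines[4], "\t")[[1]]
  labels <- labels[-(1:2)]
  labels <- labels[labels != ""]
  first_data <- 6L
  while (first_data <= length(lines) && !nzchar(trimws(lines[first_data])))
    first_data <- first_data + 1L
  dat <- utils::read.table(text = lines[first_data:length(lines)],
                           sep = "\t", header = FALSE)
  time <- dat[[2]]
  out <- list(time = time, rate = rate, L = list(), R = list())
  leg_len_guess <- NA_real_
  for (i in seq_along(labels)) {
    lab <- labels[i]
    leg <- substr(lab, 1, 1)
    mk <- tolower(substring(lab, 3))
    x <- dat[[2 + 3 * (i - 1) + 1]] * scale
    y <- dat[[2 + 3 * (i - 1) + 2]] * scale
    z <- dat[[2 + 3 * (i - 1) + 3]] * scale
    if (!leg %in% c("L", "R"))
      stop(sprintf("TRC '%s': label '%s' lacks an L_/R_ leg prefix.", path, lab))
    out[[leg]][[mk]] <- cbind(x, y)
    attr(out[[leg]][[mk]], "z_range") <- diff(range(z))
  }
  if (!is.null(out$L$hip) && !is.null(out$L$toe))
    leg_len_guess <- max(sqrt(rowSums((out$L$hip - out$L$toe)^2)))
  for (leg in c("L", "R")) for (mk in names(out[[leg]])) {
    zr <- attr(out[[leg]][[mk]], "z_range")
    if (is.finite(leg_len_guess) && isTRUE(zr > 0.05 * leg_len_guess))
      warning(sprintf(
        "marker %s_%s moves %.3f m out of the sagittal plane (> 5%% of leg length); projection may be inaccurate.",
        leg, toupper(mk), zr))
    attr(out[[leg]][[mk]], "z_range") <- NULL
  }
  out
}

#' Write a per-leg force series to CSV
#'
#' Columns: `time_s`, `fz_N`, `fx_N`, `cop_x_m`.
#'
#' @param grf_leg Data frame with `time`, `fz`, `fx`, `copx`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forces_csv <- function(grf_leg, path) {
  out <- data.frame(time_s = grf_leg$time, fz_N = grf_leg$fz,
                    fx_N = grf_leg$fx, cop_x_m = grf_leg$copx)
  utils::write.csv(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-leg force series from CSV
#'
#' @param path CSV path with header `time_s,fz_N,fx_N,cop_x_m`.
#' @return Data frame with `time`, `fz`, `fx`, `copx` and attribute `rate`
#'   (Hz, from the time column spacing).
#' @export
read_forces_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("force file '%s' not found.", path))
  dat <- utils::read.csv(path)
  for (col in c("time_s", "fz_N", "fx_N", "cop_x_m"))
    if (!col %in% names(dat))
      stop(sprintf("force file '%s' is missing required column '%s'.",
                   path, col))
  dt <- diff(dat$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6)
    stop(sprintf("force file '%s': time column is not uniformly increasing.",
                 path))
  out <- data.frame(time = dat$time_s, fz = dat$fz_N, fx = dat$fx_N,
                    copx = dat$cop_x_m)
  attr(out, "rate") <- 1 / mean(dt)
  out
}

#' Write a synthetic trial to disk
#'
#' Markers as TRC, per-leg forces as CSV, ground truth (when given) as CSV,
#' and a JSON manifest with participant metadata, condition, rates, seed
#' and the spring law.
#'
#' @param sim Result of [simulate_trial()] (or a bare `hop_trial`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(sim, dir) {
  trial <- if (inherits(sim, "hop_trial")) sim else sim$trial
  truth <- if (inherits(sim, "hop_trial")) NULL else sim$truth
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trc(trial$markers, file.path(dir, "markers.trc"))
  write_forces_csv(trial$grf$L, file.path(dir, "forces_L.csv"))
  write_forces_csv(trial$grf$R, file.path(dir, "forces_R.csv"))
  if (!is.null(truth))
    utils::write.csv(as.data.frame(truth), file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  exo <- trial$exo
  manifest <- list(
    participant = trial$participant,
    condition = trial$condition,
    marker_rate_hz = trial$markers$rate,
    grf_rate_hz = trial$grf$rate,
    seed = if (!is.null(trial$params)) trial$params$seed else NULL,
    exo = if (is.null(exo)) NULL else list(
      kind = exo$profile$kind,
      reference_force_n = exo$profile$reference_force,
      reference_displacement_m = exo$profile$reference_displacement,
      exponent = exo$profile$exponent,
      hysteresis_fraction = exo$profile$hysteresis_fraction,
      rest_length_m = exo$rest_length,
      leg_mass_kg = exo$leg_mass))
  jsonlite::write_json(manifest, file.path(dir, "trial.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a trial written by [write_trial()]
#'
#' @param dir Trial directory.
#' @return A `hop_trial`.
#' @export
read_trial <- function(dir) {
  mfile <- file.path(dir, "trial.json")
  if (!file.exists(mfile)) stop(sprintf("no trial manifest in '%s'.", dir))
  man <- jsonlite::read_json(mfile, simplifyVector = TRUE)
  mk <- read_trc(file.path(dir, "markers.trc"))
  if (abs(mk$rate - man$marker_rate_hz) > 1e-6)
    stop(sprintf("marker rate %g Hz in TRC disagrees with manifest %g Hz.",
                 mk$rate, man$marker_rate_hz))
  gl <- read_forces_csv(file.path(dir, "forces_L.csv"))
  gr <- read_forces_csv(file.path(dir, "forces_R.csv"))
  if (abs(attr(gl, "rate") - man$grf_rate_hz) > 1e-3)
    stop(sprintf("force rate %g Hz in CSV disagrees with manifest %g Hz.",
                 attr(gl, "rate"), man$grf_rate_hz))
  exo <- NULL
  if (!is.null(man$exo) && length(man$exo) > 0) {
    prof <- spring_profile(
      kind = switch(man$exo$kind, degressive = "degressive",
                    linear = "linear", progressive = "progressive",
                    man$exo$kind),
      reference_force = man$exo$reference_force_n,
      reference_displacement = man$exo$reference_displacement_m,
      exponent = man$exo$exponent,
      hysteresis_fraction = man$exo$hysteresis_fraction)
    exo <- list(profile = prof, rest_length = man$exo$rest_length_m,
                leg_mass = man$exo$leg_mass_kg)
  }
  structure(list(participant = man$participant,
                 condition = man$condition,
                 markers = mk,
                 grf = list(rate = man$grf_rate_hz, L = gl, R = gr),
                 exo = exo, params = NULL),
            class = "hop_trial")
}

#' Write tidy result tables and a run manifest
#'
#' One row per joint x contributor x metric from the power summary, plus
#' the spatiotemporal and range-of-motion summaries, and a JSON manifest
#' recording the analysis configuration and package version.
#'
#' @param analysis A `hop_analysis` from [analyze_trial()].
#' @param outdir Output directory (created if needed).
#' @param id Identifier recorded in the tables (e.g. participant id).
#' @return `outdir`, invisibly.
#' @export
write_tables <- function(analysis, outdir, id = "trial") {
  stopifnot(inherits(analysis, "hop_analysis"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pw <- as.data.frame(analysis$power)
  long <- do.call(rbind, lapply(c("p_avg_w", "p_avg_w_per_kg", "pct"),
                                function(metric)
    data.frame(id = id, condition = analysis$condition,
               joint = pw$joint, contributor = pw$contributor,
               metric = metric, value = pw[[metric]])))
  utils::write.csv(long, file.path(outdir, "power_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(id = id, condition = analysis$condition,
                         analysis$spatiotemporal),
                   file.path(outdir, "spatiotemporal.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(id = id, condition = analysis$condition,
                         analysis$rom),
                   file.path(outdir, "rom.csv"), row.names = FALSE)
  manifest <- list(id = id, condition = analysis$condition,
                   package_version = as.character(utils::packageVersion("hopexo")),
                   config = unclass(analysis$config),
                   n_cycles = nrow(analysis$cycles$cycles))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
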