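# Filtering, resampling, contact detection and hop-cycle segmentation.
# Kinetics conventions downstream assume all series share a common time
# origin and uniform sampling.

#' Zero-phase low-pass Butterworth filter
#'
#' Dual-pass (forward--backward) Butterworth filtering with reflection
#' padding, the standard treatment for marker and force data in
#' biomechanics. The requested `order` is the *effective* order: each pass
#' uses a Butterworth design of `order/2`, so two passes of a second-order
#' filter realize a fourth-order zero-phase response whose gain at the
#' cutoff frequency is 0.5.
#'
#' @param x Numeric vector or matrix (columns are channels).
#' @param rate Sampling rate (Hz).
#' @param cutoff_hz Cutoff frequency (Hz); must be below the Nyquist rate.
#' @param order Effective filter order (even), default 4.
#' @return Filtered data, same shape as `x`. DC gain is 1.
#' @export
lowpass <- function(x, rate, cutoff_hz = 20, order = 4) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop("`cutoff_hz` must be positive and below the Nyquist frequency rate/2.")
  if (order %% 2 != 0 || order < 2)
    stop("`order` must be a positive even number (half is applied per pass).")
  bf <- signal::butter(order / 2, cutoff_hz / (rate / 2), type = "low")
  if (is.matrix(x)) {
    out <- apply(x, 2, filtfilt_padded, bf = bf, rate = rate,
                 cutoff_hz = cutoff_hz)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  filtfilt_padded(x, bf, rate, cutoff_hz)
}

# forward-backward filtering with odd-reflection padding of at least three
# filter lengths (capped at the series length) to suppress edge transients
filtfilt_padded <- function(v, bf, rate, cutoff_hz) {
  n <- length(v)
  if (n < 4L) return(v)
  npad <- min(n - 1L, ceiling(3 * rate / cutoff_hz))
  head_pad <- 2 * v[1] - v[seq(npad + 1L, 2L)]
  tail_pad <- 2 * v[n] - v[seq(n - 1L, n - npad)]
  vp <- c(head_pad, v, tail_pad)
  vp <- as.numeric(signal::filter(bf, vp))
  vp <- rev(as.numeric(signal::filter(bf, rev(vp))))
  vp[seq(npad + 1L, npad + n)]
}

#' Detect ground contact events and segment hop cycles
#'
#' Applies a force threshold to the (summed) vertical ground reaction force:
#' a contact onset is the first sample at or above the threshold following a
#' sub-threshold run, and toe-off is the first sample below the threshold
#' following contact. Runs shorter than the debounce window are merged into
#' their neighbours. A hop cycle is the half-open interval from one onset to
#' the next; incomplete leading/trailing cycles are dropped.
#'
#' @param vgrf Numeric vector of vertical GRF (N).
#' @param rate Sampling rate (Hz).
#' @param threshold_n Contact threshold (N), default 20.
#' @param debounce_s Minimum event duration (s), default 0.010.
#' @return An object of class `hop_cycles`: list with `onsets`, `toeoffs`
#'   (sample indices), a `cycles` data frame (`start`, `end`, `toeoff`,
#'   `contact_time_s`, `aerial_time_s`, `aerial_fraction`), and `rate`.
#'   Zero complete cycles yields an empty `cycles` data frame, not an error.
#' @export
detect_contacts <- function(vgrf, rate, threshold_n = 20, debounce_s = 0.010) {
  stopifnot(is.numeric(vgrf), is.numeric(rate), rate > 0)
  if (threshold_n <= 0) stop("`threshold_n` must be positive.")
  above <- vgrf >= threshold_n
  min_run <- max(1L, as.integer(round(debounce_s * rate)))
  # merge interior runs shorter than the debounce window into neighbours
  repeat {
    runs <- rle(above)
    k <- length(runs$lengths)
    if (k <= 2L) break
    short <- which(runs$lengths < min_run)
    short <- short[short > 1L & short < k]
    if (length(short) == 0L) break
    ends <- cumsum(runs$lengths)
    i <- short[1]
    idx <- seq(ends[i - 1L] + 1L, ends[i])
    above[idx] <- !above[idx]
  }
  runs <- rle(above)
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  onsets <- starts[runs$values & seq_along(runs$values) > 1L]
  toeoffs <- starts[!runs$values & seq_along(runs$values) > 1L]
  cycles <- empty_cycles_df()
  if (length(onsets) >= 2L) {
    for (i in seq_len(length(onsets) - 1L)) {
      s <- onsets[i]; e <- onsets[i + 1L] - 1L
      toff <- toeoffs[toeoffs > s & toeoffs <= e + 1L]
      if (length(toff) != 1L) next
      ct <- (toff - s) / rate
      at <- (onsets[i + 1L] - toff) / rate
      cycles <- rbind(cycles, data.frame(
        start = s, end = e, toeoff = toff,
        contact_time_s = ct, aerial_time_s = at,
        aerial_fraction = at / (ct + at)))
    }
  }
  structure(list(onsets = onsets, toeoffs = toeoffs, cycles = cycles,
                 rate = rate, threshold_n = threshold_n),
            class = "hop_cycles")
}

empty_cycles_df <- function() {
  data.frame(start = integer(), end = integer(), toeoff = integer(),
             contact_time_s = numeric(), aerial_time_s = numeric(),
             aerial_fraction = numeric())
}

#' @export
print.hop_cycles <- function(x, ...) {
  cat(sprintf("<hop_cycles> %d complete cycles at %g Hz (threshold %g N)\n",
              nrow(x$cycles), x$rate, x$threshold_n))
  if (nrow(x$cycles) > 0)
    cat(sprintf("  mean contact %.3f s, mean aerial %.3f s\n",
                mean(x$cycles$contact_time_s), mean(x$cycles$aerial_time_s)))
  invisible(x)
}

# map a hop_cycles object onto a grid at a different (lower) rate sharing
# the same time origin
cycles_to_rate <- function(cycles, target_rate) {
  stopifnot(inherits(cycles, "hop_cycles"))
  f <- target_rate / cycles$rate
  conv <- function(i) as.integer(round((i - 1L) * f)) + 1L
  out <- cycles
  out$onsets <- conv(cycles$onsets)
  out$toeoffs <- conv(cycles$toeoffs)
  if (nrow(cycles$cycles) > 0) {
    out$cycles$start <- conv(cycles$cycles$start)
    out$cycles$toeoff <- conv(cycles$cycles$toeoff)
    out$cycles$end <- conv(cycles$cycles$end + 1L) - 1L
  }
  out$rate <- target_rate
  out
}

#' Decimate a series to a lower sampling rate
#'
#' Anti-alias low-pass filtering (zero-phase, cutoff at 45% of the target
#' rate) followed by point decimation. The rate ratio must be an integer.
#'
#' @inheritParams lowpass
#' @param target_rate Target sampling rate (Hz).
#' @return Decimated vector or matrix.
#' @export
resample_to <- function(x, rate, target_rate) {
  if (target_rate == rate) return(x)
  if (target_rate > rate)
    stop("`resample_to()` only decimates; target rate must not exceed the input rate.")
  ratio <- rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("rate ratio %g/%g is not an integer; cannot decimate.",
                 rate, target_rate))
  ratio <- as.integer(round(ratio))
  xf <- lowpass(x, rate, cutoff_hz = 0.45 * target_rate, order = 8)
  if (is.matrix(xf)) xf[seq(1L, nrow(xf), by = ratio), , drop = FALSE]
  else xf[seq(1L, length(xf), by = ratio)]
}

#' Time-normalize a series over one cycle
#'
#' Linear interpolation of a cycle's samples onto `n_points` points spanning
#' 0--100% of the cycle, as used for ensemble-averaged hop-cycle curves.
#'
#' @param x Numeric vector or matrix (rows are samples of one cycle).
#' @param n_points Number of output points, default 101 (0, 1, ..., 100%).
#' @return Interpolated vector or matrix with `n_points` rows, plus an
#'   attribute `percent` giving the 0--100 grid.
#' @export
time_normalize <- function(x, n_points = 101L) {
  if (n_points < 2L) stop("`n_points` must be >= 2.")
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n < 2L) stop("need at least 2 samples in the cycle.")
  at <- seq(1, n, length.out = n_points)
  interp <- function(v) stats::approx(seq_len(n), v, xout = at)$y
  out <- if (is.matrix(x)) apply(x, 2, interp) else interp(x)
  attr(out, "percent") <- seq(0, 100, length.out = n_points)
  out
}
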