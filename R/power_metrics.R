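# Average positive power per joint and contributor, and its distribution.
# The average positive power over a hop cycle is the trapezoidal integral
# of the positive part of the instantaneous power, divided by the cycle
# duration; totals sum the overall contribution over ankle, knee and hip,
# and percentages express each joint/contributor share of that total.

#' Average positive power over one cycle
#'
#' Trapezoidal integration of the positive part of a power series over one
#' hop cycle, divided by the cycle duration. Sign changes between adjacent
#' samples contribute the positive triangular sub-area via linear
#' interpolation of the zero crossing, so the result does not depend on a
#' sample landing exactly on the crossing. The positive-part threshold is
#' exactly 0 W (no dead band).
#'
#' @param p Power series (W) over one cycle.
#' @param time Sample times (s), same length, strictly increasing.
#' @return Average positive power (W).
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 201)
#' average_positive_power(sin(2 * pi * t), t)  # ~ 1/pi
average_positive_power <- function(p, time) {
  n <- length(p)
  if (n != length(time) || n < 2L)
    stop("`p` and `time` must have equal length >= 2.")
  dur <- time[n] - time[1]
  if (dur <= 0) stop("cycle has non-positive duration.")
  p1 <- p[-n]; p2 <- p[-1]
  dt <- diff(time)
  both_pos <- p1 >= 0 & p2 >= 0
  cross_down <- p1 > 0 & p2 < 0
  cross_up <- p1 < 0 & p2 > 0
  area <- numeric(n - 1L)
  area[both_pos] <- dt[both_pos] * (p1[both_pos] + p2[both_pos]) / 2
  area[cross_down] <- dt[cross_down] * p1[cross_down]^2 /
    (2 * (p1[cross_down] - p2[cross_down]))
  area[cross_up] <- dt[cross_up] * p2[cross_up]^2 /
    (2 * (p2[cross_up] - p1[cross_up]))
  sum(area) / dur
}

#' Summarize average positive power by joint and contributor
#'
#' Computes per-cycle average positive power separately for each leg and
#' each joint x contributor (overall, exoskeleton, MTU), sums the two legs,
#' averages across the analysis cycles (by default the last 20 complete
#' cycles), and expresses every entry as a percentage of the total overall
#' average positive power summed over the ankle, knee and hip.
#'
#' @param decomp_legs Named list (`L`, `R`) of [decompose()] outputs on the
#'   analysis grid.
#' @param cycles A `hop_cycles` object on the same grid.
#' @param mass Body mass (kg) for mass-normalized values.
#' @param n_cycles Number of (trailing) complete cycles to analyse,
#'   default 20; fewer are used if fewer exist.
#' @return Object of class `power_summary`: data frame with columns
#'   `joint`, `contributor`, `p_avg_w`, `p_avg_w_per_kg`, `pct`, and
#'   attributes `p_total_w` and `n_cycles`.
#' @export
summarize_power <- function(decomp_legs, cycles, mass, n_cycles = 20L) {
  stopifnot(is.list(decomp_legs), all(c("L", "R") %in% names(decomp_legs)),
            inherits(cycles, "hop_cycles"))
  if (mass <= 0) stop("`mass` must be positive.")
  cyc <- cycles$cycles
  if (nrow(cyc) < 1L) stop("need at least one complete hop cycle.")
  if (nrow(cyc) > n_cycles)
    cyc <- cyc[seq(nrow(cyc) - n_cycles + 1L, nrow(cyc)), ]
  time <- decomp_legs$L$time
  joints <- c("ankle", "knee", "hip")
  contribs <- c("overall", "exo", "mtu")
  per_cycle <- array(0, dim = c(nrow(cyc), length(joints), length(contribs)),
                     dimnames = list(NULL, joints, contribs))
  for (ci in seq_len(nrow(cyc))) {
    idx <- cyc$start[ci]:cyc$end[ci]
    for (j in joints) for (cc in contribs) {
      col <- paste0("p_", cc, "_", j)
      per_cycle[ci, j, cc] <-
        average_positive_power(decomp_legs$L[[col]][idx], time[idx]) +
        average_positive_power(decomp_legs$R[[col]][idx], time[idx])
    }
  }
  pbar <- apply(per_cycle, c(2, 3), mean)
  p_total <- sum(pbar[, "overall"])
  if (p_total <= 0)
    stop("total average positive power is zero; percentage distribution undefined.")
  out <- expand.grid(joint = joints, contributor = contribs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$p_avg_w <- mapply(function(j, cc) pbar[j, cc], out$joint,
                        out$contributor)
  out$p_avg_w_per_kg <- out$p_avg_w / mass
  out$pct <- out$p_avg_w / p_total * 100
  attr(out, "p_total_w") <- p_total
  attr(out, "n_cycles") <- nrow(cyc)
  class(out) <- c("power_summary", "data.frame")
  out
}

#' @export
print.power_summary <- function(x, ...) {
  cat(sprintf("<power_summary> total average positive power %.1f W over %d cycles\n",
              attr(x, "p_total_w"), attr(x, "n_cycles")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
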