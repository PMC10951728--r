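# Spring stiffness profiles for a passive, full-leg, parallel-elastic
# exoskeleton. Degressive (DG), linear (LN) and progressive (PG) springs are
# modelled as a power law through the origin pinned at a common secant point
# (the reference compression, 0.10 m by convention), so that all three kinds
# exert the same force at the reference displacement while differing in how
# stiffness evolves with compression.

#' Construct a parametric spring stiffness profile
#'
#' The canonical family is a power law through the origin,
#' `F(d) = reference_force * (d / reference_displacement)^exponent` on the
#' loading branch, clamped to zero force for `d <= 0`. All profiles built
#' with the same `reference_force` share the same secant stiffness at the
#' reference displacement. The exponent controls the stiffness profile:
#' below 1 the spring is degressive (initially stiff, softening with
#' compression), 1 is linear, above 1 progressive (initially compliant,
#' stiffening with compression).
#'
#' @param kind One of `"linear"`, `"degressive"`, `"progressive"`.
#' @param reference_force Force (N) exerted at `reference_displacement` on
#'   the loading branch. Must be positive.
#' @param reference_displacement Reference compression (m), default 0.10.
#' @param exponent Power-law shape exponent. Defaults to 1 (linear),
#'   0.47 (degressive) or 3.21 (progressive); these defaults are calibrated
#'   so that equal-secant stored-energy ratios are 1.36 (DG vs LN) and
#'   2.86 (DG vs PG). Must be consistent with `kind`.
#' @param hysteresis_fraction Fraction of stored elastic energy lost per
#'   loading--unloading cycle, in `[0, 1)`. The unloading branch is the
#'   loading branch scaled by `1 - hysteresis_fraction` in force, which
#'   makes the returned energy exactly `(1 - hysteresis_fraction)` times the
#'   stored energy.
#' @param rest_length Optional free length of the assembled spring (m).
#'
#' @return An object of class `spring_profile`.
#' @seealso [spring_force()], [stored_energy()], [calibrate_exponent()],
#'   [spring_profile_table()]
#' @export
#' @examples
#' ln <- spring_profile("linear", reference_force = 844)
#' dg <- spring_profile("degressive", reference_force = 844)
#' spring_force(ln, 0.05)  # 422 N
#' spring_force(dg, 0.10)  # 844 N: same secant force as the linear spring
spring_profile <- function(kind = c("linear", "degressive", "progressive"),
                           reference_force,
                           reference_displacement = 0.10,
                           exponent = NULL,
                           hysteresis_fraction = 0,
                           rest_length = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(reference_force), length(reference_force) == 1L,
            is.finite(reference_force))
  if (reference_force <= 0)
    stop("`reference_force` must be positive (N).")
  if (!is.numeric(reference_displacement) || length(reference_displacement) != 1L ||
      reference_displacement <= 0)
    stop("`reference_displacement` must be a positive length (m).")
  if (is.null(exponent))
    exponent <- switch(kind, linear = 1, degressive = 0.47, progressive = 3.21)
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent <= 0)
    stop("`exponent` must be a positive scalar.")
  ok <- switch(kind,
               linear = exponent == 1,
               degressive = exponent < 1,
               progressive = exponent > 1)
  if (!ok)
    stop(sprintf(
      "exponent %.4g is inconsistent with kind '%s' (degressive < 1, linear = 1, progressive > 1).",
      exponent, kind))
  if (!is.numeric(hysteresis_fraction) || length(hysteresis_fraction) != 1L ||
      hysteresis_fraction < 0 || hysteresis_fraction >= 1)
    stop("`hysteresis_fraction` must lie in [0, 1).")
  if (!is.null(rest_length) && (!is.numeric(rest_length) || rest_length <= 0))
    stop("`rest_length` must be a positive length (m).")
  structure(
    list(kind = kind,
         reference_force = reference_force,
         reference_displacement = reference_displacement,
         exponent = exponent,
         hysteresis_fraction = hysteresis_fraction,
         rest_length = rest_length,
         table = NULL),
    class = "spring_profile")
}

#' Construct a tabulated spring profile from measured force--displacement data
#'
#' For springs characterized on a materials testing machine rather than by a
#' parametric law. Displacements must be strictly increasing from 0 with zero
#' force at zero displacement; queries use monotone piecewise-linear
#' interpolation and refuse to extrapolate beyond the tabulated range.
#'
#' @param table Data frame with columns `displacement_m` and `force_N`
#'   (loading branch), optionally `displacement_unload_m` and
#'   `force_unload_N` for a measured unloading branch.
#' @inheritParams spring_profile
#' @return An object of class `spring_profile` with `kind = "tabulated"`.
#' @export
spring_profile_table <- function(table, hysteresis_fraction = 0,
                                 rest_length = NULL) {
  req <- c("displacement_m", "force_N")
  if (!is.data.frame(table) || !all(req %in% names(table)))
    stop("`table` must be a data frame with columns 'displacement_m' and 'force_N'.")
  d <- table$displacement_m
  f <- table$force_N
  if (anyDuplicated(d))
    stop("tabulated displacements contain ties; displacements must be strictly increasing.")
  if (is.unsorted(d, strictly = TRUE))
    stop("tabulated displacements must be strictly increasing.")
  if (d[1] != 0 || f[1] != 0)
    stop("tabulated profile must start at displacement 0 with force 0.")
  if (any(f < 0) || is.unsorted(f))
    stop("tabulated loading force must be non-negative and non-decreasing.")
  unloading <- NULL
  if (all(c("displacement_unload_m", "force_unload_N") %in% names(table))) {
    du <- table$displacement_unload_m
    fu <- table$force_unload_N
    if (is.unsorted(du, strictly = TRUE))
      stop("tabulated unloading displacements must be strictly increasing.")
    unloading <- list(d = du, f = fu)
  }
  if (!is.numeric(hysteresis_fraction) || hysteresis_fraction < 0 ||
      hysteresis_fraction >= 1)
    stop("`hysteresis_fraction` must lie in [0, 1).")
  structure(
    list(kind = "tabulated",
         reference_force = NA_real_,
         reference_displacement = max(d),
         exponent = NA_real_,
         hysteresis_fraction = hysteresis_fraction,
         rest_length = rest_length,
         table = list(loading = list(d = d, f = f), unloading = unloading)),
    class = "spring_profile")
}

#' @export
print.spring_profile <- function(x, ...) {
  if (x$kind == "tabulated") {
    cat(sprintf("<spring_profile> tabulated, %d points up to %.3f m, hysteresis %.2f\n",
                length(x$table$loading$d), x$reference_displacement,
                x$hysteresis_fraction))
  } else {
    cat(sprintf(
      "<spring_profile> %s: F(d) = %.4g N * (d / %.3g m)^%.3g, hysteresis %.2f\n",
      x$kind, x$reference_force, x$reference_displacement, x$exponent,
      x$hysteresis_fraction))
  }
  invisible(x)
}

#' Evaluate spring force at a displacement
#'
#' @param profile A [spring_profile()].
#' @param displacement Compression (m); vectorized. Forces are zero for
#'   non-positive displacements.
#' @param branch `"loading"` or `"unloading"`; either a single value or a
#'   vector matched to `displacement`. The unloading branch returns
#'   `(1 - hysteresis_fraction)` of the loading force at every displacement,
#'   unless a measured unloading table is present.
#' @return Force (N), same length as `displacement`.
#' @export
spring_force <- function(profile, displacement,
                         branch = "loading") {
  stopifnot(inherits(profile, "spring_profile"))
  if (!is.numeric(displacement) || any(!is.finite(displacement)))
    stop("`displacement` must be finite.")
  branch <- match_branch(branch, length(displacement))
  d <- pmax(displacement, 0)
  if (profile$kind == "tabulated") {
    tl <- profile$table$loading
    if (any(d > max(tl$d) + 1e-12))
      stop(sprintf(
        "displacement %.4g m outside tabulated range [0, %.4g m]; refusing to extrapolate.",
        max(d), max(tl$d)))
    f <- stats::approx(tl$d, tl$f, xout = pmin(d, max(tl$d)), rule = 2)$y
    un <- branch == "unloading"
    if (any(un)) {
      if (!is.null(profile$table$unloading)) {
        tu <- profile$table$unloading
        f[un] <- stats::approx(tu$d, tu$f, xout = pmin(d[un], max(tu$d)),
                               rule = 2)$y
      } else {
        f[un] <- f[un] * (1 - profile$hysteresis_fraction)
      }
    }
  } else {
    f <- profile$reference_force *
      (d / profile$reference_displacement)^profile$exponent
    un <- branch == "unloading"
    if (any(un)) f[un] <- f[un] * (1 - profile$hysteresis_fraction)
  }
  f[displacement <= 0] <- 0
  f
}

match_branch <- function(branch, n) {
  if (!all(branch %in% c("loading", "unloading")))
    stop("`branch` must be 'loading' or 'unloading'.")
  if (length(branch) == 1L) rep(branch, n) else {
    if (length(branch) != n)
      stop("`branch` must be scalar or match `displacement` in length.")
    branch
  }
}

#' Elastic energy stored (or returned) at a displacement
#'
#' Work integral of the force--displacement curve from 0 to `displacement`,
#' computed by trapezoidal quadrature. For parametric profiles the closed
#' form is `reference_force * displacement / (exponent + 1)` when evaluated
#' at the reference displacement.
#'
#' @inheritParams spring_force
#' @param displacement Scalar compression (m), `>= 0`.
#' @param branch `"loading"` gives stored energy, `"unloading"` gives energy
#'   returned over an unloading stroke from `displacement` back to zero.
#' @param n_nodes Number of quadrature nodes (default 10001).
#' @return Energy (J).
#' @export
#' @examples
#' ln <- spring_profile("linear", 844)
#' stored_energy(ln, 0.10)  # 42.2 J, i.e. 0.5 * k * d^2
stored_energy <- function(profile, displacement, branch = "loading",
                          n_nodes = 10001L) {
  stopifnot(inherits(profile, "spring_profile"),
            is.numeric(displacement), length(displacement) == 1L)
  if (displacement < 0) stop("`displacement` must be >= 0.")
  if (displacement == 0) return(0)
  grid <- seq(0, displacement, length.out = max(2L, as.integer(n_nodes)))
  f <- spring_force(profile, grid, branch = branch)
  pracma::trapz(grid, f)
}

#' Solve for the power-law exponent giving a target equal-secant energy ratio
#'
#' For power-law profiles sharing the same secant force at the reference
#' displacement, stored energy is `F_ref * d_ref / (exponent + 1)`, so the
#' energy ratio of a candidate profile relative to the linear one is
#' `2 / (exponent + 1)`. This inverts that relation:
#' `exponent = 2 / ratio - 1`.
#'
#' @param target_energy_ratio_vs_linear Desired ratio of stored energy to a
#'   linear spring of equal secant stiffness; must lie in `(0, 2)`.
#' @return The power-law exponent.
#' @export
#' @examples
#' calibrate_exponent(1.36)       # ~0.47: a degressive spring
#' calibrate_exponent(2 / 4.21)   # ~3.21: a progressive spring
calibrate_exponent <- function(target_energy_ratio_vs_linear) {
  r <- target_energy_ratio_vs_linear
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("`target_energy_ratio_vs_linear` must be a positive scalar.")
  if (r >= 2)
    stop("energy ratio >= 2 would require a non-positive exponent; no power-law profile attains it.")
  2 / r - 1
}

#' Reference participant and stiffness table
#'
#' The 14-participant reference cohort with per-participant calculated
#' exoskeleton stiffness (`k_calc`, kN/m, the sum of both springs at 10 cm of
#' displacement) and the stiffnesses of the degressive, linear and
#' progressive spring sets actually assigned (`k_dg`, `k_ln`, `k_pg`).
#' Used to calibrate the default body-mass stiffness prescription.
#'
#' @return A data frame with columns `sex`, `age_yr`, `height_m`,
#'   `leg_length_m`, `mass_kg`, `k_calc`, `k_dg`, `k_ln`, `k_pg`.
#' @export
participant_reference <- function() {
  data.frame(
    sex = c("F","F","F","F","F","F","F","M","M","M","M","M","M","M"),
    age_yr = c(37, 22, 23, 25, 26, 26, 23, 43, 20, 24, 30, 25, 20, 30),
    height_m = c(1.70, 1.53, 1.70, 1.65, 1.73, 1.62, 1.59, 1.63, 1.67, 1.73,
                 1.79, 1.80, 1.64, 1.73),
    leg_length_m = c(0.92, 0.86, 0.87, 0.87, 0.93, 0.84, 0.85, 0.94, 0.90,
                     0.94, 0.94, 0.98, 0.86, 0.88),
    mass_kg = c(58.9, 60.0, 60.6, 62.0, 62.8, 62.9, 63.6, 65.4, 65.9, 67.5,
                69.2, 71.6, 75.3, 77.7),
    k_calc = c(7.84, 7.98, 8.08, 8.24, 8.36, 8.38, 8.46, 8.70, 8.80, 8.98,
               9.22, 9.50, 9.96, 10.34),
    k_dg = c(7.8, 8.4, 7.8, 7.8, 8.2, 7.8, 7.8, 8.2, 9.0, 8.2, 8.2, 9.4,
             10.6, 10.6),
    k_ln = c(7.00, 8.44, 8.44, 8.44, 8.44, 8.44, 8.44, 8.44, 8.44, 8.44,
             9.46, 9.46, 9.46, 10.6),
    k_pg = c(8.00, 8.00, 8.00, 8.00, 8.00, 8.00, 8.00, 8.00, 9.00, 9.00,
             9.00, 10.00, 10.00, 10.00))
}

#' Body-mass stiffness prescription model
#'
#' Exoskeleton stiffness (both springs summed, at the reference compression)
#' is prescribed in proportion to body mass. The default constant is
#' calibrated as the mean of `k_calc / mass` over the reference cohort
#' (about 0.1330 kN/m per kg).
#'
#' @param constant Stiffness per unit mass (kN/m per kg). `NULL` (default)
#'   calibrates from [participant_reference()].
#' @param rounding Decimal places used when reporting prescribed stiffness.
#' @return An object of class `prescription_model`.
#' @export
prescription_model <- function(constant = NULL, rounding = 2L) {
  if (is.null(constant)) {
    ref <- participant_reference()
    constant <- mean(ref$k_calc / ref$mass_kg)
  }
  if (!is.numeric(constant) || length(constant) != 1L || constant <= 0)
    stop("`constant` must be a positive scalar (kN/m per kg).")
  structure(list(constant = constant, rounding = as.integer(rounding)),
            class = "prescription_model")
}

#' @export
print.prescription_model <- function(x, ...) {
  cat(sprintf("<prescription_model> k = %.5f kN/m per kg, reported to %d dp\n",
              x$constant, x$rounding))
  invisible(x)
}

#' Prescribe exoskeleton stiffness for a body mass
#'
#' @param mass Body mass (kg); vectorized.
#' @param model A [prescription_model()].
#' @return Prescribed total stiffness (kN/m, both springs summed at the
#'   reference compression), rounded per the model.
#' @export
#' @examples
#' prescribe_stiffness(58.9)  # 7.84 kN/m
prescribe_stiffness <- function(mass, model = prescription_model()) {
  stopifnot(inherits(model, "prescription_model"))
  if (!is.numeric(mass) || any(mass <= 0))
    stop("`mass` must be positive (kg).")
  round(model$constant * mass, model$rounding)
}

#' Read a tabulated spring force--displacement file
#'
#' Two-column (or four-column, with an unloading branch) CSV with header
#' `displacement_m,force_N[,displacement_unload_m,force_unload_N]`,
#' displacements strictly increasing from 0.
#'
#' @param path Path to the CSV file.
#' @inheritParams spring_profile
#' @return A `spring_profile` of kind `"tabulated"`.
#' @export
read_spring_table <- function(path, hysteresis_fraction = 0,
                              rest_length = NULL) {
  if (!file.exists(path)) stop(sprintf("spring table '%s' not found.", path))
  tab <- utils::read.csv(path, check.names = TRUE)
  if (!all(c("displacement_m", "force_N") %in% names(tab)))
    stop(sprintf("spring table '%s' must have columns 'displacement_m' and 'force_N'.",
                 path))
  spring_profile_table(tab, hysteresis_fraction = hysteresis_fraction,
                       rest_length = rest_length)
}
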