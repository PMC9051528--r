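#' Kinetic parameters of the two-compartment exchange model
#'
#' Bundles and validates the four 2CXM parameters: plasma flow `Fp`
#' (ml/min/ml), fractional plasma volume `vp`, fractional interstitial
#' volume `ve` (both dimensionless) and the permeability--surface area
#' product `PS` (ml/min/ml).  `Fp` and `PS` must be non-negative, `vp` and
#' `ve` must lie in (0, 1].  The physiological constraint `vp + ve <= 1` is
#' checked with a warning only, since fitted values may transiently violate
#' it and some valid simulation settings approach it.
#'
#' @param Fp plasma flow, ml/min/ml.
#' @param vp fractional plasma volume in (0, 1].
#' @param ve fractional interstitial volume in (0, 1].
#' @param PS permeability--surface area product, ml/min/ml.
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' kinetic_params(Fp = 1, vp = 0.05, ve = 0.2, PS = 1.5)
#' @export
kinetic_params <- function(Fp, vp, ve, PS) {
  vals <- c(Fp = Fp, vp = vp, ve = ve, PS = PS)
  if (!all(is.finite(vals))) stop("kinetic parameters must be finite")
  if (Fp < 0 || PS < 0) stop("Fp and PS must be non-negative")
  if (vp <= 0 || vp > 1) stop("vp must lie in (0, 1]")
  if (ve <= 0 || ve > 1) stop("ve must lie in (0, 1]")
  if (vp + ve > 1)
    warning("vp + ve exceeds 1; the parameter set is not physiological")
  structure(list(Fp = Fp, vp = vp, ve = ve, PS = PS),
            class = "kinetic_params")
}

as_param_vec <- function(params) {
  if (inherits(params, "kinetic_params"))
    return(c(params$Fp, params$vp, params$ve, params$PS))
  p <- unlist(params)
  if (length(p) != 4) stop("expected four kinetic parameters")
  if (!is.null(names(p)) && all(c("Fp", "vp", "ve", "PS") %in% names(p)))
    p <- p[c("Fp", "vp", "ve", "PS")]
  unname(p)
}

#' Uniform time grid for concentration--time curves
#'
#' The convention is a half-open interval `[0, T)` sampled every `dt`
#' minutes, so `T = 2` at `dt = 0.02` gives exactly 100 samples starting
#' at zero.
#'
#' @param T total duration, minutes.
#' @param dt sampling interval, minutes.
#' @return Object of class `time_grid` with elements `t` (vector, minutes)
#'   and `dt`.
#' @export
time_grid <- function(T = 2, dt = 0.02) {
  n <- round(T / dt)
  if (n < 2) stop("time grid needs at least two points")
  structure(list(t = (seq_len(n) - 1) * dt, dt = dt), class = "time_grid")
}

grid_times <- function(grid) {
  if (inherits(grid, "time_grid")) return(grid$t)
  t <- as.numeric(grid)
  if (length(t) < 2 || any(diff(t) <= 0))
    stop("time grid must be strictly increasing with at least two points")
  t
}

#' Solve the 2CXM forward problem
#'
#' Integrates the coupled plasma/interstitium ODEs
#' \deqn{v_p \dot C_p = F_p (C_{AIF} - C_p) + PS (C_e - C_p), \quad
#'       v_e \dot C_e = PS (C_p - C_e)}
#' from zero initial conditions, for an AIF sampled on the output grid and
#' treated as piecewise linear in between.  The default `"exact"` method
#' propagates the state with the matrix exponential of an augmented linear
#' system; for piecewise-linear forcing this is exact up to floating-point
#' rounding and is unconditionally stable, which matters because the system
#' is stiff for small `vp`.  `"rk4"` is an independent fixed-step
#' Runge--Kutta integrator on a refined grid (at least `refine` substeps
#' per sampling interval, increased automatically when stability demands
#' it), retained as a numerical cross-check.
#'
#' @param params a [kinetic_params] object (or coercible 4-vector).
#' @param aif arterial input function sampled on the grid, mM.
#' @param grid a [time_grid] or numeric vector of times, minutes.
#' @param method `"exact"` (default) or `"rk4"`.
#' @param refine minimum RK4 substeps per interval (ignored for `"exact"`).
#' @return Object of class `cxm_curves`: list with `t`, `Cp`, `Ce` and the
#'   tissue curve `Cmyo = vp Cp + ve Ce`, all in mM.
#' @examples
#' g <- time_grid()
#' aif <- gamma_variate_aif(g$t)
#' sol <- solve_2cxm(kinetic_params(1, 0.05, 0.2, 1.5), aif, g)
#' @export
solve_2cxm <- function(params, aif, grid, method = c("exact", "rk4"),
                       refine = 10) {
  method <- match.arg(method)
  p <- as_param_vec(params)
  t <- grid_times(grid)
  aif <- as.numeric(aif)
  if (length(aif) != length(t))
    stop("aif length must match the time grid")
  if (!all(is.finite(aif))) stop("AIF contains non-finite values")
  sol <- cxm_solve_cpp(p, t, aif, if (method == "exact") 0L else 1L,
                       as.integer(refine))
  structure(list(t = t, Cp = sol[, 1], Ce = sol[, 2],
                 Cmyo = p[2] * sol[, 1] + p[3] * sol[, 2]),
            class = "cxm_curves")
}

#' 2CXM compartment residuals
#'
#' Evaluates the residual forms of the two model ODEs,
#' \deqn{r_p = v_p \dot C_p - PS (C_e - C_p) - F_p (C_{AIF} - C_p), \quad
#'       r_e = v_e \dot C_e - PS (C_p - C_e),}
#' given concentrations and their time derivatives (supplied by the caller,
#' e.g. from automatic differentiation or [fd_derivative]).
#'
#' @param Cp,Ce plasma and interstitial concentration vectors, mM.
#' @param dCp_dt,dCe_dt their time derivatives, mM/min.
#' @param aif AIF vector, mM.
#' @param params a [kinetic_params] object (or 4-vector).
#' @return List with residual vectors `rp` and `re`.
#' @export
residuals_2cxm <- function(Cp, Ce, dCp_dt, dCe_dt, aif, params) {
  n <- length(Cp)
  if (any(c(length(Ce), length(dCp_dt), length(dCe_dt), length(aif)) != n))
    stop("all input vectors must share a length")
  p <- as_param_vec(params)
  list(rp = p[2] * dCp_dt - p[4] * (Ce - Cp) - p[1] * (aif - Cp),
       re = p[3] * dCe_dt - p[4] * (Cp - Ce))
}

#' Reduced-form tissue residual
#'
#' Summing the two 2CXM equations eliminates the exchange term and yields a
#' single conservation law for the tissue concentration,
#' \eqn{\dot C_{myo} = F_p (C_{AIF} - C_p)}; this function evaluates its
#' residual \eqn{r_{myo} = \dot C_{myo} - F_p (C_{AIF} - C_p)}.
#'
#' @param dCmyo_dt time derivative of the tissue concentration, mM/min.
#' @param Cp plasma concentration, mM.
#' @param aif AIF vector, mM.
#' @param params a [kinetic_params] object (or 4-vector).
#' @return Residual vector `rmyo`.
#' @export
residual_reduced <- function(dCmyo_dt, Cp, aif, params) {
  n <- length(dCmyo_dt)
  if (any(c(length(Cp), length(aif)) != n))
    stop("all input vectors must share a length")
  p <- as_param_vec(params)
  dCmyo_dt - p[1] * (aif - Cp)
}

#' Finite-difference time derivative
#'
#' Central differences at interior points, one-sided at the boundaries.
#' Used for residual checks outside the network (inside the PINN,
#' derivatives come from the forward-mode tangent pass).
#'
#' @param y values on the grid.
#' @param t time grid, minutes.
#' @return Vector of derivative estimates.
#' @export
fd_derivative <- function(y, t) {
  n <- length(y)
  if (length(t) != n || n < 3) stop("need at least three points")
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  d
}

#' Convert plasma quantities to blood quantities
#'
#' Plasma flow and plasma volume refer to the plasma fraction of blood;
#' dividing by `1 - hct` rescales them to whole blood, and dividing by the
#' myocardial specific density converts from per-ml tissue to per-g tissue,
#' giving myocardial blood flow `Fb` in ml/min/g and blood volume `vb`.
#'
#' @param params a [kinetic_params] object (or 4-vector).
#' @param hct haematocrit, in \[0, 1); default 0.45.
#' @param density myocardial specific density, g/ml; default 1.05.
#' @return List with `Fb` (ml/min/g) and `vb`.
#' @examples
#' plasma_to_blood(kinetic_params(1, 0.05, 0.2, 1.5))
#' @export
plasma_to_blood <- function(params, hct = 0.45, density = 1.05) {
  if (!is.finite(hct) || hct < 0 || hct >= 1)
    stop("hct must lie in [0, 1)")
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  p <- as_param_vec(params)
  list(Fb = p[1] / (1 - hct) / density, vb = p[2] / (1 - hct) / density)
}
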