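#' Kinetic rate constants of one aggregation condition
#'
#' Bundles the physical constants of the two-step autocatalytic scheme:
#' slow first-order nucleation (rate constant `kn`) followed by fast
#' second-order, aggregate-catalysed elongation (rate constant `ke`), at
#' initial monomer concentration `a`.
#'
#' @param kn Nucleation rate constant, s^-1. Must be > 0.
#' @param ke Elongation rate constant, L mol^-1 s^-1. Must be > 0.
#' @param a Initial monomer concentration, mol L^-1. Must be > 0.
#'
#' @return An object of class `kinetic_rates` (named list with `kn`, `ke`, `a`).
#' @seealso [reduce_rates()], [expand_params()]
#' @export
#' @examples
#' kinetic_rates(kn = 3.73e-6, ke = 3.378, a = 80e-6)
kinetic_rates <- function(kn, ke, a) {
  stopifnot(is.numeric(kn), is.numeric(ke), is.numeric(a),
            length(kn) == 1L, length(ke) == 1L, length(a) == 1L)
  if (!is.finite(kn) || kn <= 0) stop("'kn' must be a finite positive number")
  if (!is.finite(ke) || ke <= 0) stop("'ke' must be a finite positive number")
  if (!is.finite(a) || a <= 0) stop("'a' must be a finite positive number")
  structure(list(kn = kn, ke = ke, a = a), class = "kinetic_rates")
}

#' Reduced model parameterization
#'
#' The closed-form solution depends on the rates only through the combined
#' timescale `k = ke * a` (s^-1) and the dimensionless nucleation-to-growth
#' ratio `rho = kn / k`. Small `rho` produces a pronounced lag phase.
#'
#' @param k Combined rate `ke * a`, s^-1. Must be > 0.
#' @param rho Dimensionless ratio `kn / (ke * a)`. Must be > 0.
#'
#' @return An object of class `reduced_params`.
#' @export
reduced_params <- function(k, rho) {
  stopifnot(is.numeric(k), is.numeric(rho), length(k) == 1L, length(rho) == 1L)
  if (!is.finite(k) || k <= 0) stop("'k' must be a finite positive number")
  if (!is.finite(rho) || rho <= 0) stop("'rho' must be a finite positive number")
  structure(list(k = k, rho = rho), class = "reduced_params")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat(sprintf("kinetic rates: kn = %.4g /s, ke = %.4g L/mol/s, a = %.4g mol/L\n",
              x$kn, x$ke, x$a))
  invisible(x)
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf("reduced params: k = %.4g /s, rho = %.4g\n", x$k, x$rho))
  invisible(x)
}

#' Convert physical rate constants to the reduced parameterization
#'
#' Computes `k = ke * a` and `rho = kn / (ke * a)`.
#'
#' @param rates A [kinetic_rates()] object.
#' @return A [reduced_params()] object.
#' @export
#' @examples
#' reduce_rates(kinetic_rates(3.73e-6, 3.378, 80e-6))
reduce_rates <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  k <- rates$ke * rates$a
  reduced_params(k = k, rho = rates$kn / k)
}

#' Recover physical rate constants from the reduced parameterization
#'
#' Inverse of [reduce_rates()] at a given monomer concentration:
#' `ke = k / a`, `kn = rho * k`.
#'
#' @param params A [reduced_params()] object.
#' @param a Initial monomer concentration, mol L^-1. Must be > 0.
#' @return A [kinetic_rates()] object.
#' @export
expand_params <- function(params, a) {
  stopifnot(inherits(params, "reduced_params"), is.numeric(a), length(a) == 1L)
  if (!is.finite(a) || a <= 0) stop("'a' must be a finite positive number")
  kinetic_rates(kn = params$rho * params$k, ke = params$k / a, a = a)
}

#' Closed-form fibril fraction of the autocatalytic model
#'
#' Evaluates the sigmoidal solution of `df/dt = k (1 - f) (rho + f)` with
#' `f(0) = 0`:
#' \deqn{f(t) = \frac{\rho\,(e^{(1+\rho)kt} - 1)}{1 + \rho\,e^{(1+\rho)kt}}}
#' computed through the algebraically equivalent decaying form
#' `f = rho (1 - E) / (E + rho)` with `E = exp(-(1+rho) k t)`, which cannot
#' overflow for large exponents and saturates cleanly at 1.
#'
#' @param params A [reduced_params()] object.
#' @param t Time(s) in seconds, each >= 0. Vectorized.
#' @return Fibril fraction(s) in `[0, 1)`, same length as `t`.
#' @export
#' @examples
#' p <- reduced_params(k = 1e-4, rho = 0.02)
#' fibril_fraction(p, c(0, 3600, 7200, 3600 * 24))
fibril_fraction <- function(params, t) {
  stopifnot(inherits(params, "reduced_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be finite and >= 0")
  E <- exp(-(1 + params$rho) * params$k * t)
  params$rho * (1 - E) / (E + params$rho)
}

#' Numerically integrated fibril fraction (independent oracle)
#'
#' Integrates the rate law `df/dt = k (1 - f) (rho + f)`, `f(0) = 0`, with
#' an adaptive stiff/non-stiff solver. Serves as an independent check on
#' [fibril_fraction()]: both are representations of the same two-step
#' scheme, one analytic and one numeric.
#'
#' @param params A [reduced_params()] object.
#' @param times Increasing times in seconds, each >= 0.
#' @param rel_tol Relative integration tolerance, in `(0, 1e-3]`.
#' @return A [fraction_curve()] with fractions at `times`.
#' @export
ode_oracle <- function(params, times, rel_tol = 1e-8) {
  stopifnot(inherits(params, "reduced_params"), is.numeric(times))
  if (length(times) < 1L || any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing and >= 0")
  if (!is.numeric(rel_tol) || rel_tol <= 0 || rel_tol > 1e-3)
    stop("'rel_tol' must be in (0, 1e-3]")
  if (length(times) == 1L && times[1] == 0)
    return(fraction_curve(times = 0, fractions = 0))
  # deSolve requires the initial time in the grid; prepend 0 if absent
  grid <- if (times[1] > 0) c(0, times) else times
  rhs <- function(t, y, parms) {
    list(parms$k * (1 - y[1]) * (parms$rho + y[1]))
  }
  sol <- deSolve::ode(y = c(f = 0), times = grid, func = rhs,
                      parms = params, method = "lsoda",
                      rtol = rel_tol, atol = rel_tol * 1e-2)
  diagn <- attr(sol, "istate")
  if (is.null(diagn) || diagn[1] < 0 || nrow(sol) < length(grid))
    stop("ODE integration failed (solver did not reach all requested times)")
  f <- sol[, "f"]
  if (times[1] > 0) f <- f[-1]
  fraction_curve(times = times, fractions = pmin(pmax(f, 0), 1))
}

#' Half time of aggregation
#'
#' Time at which the fibril fraction reaches 1/2, from inverting the
#' closed form: `t50 = ln((1 + 2 rho) / rho) / ((1 + rho) k)`.
#'
#' @param params A [reduced_params()] object.
#' @return Half time in seconds.
#' @export
half_time <- function(params) {
  stopifnot(inherits(params, "reduced_params"))
  log((1 + 2 * params$rho) / params$rho) / ((1 + params$rho) * params$k)
}

#' Lag time by the tangent-at-inflection construction
#'
#' The slope `df/dt = k (1 - f) (rho + f)` is maximal at the inflection
#' fraction `f* = (1 - rho) / 2`, reached at `t* = -ln(rho) / ((1+rho) k)`.
#' The lag time is the intercept of the inflection tangent with f = 0:
#' `tlag = t* - f* / f'(t*)`. An interior inflection exists only for
#' `rho < 1`; for `rho >= 1` the curve is concave from t = 0 and the lag
#' time is undefined (`NA` is returned). A negative intercept (large rho)
#' is clamped to 0.
#'
#' @param params A [reduced_params()] object.
#' @return Lag time in seconds, or `NA_real_` when `rho >= 1`.
#' @export
lag_time <- function(params) {
  stopifnot(inherits(params, "reduced_params"))
  rho <- params$rho
  k <- params$k
  if (rho >= 1) return(NA_real_)
  t_infl <- -log(rho) / ((1 + rho) * k)
  f_infl <- (1 - rho) / 2
  slope <- k * (1 + rho)^2 / 4
  max(0, t_infl - f_infl / slope)
}

#' Dimensionless fibril-fraction curve
#'
#' @param times Times in seconds, strictly increasing, each >= 0.
#' @param fractions Fibril fractions, each in `[0, 1]`, same length as `times`.
#' @return An object of class `fraction_curve` (data.frame with columns
#'   `time_s`, `fraction`).
#' @export
fraction_curve <- function(times, fractions) {
  stopifnot(is.numeric(times), is.numeric(fractions))
  if (length(times) != length(fractions))
    stop("'times' and 'fractions' must have equal length")
  if (length(times) < 1L) stop("curve must contain at least one point")
  if (any(times < 0) || (length(times) > 1L && is.unsorted(times, strictly = TRUE)))
    stop("'times' must be strictly increasing and >= 0")
  if (any(fractions < 0 | fractions > 1))
    stop("'fractions' must lie in [0, 1]")
  structure(data.frame(time_s = as.numeric(times), fraction = as.numeric(fractions)),
            class = c("fraction_curve", "data.frame"))
}

#' ThT fluorescence time course
#'
#' One observed intensity-versus-time series for a single condition and
#' replicate. Intensities are in arbitrary fluorimeter units (483 nm
#' emission of bound thioflavin T, proxying fibril content).
#'
#' @param times Times in seconds, strictly increasing, each >= 0.
#' @param intensities Fluorescence intensities, each >= 0.
#' @param condition Condition label (e.g. `"alone"`, `"Chol"`).
#' @param replicate Replicate identifier, or `"mean"` for an averaged series.
#' @return An object of class `tht_timecourse` (data.frame with columns
#'   `time_s`, `intensity` and attributes `condition`, `replicate`).
#' @export
tht_timecourse <- function(times, intensities, condition = "unspecified",
                           replicate = "mean") {
  stopifnot(is.numeric(times), is.numeric(intensities))
  if (length(times) != length(intensities))
    stop("'times' and 'intensities' must have equal length")
  if (any(times < 0) || (length(times) > 1L && is.unsorted(times, strictly = TRUE)))
    stop("'times' must be strictly increasing and >= 0")
  if (any(intensities < 0)) stop("'intensities' must be >= 0")
  out <- data.frame(time_s = as.numeric(times), intensity = as.numeric(intensities))
  attr(out, "condition") <- as.character(condition)
  attr(out, "replicate") <- as.character(replicate)
  class(out) <- c("tht_timecourse", "data.frame")
  out
}

#' Convert hours to seconds
#' @param h Time(s) in hours.
#' @return Time(s) in seconds.
#' @export
hours_to_seconds <- function(h) as.numeric(h) * 3600
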