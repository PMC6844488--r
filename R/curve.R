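#' Reference stem-cell-fraction curve
#'
#' A sampled stem-cell fraction s(t) on a uniform time grid, together with
#' its first and second time derivatives and (optionally) continuous-time
#' evaluator functions used to obtain values between grid nodes (the
#' implicit inversion scheme needs s, sdot, sddot at half steps).
#'
#' Fractions are canonical on the 0-1 scale; the non-stem fraction is
#' `d(t) = 1 - s(t)`.
#'
#' @param times Strictly increasing uniform time grid.
#' @param s Stem-cell fraction values in \[0, 1\].
#' @param sdot,sddot First and second derivatives on the grid.  If omitted
#'   they are built from an interpolating cubic spline through `s`.
#' @param provenance One of `"parametric"`, `"simulated"`, `"measured"`.
#' @param funs Optional list of functions `s(t)`, `sdot(t)`, `sddot(t)`
#'   evaluating the curve at arbitrary times (analytic for parametric and
#'   simulated curves; spline-based otherwise).
#' @param params Optional list of generator parameters kept as metadata.
#' @return An object of class `reference_curve`.
#' @seealso [make_reference_curve()], [differentiate_sampled_curve()]
#' @export
reference_curve <- function(times, s, sdot = NULL, sddot = NULL,
                            provenance = c("measured", "parametric",
                                           "simulated"),
                            funs = NULL, params = NULL) {
  provenance <- match.arg(provenance)
  check_uniform_grid(times)
  if (length(s) != length(times))
    stop("times and s must have equal length", call. = FALSE)
  if (any(!is.finite(s)) || any(s < -1e-9) || any(s > 1 + 1e-9))
    stop("fractions s must lie in [0, 1]", call. = FALSE)
  s <- pmin(pmax(s, 0), 1)
  if (is.null(funs)) {
    sf <- stats::splinefun(times, s, method = "fmm")
    funs <- list(s = function(t) sf(t),
                 sdot = function(t) sf(t, deriv = 1),
                 sddot = function(t) sf(t, deriv = 2))
  }
  if (is.null(sdot)) sdot <- funs$sdot(times)
  if (is.null(sddot)) sddot <- funs$sddot(times)
  structure(list(times = times, s = s, sdot = sdot, sddot = sddot,
                 provenance = provenance, funs = funs, params = params),
            class = "reference_curve")
}

check_uniform_grid <- function(times, tol = 1e-8) {
  if (length(times) < 2 || any(!is.finite(times)))
    stop("time grid must contain at least 2 finite points", call. = FALSE)
  h <- diff(times)
  if (any(h <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  if ((max(h) - min(h)) > tol * max(abs(h)))
    stop("time grid must be uniform", call. = FALSE)
  invisible(mean(h))
}

#' Evaluate a reference curve (and derivatives) at arbitrary times
#'
#' @param curve A [reference_curve()].
#' @param t Times inside the curve's span.
#' @return A list with components `s`, `sdot`, `sddot` (vectors like `t`).
#' @export
curve_eval <- function(curve, t) {
  stopifnot(inherits(curve, "reference_curve"))
  list(s = curve$funs$s(t),
       sdot = curve$funs$sdot(t),
       sddot = curve$funs$sddot(t))
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf(
    "<reference_curve> %d points on [%g, %g], provenance: %s\n  s: %.4f -> %.4f\n",
    length(x$times), min(x$times), max(x$times), x$provenance,
    x$s[1], x$s[length(x$s)]))
  invisible(x)
}

#' Parametric stabilization curve family
#'
#' Generates the canonical stabilization shape: a monotone exponential
#' relaxation of the stem-cell fraction from `s0` (a sorted, initially pure
#' CSC population has `s0 = 1`) down to a basal plateau `s_eq`,
#' `s(t) = s_eq + (s0 - s_eq) exp(-k t)`.  First and second derivatives are
#' attached analytically, so half-step values used by the inversion scheme
#' are exact.
#'
#' @param s_eq Basal plateau fraction, `0 < s_eq < s0`.
#' @param k Relaxation rate (> 0, per time unit).
#' @param s0 Initial fraction (default 1).
#' @param t_max Duration (default 10 time units).
#' @param n_points Grid size (default 201).
#' @return A [reference_curve()] with provenance `"parametric"`.
#' @examples
#' crv <- make_reference_curve(s_eq = 0.1, k = 1)
#' crv$s[1]                        # 1 at t = 0
#' curve_eval(crv, log(9))$s       # 0.2
#' @export
make_reference_curve <- function(s_eq, k, s0 = 1, t_max = 10,
                                 n_points = 201) {
  if (!is.finite(s_eq) || !is.finite(k) || !is.finite(s0))
    stop("curve family parameters must be finite", call. = FALSE)
  if (k <= 0) stop("relaxation rate k must be > 0", call. = FALSE)
  if (!(s_eq > 0 && s_eq < s0 && s0 <= 1))
    stop("need 0 < s_eq < s0 <= 1", call. = FALSE)
  if (t_max <= 0 || n_points < 2)
    stop("need t_max > 0 and n_points >= 2", call. = FALSE)
  times <- seq(0, t_max, length.out = n_points)
  amp <- s0 - s_eq
  funs <- list(
    s = function(t) s_eq + amp * exp(-k * t),
    sdot = function(t) -k * amp * exp(-k * t),
    sddot = function(t) k^2 * amp * exp(-k * t))
  reference_curve(times, funs$s(times), funs$sdot(times), funs$sddot(times),
                  provenance = "parametric", funs = funs,
                  params = list(s_eq = s_eq, k = k, s0 = s0))
}

#' Derivative estimation for a sampled fraction curve
#'
#' Builds a [reference_curve()] from raw samples, estimating first and
#' second derivatives.  With `smoothing = 0` an interpolating cubic spline
#' (FMM end conditions, exact for polynomial data up to degree 3) is used;
#' otherwise a smoothing spline is fitted, with the smoothing level chosen
#' by generalized cross-validation when `smoothing = NULL` (the default) or
#' set directly via `spar` when `smoothing > 0`.  Smoothing matters because
#' the inversion needs the noise-amplifying second derivative.
#'
#' @param times Uniform, strictly increasing time grid (>= 7 points).
#' @param s_values Sampled fractions in \[0, 1\].
#' @param smoothing `NULL` (GCV), `0` (exact interpolation) or a positive
#'   `spar` value passed to [stats::smooth.spline()].
#' @return A [reference_curve()] with provenance `"measured"`.
#' @export
differentiate_sampled_curve <- function(times, s_values, smoothing = NULL) {
  if (length(times) < 7)
    stop("need at least 7 samples to estimate derivatives", call. = FALSE)
  check_uniform_grid(times)
  if (length(s_values) != length(times))
    stop("times and s_values must have equal length", call. = FALSE)
  if (!is.null(smoothing) && smoothing == 0) {
    sf <- stats::splinefun(times, s_values, method = "fmm")
    funs <- list(s = function(t) sf(t),
                 sdot = function(t) sf(t, deriv = 1),
                 sddot = function(t) sf(t, deriv = 2))
  } else {
    fit <- if (is.null(smoothing)) {
      stats::smooth.spline(times, s_values, cv = FALSE)
    } else {
      if (smoothing < 0) stop("smoothing must be >= 0", call. = FALSE)
      stats::smooth.spline(times, s_values, spar = smoothing)
    }
    funs <- list(
      s = function(t) stats::predict(fit, t)$y,
      sdot = function(t) stats::predict(fit, t, deriv = 1)$y,
      sddot = function(t) stats::predict(fit, t, deriv = 2)$y)
  }
  reference_curve(times, pmin(pmax(funs$s(times), 0), 1),
                  funs$sdot(times), funs$sddot(times),
                  provenance = "measured", funs = funs,
                  params = list(smoothing = smoothing))
}

#' Constant reference curve
#'
#' Convenience constructor for a curve frozen at a single fraction, with
#' identically zero derivatives.  Useful as the degenerate fixture in which
#' the minimal-change principle forces all probabilities to stay constant.
#'
#' @param s Constant fraction in (0, 1\].
#' @inheritParams make_reference_curve
#' @return A [reference_curve()] with provenance `"parametric"`.
#' @export
constant_reference_curve <- function(s, t_max = 10, n_points = 201) {
  if (s <= 0 || s > 1) stop("need 0 < s <= 1", call. = FALSE)
  times <- seq(0, t_max, length.out = n_points)
  funs <- list(s = function(t) rep(s, length(t)),
               sdot = function(t) rep(0, length(t)),
               sddot = function(t) rep(0, length(t)))
  reference_curve(times, rep(s, n_points), rep(0, n_points),
                  rep(0, n_points), provenance = "parametric", funs = funs,
                  params = list(constant = s))
}
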