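#' Division coefficients of the two-compartment population system
#'
#' Converts one set of scenario probabilities and rates into the four
#' coefficients of the linear S/D system
#' `dS/dt = alphaS * S + betaD * D`, `dD/dt = betaS * S + alphaD * D`:
#' `alphaS = (p1 + 2 p3 - 1) lambda1 - gamma1`, `betaD = q2 lambda2`,
#' `betaS = (p1 + 2 p2 + p4) lambda1`, `alphaD = q1 lambda2 - gamma2`.
#'
#' @param probs A [probability_state()].
#' @param rates A [rate_params()].
#' @return Named numeric vector `c(alphaS, betaD, betaS, alphaD)`.
#' @examples
#' division_coefficients(
#'   probability_state(0, 0, 1, 0, 1, 0), rate_params(1, 1))
#' @export
division_coefficients <- function(probs, rates) {
  stopifnot(inherits(probs, "probability_state"),
            inherits(rates, "rate_params"))
  c(alphaS = (probs[["p1"]] + 2 * probs[["p3"]] - 1) * rates$lambda1 -
      rates$gamma1,
    betaD = probs[["q2"]] * rates$lambda2,
    betaS = (probs[["p1"]] + 2 * probs[["p2"]] + probs[["p4"]]) *
      rates$lambda1,
    alphaD = probs[["q1"]] * rates$lambda2 - rates$gamma2)
}

#' Forward simulation of stem / non-stem cell abundances
#'
#' Integrates the two-compartment linear (for a constant schedule) or
#' piecewise-linear system with the classic fixed-step 4th-order
#' Runge-Kutta method.  Abundances are continuous and scale-free: only the
#' fraction s(t) matters downstream.
#'
#' @param rates A [rate_params()].
#' @param schedule Either a [probability_state()] (held constant) or a
#'   function of time returning one.
#' @param S0,D0 Initial abundances (`S0 + D0 > 0`); the canonical sorted
#'   pure-CSC experiment has `D0 = 0`.
#' @param t_max Duration (> 0).
#' @param dt Time step (> 0).
#' @return A data frame of class `population_trajectory` with columns
#'   `time`, `S`, `D` and attributes `rates`, `schedule`.
#' @examples
#' tr <- simulate_population(rate_params(1, 5, 0.1, 0.1),
#'   probability_state(0.5, 0.1, 0.3, 0.1, 0.9, 0.1), t_max = 5)
#' head(tr)
#' @export
simulate_population <- function(rates, schedule, S0 = 1, D0 = 0,
                                t_max = 10, dt = 0.05) {
  stopifnot(inherits(rates, "rate_params"))
  if (S0 < 0 || D0 < 0 || S0 + D0 <= 0)
    stop("need S0 >= 0, D0 >= 0 and S0 + D0 > 0", call. = FALSE)
  if (dt <= 0 || t_max < dt)
    stop("need dt > 0 and t_max >= dt", call. = FALSE)
  probs_at <- if (is.function(schedule)) schedule else function(t) schedule
  deriv <- function(t, y, parms) {
    co <- division_coefficients(probs_at(t), rates)
    list(c(co[["alphaS"]] * y[1] + co[["betaD"]] * y[2],
           co[["betaS"]] * y[1] + co[["alphaD"]] * y[2]))
  }
  times <- seq(0, t_max, by = dt)
  sol <- deSolve::ode(c(S = S0, D = D0), times, deriv, parms = NULL,
                      method = "rk4")
  out <- as.data.frame(sol)
  scale <- max(abs(out$S), abs(out$D), 1e-300)
  if (min(out$S) < -1e-9 * scale || min(out$D) < -1e-9 * scale)
    stop("integration produced negative abundances; ",
         "check parameters and step size", call. = FALSE)
  out$S <- pmax(out$S, 0)
  out$D <- pmax(out$D, 0)
  structure(out, rates = rates, schedule = schedule,
            class = c("population_trajectory", "data.frame"))
}

#' Stem-cell fraction of a simulated trajectory
#'
#' Computes `s(t) = S / (S + D)` on the trajectory grid and returns it as a
#' [reference_curve()] (provenance `"simulated"`) whose derivatives come
#' from an interpolating spline of s.
#'
#' @param traj A `population_trajectory` from [simulate_population()].
#' @return A [reference_curve()].
#' @export
stem_fraction <- function(traj) {
  stopifnot(inherits(traj, "population_trajectory"))
  tot <- traj$S + traj$D
  if (any(tot <= 0))
    stop("degenerate population: S + D must stay positive", call. = FALSE)
  reference_curve(traj$time, traj$S / tot, provenance = "simulated")
}

ss_coefficients <- function(probs, rates) {
  # quadratic c0 + c1 s + c2 s^2 equal to the fraction velocity sdot
  p2 <- probs[["p2"]]; p3 <- probs[["p3"]]; p4 <- probs[["p4"]]
  q2 <- probs[["q2"]]
  c(c0 = q2 * rates$lambda2,
    c1 = (p3 - p2 - p4) * rates$lambda1 - (1 + q2) * rates$lambda2 +
      rates$gamma2 - rates$gamma1,
    c2 = rates$lambda2 - (1 - p4) * rates$lambda1 - rates$gamma2 +
      rates$gamma1)
}

#' Steady-state stem-cell fractions
#'
#' Real roots in \[0, 1\] of the fraction-velocity quadratic
#' `q2 l2 + ((p3-p2-p4) l1 - (1+q2) l2 + g2 - g1) s +
#' (l2 - (1-p4) l1 - g2 + g1) s^2 = 0` for a constant scenario schedule.
#' Degenerate (linear / constant) cases are handled; when every coefficient
#' vanishes any fraction is stationary and the `any_s` sentinel is set.
#'
#' @param probs A [probability_state()].
#' @param rates A [rate_params()].
#' @param tol Numeric tolerance for degeneracy and the \[0, 1\] filter.
#' @return A list with `roots` (sorted fractions in \[0, 1\], possibly
#'   empty) and logical `any_s`.
#' @examples
#' steady_state_fractions(
#'   probability_state(0.5, 0.1, 0.3, 0.1, 0.9, 0.1),
#'   rate_params(1, 5, 0.1, 0.1))
#' @export
steady_state_fractions <- function(probs, rates, tol = 1e-12) {
  stopifnot(inherits(probs, "probability_state"),
            inherits(rates, "rate_params"))
  co <- ss_coefficients(probs, rates)
  scale <- max(abs(co), rates$lambda1, rates$lambda2)
  c0 <- co[["c0"]]; c1 <- co[["c1"]]; c2 <- co[["c2"]]
  keep_unit <- function(r) {
    r <- r[is.finite(r) & r >= -1e-9 & r <= 1 + 1e-9]
    sort(unique(pmin(pmax(r, 0), 1)))
  }
  if (abs(c2) <= tol * scale) {
    if (abs(c1) <= tol * scale) {
      if (abs(c0) <= tol * scale)
        return(list(roots = numeric(0), any_s = TRUE))
      return(list(roots = numeric(0), any_s = FALSE))
    }
    return(list(roots = keep_unit(-c0 / c1), any_s = FALSE))
  }
  disc <- c1^2 - 4 * c0 * c2
  if (disc < 0) return(list(roots = numeric(0), any_s = FALSE))
  # numerically stable quadratic roots
  q <- -(c1 + sign(c1 + (c1 == 0)) * sqrt(disc)) / 2
  r <- if (abs(q) > 0) c(q / c2, c0 / q) else c(0, -c1 / c2)
  list(roots = keep_unit(r), any_s = FALSE)
}

#' Write a population trajectory to CSV
#'
#' Columns `time,S,D,s` with the fraction on the 0-1 scale.
#'
#' @param traj A `population_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "population_trajectory"))
  df <- data.frame(time = traj$time, S = traj$S, D = traj$D,
                   s = traj$S / (traj$S + traj$D))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
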