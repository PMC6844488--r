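#' Probability channels assembled from known field factors
#'
#' Evaluates the factor decomposition
#' `y_i(t) = sum_k b_ik exp(-a_k (t - c_k)^m)` for all six probability
#' channels on a time grid.  Used to build ground-truth fixtures for the
#' decomposition stage; an attribute `valid` records whether every channel
#' stays inside \[0, 1\] (fixtures meant to be probability trajectories
#' must be constructed inside the unit interval).
#'
#' @param fset A [factor_set()] (or list of [field_factor()]).
#' @param times Evaluation grid.
#' @return A numeric matrix `length(times) x 6` with columns
#'   `p1, p2, p3, p4, q1, q2` and attribute `valid`.
#' @export
make_probability_curves_from_factors <- function(fset, times) {
  factors <- if (inherits(fset, "factor_set")) fset$factors else fset
  y <- matrix(0, length(times), 6,
              dimnames = list(NULL, prob_channels))
  for (fc in factors) {
    e <- bump_basis(times, fc$a, fc$c, fc$m)
    y <- y + outer(e, fc$b_weights)
  }
  attr(y, "valid") <- all(y >= -1e-12 & y <= 1 + 1e-12)
  y
}

#' Forward-simulated curve with known constant ground truth
#'
#' Closed-loop fixture generator: solves the two-compartment system in
#' closed form (eigen-decomposition of the constant-coefficient 2x2 matrix)
#' for one constant [probability_state()], and returns the stem-fraction
#' curve together with the generating probabilities.  The curve carries
#' analytic evaluators: s(t) from the closed form, sdot from the fraction
#' velocity quadratic and sddot from its chain-rule time derivative, so
#' half-step values used by the inversion are exact.
#'
#' @param rates A [rate_params()].
#' @param probs A [probability_state()] held constant.
#' @param t_max Duration.
#' @param n_points Grid size.
#' @param S0,D0 Initial abundances.
#' @return A list with components `curve` (a [reference_curve()],
#'   provenance `"simulated"`) and `probs` (the ground truth).
#' @examples
#' gt <- make_ground_truth_bundle(rate_params(1, 5, 0.1, 0.1),
#'   probability_state(0.55, 0.05, 0.3, 0.1, 0.8, 0.2), t_max = 10)
#' gt$curve
#' @export
make_ground_truth_bundle <- function(rates, probs, t_max = 10,
                                     n_points = 201, S0 = 1, D0 = 0) {
  stopifnot(inherits(rates, "rate_params"),
            inherits(probs, "probability_state"))
  if (S0 < 0 || D0 < 0 || S0 + D0 <= 0)
    stop("need S0 >= 0, D0 >= 0 and S0 + D0 > 0", call. = FALSE)
  co <- division_coefficients(probs, rates)
  A <- matrix(c(co[["alphaS"]], co[["betaS"]],
                co[["betaD"]], co[["alphaD"]]), 2, 2)
  eg <- eigen(A)
  if (is.complex(eg$values) || abs(eg$values[1] - eg$values[2]) < 1e-12 ||
      abs(det(eg$vectors)) < 1e-12) {
    # defective / oscillatory corner: fall back to numerical integration
    traj <- simulate_population(rates, probs, S0, D0, t_max,
                                dt = t_max / (20 * (n_points - 1)))
    curve <- stem_fraction(traj)
    times <- seq(0, t_max, length.out = n_points)
    sv <- curve$funs$s(times)
    crv <- reference_curve(times, sv, provenance = "simulated",
                           funs = curve$funs)
    return(list(curve = crv, probs = probs))
  }
  w <- solve(eg$vectors, c(S0, D0))
  sd_co <- ss_coefficients(probs, rates)
  s_fun <- function(t) {
    m1 <- exp(eg$values[1] * t) * w[1]
    m2 <- exp(eg$values[2] * t) * w[2]
    S <- eg$vectors[1, 1] * m1 + eg$vectors[1, 2] * m2
    D <- eg$vectors[2, 1] * m1 + eg$vectors[2, 2] * m2
    S / (S + D)
  }
  sdot_fun <- function(t) {
    s <- s_fun(t)
    sd_co[["c0"]] + sd_co[["c1"]] * s + sd_co[["c2"]] * s^2
  }
  sddot_fun <- function(t) {
    s <- s_fun(t)
    (sd_co[["c1"]] + 2 * sd_co[["c2"]] * s) * sdot_fun(t)
  }
  times <- seq(0, t_max, length.out = n_points)
  funs <- list(s = s_fun, sdot = sdot_fun, sddot = sddot_fun)
  curve <- reference_curve(times, s_fun(times), sdot_fun(times),
                           sddot_fun(times), provenance = "simulated",
                           funs = funs,
                           params = list(rates = rates, probs = probs,
                                         S0 = S0, D0 = D0))
  list(curve = curve, probs = probs)
}
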