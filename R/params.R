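#' Division, transition and death rates of the two cell compartments
#'
#' Bundles the four constant kinetic rates of the two-compartment model:
#' stem (S) cells divide or transition with rate `lambda1` and die with rate
#' `gamma1`; non-stem daughter (D) cells divide with rate `lambda2` and die
#' with rate `gamma2`.  All rates are per unit time (documented default unit:
#' days, matching a typical 10-day stabilization window); they are held
#' constant over the stabilization period.
#'
#' @param lambda1 Division/transition rate of S cells (> 0).
#' @param lambda2 Division rate of D cells (> 0).
#' @param gamma1 Death rate of S cells (>= 0).
#' @param gamma2 Death rate of D cells (>= 0).
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(1, 5, 0.1, 0.1)
#' @export
rate_params <- function(lambda1, lambda2, gamma1 = 0, gamma2 = 0) {
  vals <- c(lambda1 = lambda1, lambda2 = lambda2,
            gamma1 = gamma1, gamma2 = gamma2)
  if (!all(is.finite(vals)))
    stop("all rates must be finite numbers", call. = FALSE)
  if (lambda1 <= 0 || lambda2 <= 0)
    stop("division rates lambda1 and lambda2 must be > 0", call. = FALSE)
  if (gamma1 < 0 || gamma2 < 0)
    stop("death rates gamma1 and gamma2 must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf(
    "<rate_params> lambda1 = %g, lambda2 = %g, gamma1 = %g, gamma2 = %g\n",
    x$lambda1, x$lambda2, x$gamma1, x$gamma2))
  invisible(x)
}

#' Scenario probabilities of stem and non-stem cell behavior
#'
#' The six cell-fate scenario probabilities at one instant: for a stem cell,
#' `p1` (asymmetric division S -> S+D), `p2` (symmetric differentiating
#' division S -> D+D), `p3` (symmetric renewal S -> S+S) and `p4` (direct
#' differentiation S -> D); for a daughter cell, `q1` (symmetric division
#' D -> D+D) and `q2` (dedifferentiating asymmetric division D -> S+D).
#' The remaining theoretically possible daughter scenarios (D -> S+S,
#' D -> S) are fixed at probability zero in this model.
#'
#' Each component must lie in \[0, 1\]; `p1+p2+p3+p4 = 1` and `q1+q2 = 1`
#' within `tol`.
#'
#' @param p1,p2,p3,p4 S-cell scenario probabilities.
#' @param q1,q2 D-cell scenario probabilities.
#' @param tol Tolerance on the simplex sums (default `1e-12`).
#' @return An object of class `probability_state` (named numeric vector).
#' @examples
#' probability_state(0.55, 0.05, 0.3, 0.1, 0.8, 0.2)
#' @export
probability_state <- function(p1, p2, p3, p4, q1, q2, tol = 1e-12) {
  x <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4, q1 = q1, q2 = q2)
  if (!all(is.finite(x)))
    stop("probabilities must be finite", call. = FALSE)
  if (any(x < -tol) || any(x > 1 + tol))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(p1 + p2 + p3 + p4 - 1) > tol)
    stop("p1 + p2 + p3 + p4 must equal 1", call. = FALSE)
  if (abs(q1 + q2 - 1) > tol)
    stop("q1 + q2 must equal 1", call. = FALSE)
  structure(pmin(pmax(x, 0), 1), class = "probability_state")
}

#' @export
print.probability_state <- function(x, ...) {
  cat("<probability_state>\n")
  print(round(unclass(x), 6))
  invisible(x)
}

prob_channels <- c("p1", "p2", "p3", "p4", "q1", "q2")
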