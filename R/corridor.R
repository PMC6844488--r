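#' Closure of the probability simplex given the fraction curve
#'
#' Given the three free probabilities (p1, p2, q2) and the curve values
#' (s, sdot) at one instant, the remaining probabilities follow from the
#' fraction-velocity identity and the two simplex constraints:
#' `p3 = (sdot - l2 q2 + (g1 - g2 + l1 + l2 - l1 p1 + l2 q2 +
#' (g2 - g1 - l2 + l1 (p1 + p2)) s) s) / (l1 s (2 - s))`,
#' `p4 = 1 - p1 - p2 - p3`, `q1 = 1 - q2`.  Substituting the closed state
#' back into the fraction-velocity quadratic reproduces `sdot` exactly (an
#' algebraic identity of the closure).
#'
#' All arguments are vectorized.
#'
#' @param p1,p2,q2 Free probabilities.
#' @param s,sdot Fraction and its derivative; `s` must satisfy
#'   `0 < s < 2 - tol` (`s = 1` is legal; the closure is singular at
#'   `s = 0`).
#' @param rates A [rate_params()].
#' @param tol Singularity guard tolerance.
#' @return List with vectors `p3`, `p4`, `q1`.
#' @export
close_probabilities <- function(p1, p2, q2, s, sdot, rates, tol = 1e-12) {
  stopifnot(inherits(rates, "rate_params"))
  if (any(s <= tol) || any(s >= 2 - tol))
    stop("singular closure: need 0 < s < 2", call. = FALSE)
  l1 <- rates$lambda1; l2 <- rates$lambda2
  g1 <- rates$gamma1; g2 <- rates$gamma2
  p3 <- (sdot - l2 * q2 +
           (g1 - g2 + l1 + l2 - l1 * p1 + l2 * q2 +
              (g2 - g1 - l2 + l1 * (p1 + p2)) * s) * s) /
    (l1 * s * (2 - s))
  list(p3 = p3, p4 = 1 - p1 - p2 - p3, q1 = 1 - q2)
}

# affine decomposition of the minimal-change right-hand sides:
# each of the three derivatives is channel_multiplier * Phi where
# Phi = Phi0 + gp1 p1 + gp2 p2 + gq2 q2 (affine in the free probabilities).
mc_affine <- function(s, sdot, sddot, rates) {
  l1 <- rates$lambda1; l2 <- rates$lambda2
  g1 <- rates$gamma1; g2 <- rates$gamma2
  A2 <- 2 + (s - 2) * s
  E <- g2 - g1 + l1 - l2
  den <- (s - 2) * (4 * l2^2 * (1 - s)^2 +
                      2 * l1^2 * s^2 * (11 + 3 * s * (s - 2)))
  list(
    phi0 = -2 * sdot^2 + s * (s * (E * sdot - sddot) +
                                2 * (sdot^2 + sddot)),
    gp1 = l1 * s^2 * sdot,
    gp2 = 2 * l1 * s^2 * sdot,
    gq2 = l2 * A2 * sdot,
    c1 = 2 * l1 * (s - 1) / den,
    c2 = 2 * l1 * (s + 3) / den,
    c3 = 4 * l2 * (s - 1) / (s * den),
    den = den)
}

#' Minimal-change right-hand sides for the free probabilities
#'
#' Time derivatives of (p1, p2, q2) under the minimal-change principle:
#' among all probability evolutions consistent with the observed fraction
#' curve, the one minimizing the summed squared probability derivatives.
#' The three right-hand sides share one affine numerator factor which
#' vanishes when `sdot = sddot = 0` (no change required, none made) and
#' carry a factor `(s - 1)` on the p1 and q2 channels.
#'
#' Vectorized over all arguments.
#'
#' @inheritParams close_probabilities
#' @param sddot Second derivative of the fraction.
#' @return List with vectors `dp1dt`, `dp2dt`, `dq2dt`.
#' @export
minimal_change_rhs <- function(p1, p2, q2, s, sdot, sddot, rates,
                               tol = 1e-12) {
  stopifnot(inherits(rates, "rate_params"))
  if (any(s <= tol))
    stop("singular right-hand side: need s > 0", call. = FALSE)
  af <- mc_affine(s, sdot, sddot, rates)
  if (any(abs(af$den) <= tol))
    stop("singular right-hand side: zero denominator", call. = FALSE)
  phi <- af$phi0 + af$gp1 * p1 + af$gp2 * p2 + af$gq2 * q2
  list(dp1dt = af$c1 * phi, dp2dt = af$c2 * phi, dq2dt = af$c3 * phi)
}

mc_grid <- function(curve, dt) {
  t_max <- max(curve$times)
  n <- max(1L, round(t_max / dt))
  dt <- t_max / n
  times <- seq(0, t_max, length.out = n + 1)
  nodes <- curve_eval(curve, times)
  halves <- curve_eval(curve, times[-length(times)] + dt / 2)
  if (any(nodes$s <= 0) || any(halves$s <= 0))
    stop("singular closure along the curve: s must stay positive",
         call. = FALSE)
  list(times = times, dt = dt, n = n, nodes = nodes, halves = halves)
}

# one implicit midpoint step for a 3 x M state matrix X = (p1; p2; q2).
# The update equations are linear in the new state through the half-step
# averages, so the step is one exact 3x3 linear solve shared by all
# columns (the matrix depends only on curve values and rates).
mc_step <- function(X, af_h, dt) {
  C <- c(af_h$c1, af_h$c2, af_h$c3)
  g <- c(af_h$gp1, af_h$gp2, af_h$gq2)
  A <- diag(3) - (dt / 2) * tcrossprod(C, g)
  gx <- drop(crossprod(g, X))
  rhs <- X + outer(dt * C, af_h$phi0 + gx / 2)
  solve(A, rhs)
}

six_rows <- function(X, cl) {
  rbind(p1 = X[1, ], p2 = X[2, ], p3 = cl$p3, p4 = cl$p4,
        q1 = cl$q1, q2 = X[3, ])
}

#' Integrate the minimal-change scheme for one initial triple
#'
#' Advances the free probabilities (p1, p2, q2) with the implicit
#' second-order midpoint scheme (half-step averages of the unknowns; curve
#' values taken at half steps), then closes p3, p4, q1 at each node from
#' [close_probabilities()], so the two simplex sums hold exactly at every
#' step by construction.  Integration stops at the first step where any of
#' the six probabilities leaves \[0 - slack, 1 + slack\]; the returned
#' trajectory is then flagged infeasible with the violating step index.
#'
#' @param triple Numeric `c(p10, p20, q20)` initial free probabilities.
#' @param curve A [reference_curve()].
#' @param rates A [rate_params()].
#' @param dt Time step (default `1e-3`); coerced so that an integer number
#'   of steps spans the curve.
#' @param slack Feasibility slack absorbing roundoff at the 0/1 boundary.
#' @return A data frame of class `probability_trajectory` with columns
#'   `time, p1, p2, p3, p4, q1, q2` and attributes `triple`, `feasible`,
#'   `violation_index` (NA when feasible).
#' @export
integrate_scheme <- function(triple, curve, rates, dt = 1e-3,
                             slack = 1e-9) {
  stopifnot(inherits(curve, "reference_curve"),
            inherits(rates, "rate_params"), length(triple) == 3)
  gr <- mc_grid(curve, dt)
  X <- matrix(triple, 3, 1)
  states <- matrix(NA_real_, 6, gr$n + 1,
                   dimnames = list(prob_channels, NULL))
  feasible <- TRUE
  violation <- NA_integer_
  cl <- close_probabilities(X[1, ], X[2, ], X[3, ],
                            gr$nodes$s[1], gr$nodes$sdot[1], rates)
  states[, 1] <- six_rows(X, cl)
  if (any(states[, 1] < -slack | states[, 1] > 1 + slack)) {
    feasible <- FALSE
    violation <- 0L
  } else {
    for (n in seq_len(gr$n)) {
      af_h <- mc_affine(gr$halves$s[n], gr$halves$sdot[n],
                        gr$halves$sddot[n], rates)
      if (!all(is.finite(c(af_h$c1, af_h$c2, af_h$c3))))
        stop(sprintf("singular scheme denominator at t = %g",
                     gr$times[n] + gr$dt / 2), call. = FALSE)
      X <- mc_step(X, af_h, gr$dt)
      cl <- close_probabilities(X[1, ], X[2, ], X[3, ],
                                gr$nodes$s[n + 1], gr$nodes$sdot[n + 1],
                                rates)
      states[, n + 1] <- six_rows(X, cl)
      if (any(states[, n + 1] < -slack | states[, n + 1] > 1 + slack)) {
        feasible <- FALSE
        violation <- n
        break
      }
    }
  }
  keep <- if (feasible) seq_len(gr$n + 1) else seq_len(violation + 1)
  out <- data.frame(time = gr$times[keep], t(states[, keep, drop = FALSE]))
  names(out) <- c("time", prob_channels)
  structure(out, triple = c(p10 = triple[1], p20 = triple[2],
                            q20 = triple[3]),
            feasible = feasible, violation_index = violation,
            class = c("probability_trajectory", "data.frame"))
}

# vectorized sweep core: propagate all triples at once, returning the
# survivor mask (pass 1) or survivor mask + envelopes (pass 2).
sweep_pass <- function(triples, gr, rates, slack, envelopes = FALSE) {
  M <- nrow(triples)
  X <- t(as.matrix(triples))
  cols <- seq_len(M)
  violation <- rep(NA_integer_, M)
  lower <- upper <- NULL
  if (envelopes) {
    lower <- matrix(Inf, 6, gr$n + 1, dimnames = list(prob_channels, NULL))
    upper <- matrix(-Inf, 6, gr$n + 1, dimnames = list(prob_channels, NULL))
  }
  record <- function(Y6, n) {
    if (envelopes && length(Y6) > 0) {
      lower[, n] <<- pmin(lower[, n], apply(Y6, 1, min))
      upper[, n] <<- pmax(upper[, n], apply(Y6, 1, max))
    }
  }
  cl <- close_probabilities(X[1, ], X[2, ], X[3, ],
                            gr$nodes$s[1], gr$nodes$sdot[1], rates)
  Y6 <- six_rows(X, cl)
  ok <- colSums(Y6 < -slack | Y6 > 1 + slack) == 0
  violation[cols[!ok]] <- 0L
  X <- X[, ok, drop = FALSE]
  cols <- cols[ok]
  record(Y6[, ok, drop = FALSE], 1L)
  for (n in seq_len(gr$n)) {
    if (length(cols) == 0) break
    af_h <- mc_affine(gr$halves$s[n], gr$halves$sdot[n],
                      gr$halves$sddot[n], rates)
    X <- mc_step(X, af_h, gr$dt)
    cl <- close_probabilities(X[1, ], X[2, ], X[3, ],
                              gr$nodes$s[n + 1], gr$nodes$sdot[n + 1],
                              rates)
    Y6 <- six_rows(X, cl)
    ok <- colSums(Y6 < -slack | Y6 > 1 + slack) == 0
    if (!all(ok)) {
      violation[cols[!ok]] <- n
      X <- X[, ok, drop = FALSE]
      cols <- cols[ok]
      Y6 <- Y6[, ok, drop = FALSE]
    }
    record(Y6, n + 1L)
  }
  list(survivors = cols, violation = violation, lower = lower,
       upper = upper)
}

#' Corridors of scenario probabilities by initial-condition sweep
#'
#' Sweeps the cube of initial triples (p10, p20, q20) over \[0, 1\]^3 at
#' resolution `grid_step`, integrates the minimal-change scheme for every
#' triple, discards any triple whose trajectory leaves the unit interval in
#' any of the six channels, and returns the pointwise per-channel min/max
#' envelopes ("corridors") over all surviving trajectories together with
#' the admissible triples.  Deterministic for fixed inputs.
#'
#' Two vectorized passes are made (all triples share each step's 3x3
#' matrix): the first determines survivors, the second accumulates
#' envelopes over survivors only, so a trajectory that dies late never
#' contributes to early envelope values.
#'
#' @inheritParams integrate_scheme
#' @param grid_step Sweep resolution in (0, 0.5\] (default 0.05; the
#'   original tabulated resolution 0.01 is available but costs ~1e6
#'   integrations).
#' @param dt Scheme time step for the sweep (default 0.01).
#' @return An object of class `corridor_set`: list with `times`, `lower`
#'   and `upper` (6 x n matrices, rows `p1..q2`), `admissible_triples`
#'   (data frame `p10, p20, q20`), `grid_step`, `dt`, `n_swept`, `empty`.
#' @export
scan_corridors <- function(curve, rates, grid_step = 0.05, dt = 0.01,
                           slack = 1e-9) {
  stopifnot(inherits(curve, "reference_curve"),
            inherits(rates, "rate_params"))
  if (grid_step <= 0 || grid_step > 0.5)
    stop("grid_step must lie in (0, 0.5]", call. = FALSE)
  g <- seq(0, 1, by = grid_step)
  if (1 - g[length(g)] > 1e-12) g <- c(g, 1)
  triples <- expand.grid(p10 = g, p20 = g, q20 = g,
                         KEEP.OUT.ATTRS = FALSE)
  gr <- mc_grid(curve, dt)
  p1 <- sweep_pass(triples, gr, rates, slack, envelopes = FALSE)
  adm <- triples[p1$survivors, , drop = FALSE]
  rownames(adm) <- NULL
  if (nrow(adm) == 0) {
    return(structure(list(times = gr$times, lower = NULL, upper = NULL,
                          admissible_triples = adm, grid_step = grid_step,
                          dt = gr$dt, n_swept = nrow(triples),
                          empty = TRUE),
                     class = "corridor_set"))
  }
  p2 <- sweep_pass(adm, gr, rates, slack, envelopes = TRUE)
  structure(list(times = gr$times,
                 lower = pmin(pmax(p2$lower, 0), 1),
                 upper = pmin(pmax(p2$upper, 0), 1),
                 admissible_triples = adm, grid_step = grid_step,
                 dt = gr$dt, n_swept = nrow(triples), empty = FALSE),
            class = "corridor_set")
}

#' @export
print.corridor_set <- function(x, ...) {
  cat(sprintf(
    "<corridor_set> %d/%d admissible triples at resolution %g, %d times\n",
    nrow(x$admissible_triples), x$n_swept, x$grid_step, length(x$times)))
  if (!x$empty) {
    rng <- t(vapply(prob_channels, function(ch)
      c(min(x$lower[ch, ]), max(x$upper[ch, ])), numeric(2)))
    colnames(rng) <- c("min", "max")
    print(round(rng, 4))
  }
  invisible(x)
}

parse_objective <- function(objective) {
  if (is.character(objective)) {
    objective <- match.arg(objective, c("min_q20", "max_p10"))
    if (objective == "min_q20") list(component = "q20", direction = "min")
    else list(component = "p10", direction = "max")
  } else {
    stopifnot(is.list(objective),
              objective$component %in% c("p10", "p20", "q20"),
              objective$direction %in% c("min", "max"))
    objective
  }
}

#' Extremal unique probability trajectory
#'
#' Among all admissible initial triples, selects the one extremizing an
#' objective (minimal q20 — probing whether the dedifferentiation scenario
#' D -> S can be absent — or maximal p10 — the largest sustainable
#' asymmetric-division probability — or any custom component/direction)
#' and integrates its unique minimal-change trajectory.  Ties within
#' `1e-12` are broken lexicographically over (p10, p20, q20) ascending.
#'
#' @inheritParams scan_corridors
#' @param objective `"min_q20"`, `"max_p10"`, or
#'   `list(component = "p10"|"p20"|"q20", direction = "min"|"max")`.
#' @param corridors Optional precomputed [scan_corridors()] result for the
#'   same curve/rates/resolution (avoids re-sweeping).
#' @return A `probability_trajectory` (see [integrate_scheme()]).
#' @export
extremal_trajectory <- function(curve, rates, objective = "min_q20",
                                grid_step = 0.05, dt = 0.01,
                                corridors = NULL, slack = 1e-9) {
  obj <- parse_objective(objective)
  if (is.null(corridors))
    corridors <- scan_corridors(curve, rates, grid_step, dt, slack)
  adm <- corridors$admissible_triples
  if (nrow(adm) == 0)
    stop("no admissible initial triple: empty corridor", call. = FALSE)
  v <- adm[[obj$component]]
  best <- if (obj$direction == "min") min(v) else max(v)
  cand <- adm[abs(v - best) < 1e-12, , drop = FALSE]
  cand <- cand[order(cand$p10, cand$p20, cand$q20), , drop = FALSE]
  integrate_scheme(as.numeric(cand[1, ]), curve, rates, dt = dt,
                   slack = slack)
}

#' Write corridor envelopes to CSV
#'
#' Header `time,p1_min,p1_max,...,q2_min,q2_max`.
#'
#' @param corridors A `corridor_set`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_corridor_csv <- function(corridors, path) {
  stopifnot(inherits(corridors, "corridor_set"))
  if (corridors$empty)
    stop("empty corridor set has no envelopes to write", call. = FALSE)
  df <- data.frame(time = corridors$times)
  for (ch in prob_channels) {
    df[[paste0(ch, "_min")]] <- corridors$lower[ch, ]
    df[[paste0(ch, "_max")]] <- corridors$upper[ch, ]
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write admissible initial triples to CSV
#'
#' Header `p10,p20,q20`.
#'
#' @inheritParams write_corridor_csv
#' @export
write_triples_csv <- function(corridors, path) {
  stopifnot(inherits(corridors, "corridor_set"))
  utils::write.csv(corridors$admissible_triples, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a probability trajectory to CSV
#'
#' Header `time,p1,p2,p3,p4,q1,q2`.
#'
#' @param traj A `probability_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_prob_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "probability_trajectory"))
  utils::write.csv(format(as.data.frame(traj), digits = 17,
                          scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
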