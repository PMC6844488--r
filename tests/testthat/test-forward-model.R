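test_that("parameter constructors enforce their invariants", {
  expect_error(rate_params(0, 1), "lambda")
  expect_error(rate_params(1, 1, -0.1), "death")
  expect_error(probability_state(0.5, 0.5, 0.5, 0.5, 1, 0), "equal 1")
  expect_error(probability_state(0.5, 0.5, 0, 0, 0.5, 0.4), "q1 \\+ q2")
  expect_error(probability_state(1.2, -0.2, 0, 0, 1, 0), "\\[0, 1\\]")
  expect_silent(probability_state(0.25, 0.25, 0.25, 0.25, 0.5, 0.5))
})

test_that("division coefficients follow the scenario bookkeeping", {
  # pure symmetric renewal: S grows at lambda1, no coupling to D
  co <- division_coefficients(probability_state(0, 0, 1, 0, 1, 0),
                              rate_params(1, 1))
  expect_equal(unname(co), c(1, 0, 0, 1))
  # pure asymmetric division leaves the S count static
  co <- division_coefficients(probability_state(1, 0, 0, 0, 1, 0),
                              rate_params(1, 1))
  expect_equal(co[["alphaS"]], 0)
  expect_equal(co[["betaD"]], 0)
  expect_equal(co[["betaS"]], 1)
  # uniform scenarios, mixed rates (hand-substituted values)
  co <- division_coefficients(
    probability_state(0.25, 0.25, 0.25, 0.25, 0.5, 0.5),
    rate_params(2, 4, 0.1, 0.5))
  expect_equal(unname(co), c(-0.6, 2, 2, 1.5), tolerance = 1e-12)
})

test_that("simulation matches closed forms and the matrix exponential", {
  # decoupled exponential growth
  tr <- simulate_population(rate_params(1, 1),
                            probability_state(0, 0, 1, 0, 1, 0),
                            t_max = 5, dt = 0.01)
  expect_equal(tr$S, exp(tr$time), tolerance = 1e-8)
  expect_equal(tr$D, rep(0, nrow(tr)))
  # constant source: S stays 1, D grows linearly when lambda2 -> 0
  tr <- simulate_population(rate_params(2, 1e-12),
                            probability_state(1, 0, 0, 0, 1, 0),
                            t_max = 5, dt = 0.01)
  expect_equal(tr$S, rep(1, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$D, 2 * tr$time, tolerance = 1e-6)
  # general constant-coefficient system vs matrix exponential
  skip_if_not_installed("Matrix")
  rates <- rate_params(1, 5, 0.1, 0.1)
  probs <- probability_state(0.5, 0.1, 0.3, 0.1, 0.9, 0.1)
  tr <- simulate_population(rates, probs, t_max = 10, dt = 0.002)
  co <- division_coefficients(probs, rates)
  A <- matrix(c(co[["alphaS"]], co[["betaS"]],
                co[["betaD"]], co[["alphaD"]]), 2, 2)
  for (t in c(1, 5, 10)) {
    ref <- as.numeric(Matrix::expm(A * t) %*% c(1, 0))
    row <- tr[abs(tr$time - t) < 1e-9, ]
    expect_equal(c(row$S, row$D), ref, tolerance = 1e-8)
  }
})

test_that("stem fraction handles the degenerate and symmetric cases", {
  tr <- simulate_population(rate_params(1, 1),
                            probability_state(0, 0, 1, 0, 1, 0),
                            t_max = 2, dt = 0.01)
  expect_equal(stem_fraction(tr)$s, rep(1, nrow(tr)))
  eq <- structure(data.frame(time = 0:5, S = 2^(0:5), D = 2^(0:5)),
                  class = c("population_trajectory", "data.frame"))
  expect_equal(stem_fraction(eq)$s, rep(0.5, 6))
  zero <- structure(data.frame(time = 0:5, S = 0, D = 0),
                    class = c("population_trajectory", "data.frame"))
  expect_error(stem_fraction(zero), "degenerate")
})

test_that("steady-state fractions cover the root, sentinel and limit cases", {
  # factorable case: s (-lambda2 + (lambda2 - lambda1) s) = 0
  ss <- steady_state_fractions(probability_state(1, 0, 0, 0, 1, 0),
                               rate_params(1, 5, 0.2, 0.2))
  expect_equal(ss$roots, 0)   # the 5/4 root is outside [0, 1]
  expect_false(ss$any_s)
  # identical growth of S and D: every coefficient vanishes
  ss <- steady_state_fractions(probability_state(0, 0, 1, 0, 1, 0),
                               rate_params(1, 1, 0.3, 0.3))
  expect_true(ss$any_s)
  expect_length(ss$roots, 0)
  # interior root equals the long-time forward-simulation fraction
  probs <- probability_state(0.5, 0.1, 0.3, 0.1, 0.9, 0.1)
  rates <- rate_params(1, 5, 0.1, 0.1)
  ss <- steady_state_fractions(probs, rates)
  # the eigenvalue gap (~4.5 per unit time) makes t = 40 effectively
  # infinite while keeping abundances inside double range
  tr <- simulate_population(rates, probs, t_max = 40, dt = 0.02)
  s_inf <- tr$S[nrow(tr)] / (tr$S[nrow(tr)] + tr$D[nrow(tr)])
  expect_true(any(abs(ss$roots - s_inf) <= 1e-10))
})

test_that("fraction velocity from the abundance system matches the quadratic", {
  # substituting S = s N, D = (1-s) N into the abundance ODEs must give
  # the single fraction-velocity quadratic identically
  set.seed(11)
  for (i in 1:1000) {
    p <- diff(sort(c(0, runif(3), 1)))
    q2 <- runif(1)
    probs <- probability_state(p[1], p[2], p[3], p[4], 1 - q2, q2,
                               tol = 1e-9)
    rates <- rate_params(runif(1, 0.2, 3), runif(1, 0.2, 10),
                         runif(1, 0, 1), runif(1, 0, 1))
    s <- runif(1, 0.01, 0.99)
    co <- division_coefficients(probs, rates)
    Sdot <- co[["alphaS"]] * s + co[["betaD"]] * (1 - s)
    Ddot <- co[["betaS"]] * s + co[["alphaD"]] * (1 - s)
    sdot_ode <- Sdot - s * (Sdot + Ddot)  # N = 1 w.l.o.g.
    sdot_quad <- q2 * rates$lambda2 +
      ((p[3] - p[2] - p[4]) * rates$lambda1 -
         (1 + q2) * rates$lambda2 + rates$gamma2 - rates$gamma1) * s +
      (rates$lambda2 - (1 - p[4]) * rates$lambda1 -
         rates$gamma2 + rates$gamma1) * s^2
    expect_equal(sdot_ode, sdot_quad, tolerance = 1e-8)
  }
})

test_that("simulated fractions stay within the unit interval", {
  set.seed(12)
  for (i in 1:20) {
    p <- diff(sort(c(0, runif(3), 1)))
    q2 <- runif(1)
    probs <- probability_state(p[1], p[2], p[3], p[4], 1 - q2, q2,
                               tol = 1e-9)
    rates <- rate_params(runif(1, 0.2, 2), runif(1, 0.2, 6),
                         runif(1, 0, 0.4), runif(1, 0, 0.4))
    crv <- stem_fraction(simulate_population(rates, probs, t_max = 10,
                                             dt = 0.02))
    expect_true(all(crv$s >= 0 & crv$s <= 1))
  }
})
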