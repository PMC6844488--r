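test_that("closure reproduces the hand-computed states and guards s", {
  r <- rate_params(1, 1)
  cl <- close_probabilities(0, 0, 0, 0.5, 0, r)
  expect_equal(cl$p3, 1)
  expect_equal(cl$p4, 0)
  expect_equal(cl$q1, 1)
  cl <- close_probabilities(0, 0, 0.2, 0.5, 0, r)
  expect_equal(cl$p3, 13 / 15, tolerance = 1e-12)
  expect_equal(cl$p4, 2 / 15, tolerance = 1e-12)
  expect_error(close_probabilities(0, 0, 0.2, 0, 0, r), "singular")
})

test_that("closure satisfies the fraction-velocity identity", {
  set.seed(21)
  n <- 2000
  r <- rate_params(1.3, 4.2, 0.15, 0.4)
  p1 <- runif(n); p2 <- runif(n) * (1 - p1); q2 <- runif(n)
  s <- runif(n, 0.05, 1); sdot <- runif(n, -0.5, 0.5)
  cl <- close_probabilities(p1, p2, q2, s, sdot, r)
  rhs <- q2 * r$lambda2 +
    ((cl$p3 - p2 - cl$p4) * r$lambda1 - (1 + q2) * r$lambda2 +
       r$gamma2 - r$gamma1) * s +
    (r$lambda2 - (1 - cl$p4) * r$lambda1 - r$gamma2 + r$gamma1) * s^2
  expect_lt(max(abs(rhs - sdot)), 1e-10)
})

test_that("minimal-change derivatives vanish and match the symbolic oracle", {
  r <- rate_params(1, 1)
  # no change in the curve requires no change in the probabilities
  mc <- minimal_change_rhs(0.3, 0.2, 0.4, 0.6, 0, 0, r)
  expect_equal(unlist(mc), c(dp1dt = 0, dp2dt = 0, dq2dt = 0))
  # the (s - 1) factor silences the p1 and q2 channels at s = 1
  mc <- minimal_change_rhs(0.3, 0.2, 0.4, 1, -0.5, 0.3, r)
  expect_equal(mc$dp1dt, 0)
  expect_equal(mc$dq2dt, 0)
  # frozen values from exact rational evaluation of the printed
  # right-hand sides (independent computer-algebra oracle)
  mc <- minimal_change_rhs(0.3, 0.1, 0.2, 0.5, -0.1, 0.05, r)
  expect_equal(mc$dp1dt, -4 / 3225, tolerance = 1e-12)
  expect_equal(mc$dp2dt, 28 / 3225, tolerance = 1e-12)
  expect_equal(mc$dq2dt, -16 / 3225, tolerance = 1e-12)
  expect_error(minimal_change_rhs(0.3, 0.1, 0.2, 0, -0.1, 0.05, r),
               "singular")
})

test_that("constant curves are fixed points of the integration scheme", {
  crv <- constant_reference_curve(0.5, t_max = 5, n_points = 51)
  r <- rate_params(1, 1)
  tr <- integrate_scheme(c(0.2, 0.1, 0.5), crv, r, dt = 0.01)
  expect_true(attr(tr, "feasible"))
  for (ch in c("p1", "p2", "q2"))
    expect_equal(tr[[ch]], rep(tr[[ch]][1], nrow(tr)))
  expect_equal(tr$p3, rep(tr$p3[1], nrow(tr)), tolerance = 1e-12)
})

test_that("the scheme conserves both probability simplexes exactly", {
  gt <- make_ground_truth_bundle(gt_rates(), gt_probs())
  tr <- integrate_scheme(c(0.55, 0.05, 0.2), gt$curve, gt_rates(),
                         dt = 0.01)
  expect_lt(max(abs(tr$p1 + tr$p2 + tr$p3 + tr$p4 - 1)), 1e-14)
  expect_lt(max(abs(tr$q1 + tr$q2 - 1)), 1e-14)
})

test_that("the scheme recovers constant ground-truth probabilities", {
  gt <- make_ground_truth_bundle(gt_rates(), gt_probs())
  tr <- integrate_scheme(c(0.55, 0.05, 0.2), gt$curve, gt_rates(),
                         dt = 1e-3)
  expect_true(attr(tr, "feasible"))
  truth <- unclass(gt_probs())
  for (ch in names(truth))
    expect_lt(max(abs(tr[[ch]] - truth[[ch]])), 1e-3)
})

test_that("the scheme agrees with an independent explicit integration", {
  crv <- make_reference_curve(0.1, 1)
  r <- gt_rates()
  triple <- c(0.2, 0.3, 0.3)
  tr <- integrate_scheme(triple, crv, r, dt = 1e-3)
  expect_true(attr(tr, "feasible"))
  deriv <- function(t, y, parms) {
    cv <- curve_eval(crv, t)
    mc <- minimal_change_rhs(y[1], y[2], y[3], cv$s, cv$sdot, cv$sddot, r)
    list(c(mc$dp1dt, mc$dp2dt, mc$dq2dt))
  }
  sol <- deSolve::ode(triple, seq(0, 10, 1e-3), deriv, NULL,
                      method = "rk4")
  expect_lt(max(abs(sol[, 2:4] -
                      as.matrix(tr[, c("p1", "p2", "q2")]))), 1e-6)
})

test_that("the global error of the scheme decays at second order", {
  crv <- make_reference_curve(0.1, 1)
  r <- gt_rates()
  triple <- c(0.2, 0.3, 0.3)
  at <- seq(0, 10, 0.5)
  sol <- function(dt) {
    tr <- integrate_scheme(triple, crv, r, dt = dt)
    as.matrix(tr[tr$time %in% at, -1])
  }
  ref <- sol(0.000625)
  errs <- vapply(c(0.02, 0.01, 0.005), function(dt)
    max(abs(sol(dt) - ref)), numeric(1))
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 3 & ratios < 5))
})

test_that("the sweep on a constant curve equals direct closure screening", {
  crv <- constant_reference_curve(0.5, t_max = 5, n_points = 51)
  r <- rate_params(1, 1)
  cs <- scan_corridors(crv, r, grid_step = 0.25, dt = 0.05)
  # with zero change required, a triple is admissible iff its closure at
  # t = 0 already lies in the unit interval
  g <- seq(0, 1, 0.25)
  grid <- expand.grid(p10 = g, p20 = g, q20 = g, KEEP.OUT.ATTRS = FALSE)
  cl <- close_probabilities(grid$p10, grid$p20, grid$q20, 0.5, 0, r)
  ok <- cl$p3 >= -1e-9 & cl$p3 <= 1 + 1e-9 &
    cl$p4 >= -1e-9 & cl$p4 <= 1 + 1e-9
  expect_equal(nrow(cs$admissible_triples), sum(ok))
  expect_equal(as.matrix(cs$admissible_triples),
               as.matrix(grid[ok, ]), ignore_attr = TRUE)
  # envelopes of constant trajectories are constant in time
  expect_equal(cs$lower, cs$lower[, rep(1, ncol(cs$lower))],
               ignore_attr = TRUE)
  expect_equal(cs$upper, cs$upper[, rep(1, ncol(cs$upper))],
               ignore_attr = TRUE)
})

test_that("ground truth is admissible and contained in its corridors", {
  gt <- make_ground_truth_bundle(gt_rates(), gt_probs())
  cs <- scan_corridors(gt$curve, gt_rates(), grid_step = 0.05, dt = 0.01)
  adm <- cs$admissible_triples
  expect_true(any(abs(adm$p10 - 0.55) < 1e-9 & abs(adm$p20 - 0.05) < 1e-9 &
                    abs(adm$q20 - 0.2) < 1e-9))
  truth <- unclass(gt_probs())
  for (ch in names(truth)) {
    expect_true(all(cs$lower[ch, ] <= truth[[ch]] + 1e-9))
    expect_true(all(cs$upper[ch, ] >= truth[[ch]] - 1e-9))
  }
})

test_that("surviving trajectories lie within the returned envelopes", {
  crv <- make_reference_curve(0.1, 1, n_points = 101)
  r <- gt_rates()
  cs <- scan_corridors(crv, r, grid_step = 0.2, dt = 0.01)
  adm <- cs$admissible_triples
  expect_gt(nrow(adm), 0)
  for (i in seq_len(min(5, nrow(adm)))) {
    tr <- integrate_scheme(as.numeric(adm[i, ]), crv, r, dt = cs$dt)
    expect_true(attr(tr, "feasible"))
    for (ch in c("p1", "p2", "p3", "p4", "q1", "q2")) {
      expect_true(all(tr[[ch]] >= cs$lower[ch, ] - 1e-9))
      expect_true(all(tr[[ch]] <= cs$upper[ch, ] + 1e-9))
    }
  }
})

test_that("extremal trajectories honor objective, ties and emptiness", {
  crv <- constant_reference_curve(0.5, t_max = 5, n_points = 51)
  r <- rate_params(1, 1)
  cs <- scan_corridors(crv, r, grid_step = 0.25, dt = 0.05)
  tr <- extremal_trajectory(crv, r, "max_p10", corridors = cs, dt = 0.05)
  expect_equal(attr(tr, "triple")[["p10"]],
               max(cs$admissible_triples$p10))
  expect_equal(tr$p1, rep(tr$p1[1], nrow(tr)))
  # truth attaining the bound: q2 = 0 ground truth gives min q20 = 0
  gt <- make_ground_truth_bundle(
    rate_params(1, 2, 0.1, 0.1),
    probability_state(0.5, 0.2, 0.2, 0.1, 1, 0))
  tr <- extremal_trajectory(gt$curve, rate_params(1, 2, 0.1, 0.1),
                            "min_q20", grid_step = 0.1, dt = 0.01)
  expect_equal(attr(tr, "triple")[["q20"]], 0)
  # a cliff-steep curve admits no probability evolution at all
  steep <- make_reference_curve(0.1, 5, n_points = 101)
  cs <- scan_corridors(steep, rate_params(1, 1, 0.1, 0.1),
                       grid_step = 0.25, dt = 0.01)
  expect_true(cs$empty)
  expect_error(extremal_trajectory(steep, rate_params(1, 1, 0.1, 0.1),
                                   corridors = cs), "no admissible")
})
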