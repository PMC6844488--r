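# shared fixtures: all inputs are generated in code, no files

gt_rates <- function() rate_params(1, 5, 0.1, 0.1)

gt_probs <- function() probability_state(0.55, 0.05, 0.3, 0.1, 0.8, 0.2)

# the six biologically motivated rate sets: lambda1 = 1, stem/non-stem
# division ratios 1:1, 1:5, 1:10, death rates 0.1 and 0.1-or-0.5
six_rate_sets <- function() {
  g <- expand.grid(l2 = c(1, 5, 10), g2 = c(0.1, 0.5))
  lapply(seq_len(nrow(g)), function(i)
    rate_params(1, g$l2[i], 0.1, g$g2[i]))
}

# K well-separated bump factors with seeded jitter; centers spread over
# [1.2, 8.8] of the 10-unit window, widths ~ 0.8-1.2 time units
make_factor_fixture <- function(K, seed, b_range = c(0.15, 0.6)) {
  set.seed(seed)
  centers <- seq(1.2, 8.8, length.out = K) + runif(K, -0.25, 0.25)
  widths <- runif(K, 0.8, 1.2)
  lapply(seq_len(K), function(k)
    field_factor(widths[k]^(-6), centers[k], 6,
                 runif(6, b_range[1], b_range[2])))
}

# channels generated under a cell-type assignment: each factor's basis is
# multiplied by s(t), d(t) or 1 before weighting
make_attributed_channels <- function(factors, labels, curve, times) {
  sv <- curve_eval(curve, times)$s
  mods <- cbind(S = sv, D = 1 - sv, `1` = rep(1, length(times)))
  y <- matrix(0, length(times), 6,
              dimnames = list(NULL, c("p1", "p2", "p3", "p4", "q1", "q2")))
  for (k in seq_along(factors)) {
    fc <- factors[[k]]
    basis <- mods[, labels[k]] * exp(-fc$a * (times - fc$c)^fc$m)
    y <- y + outer(basis, fc$b_weights)
  }
  y
}

# match fitted factors to true ones by center distance (all permutations;
# K is small) and return per-parameter relative errors
match_factors <- function(fitted, truth) {
  K <- length(truth)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  fc <- vapply(fitted, `[[`, numeric(1), "c")
  tc <- vapply(truth, `[[`, numeric(1), "c")
  best <- NULL
  for (p in perms(seq_len(K))) {
    d <- sum(abs(fc[p] - tc))
    if (is.null(best) || d < best$d) best <- list(d = d, p = p)
  }
  p <- best$p
  list(
    center_err = abs(fc[p] - tc),
    a_rel = abs(vapply(fitted, `[[`, numeric(1), "a")[p] -
                  vapply(truth, `[[`, numeric(1), "a")) /
      vapply(truth, `[[`, numeric(1), "a"),
    b_rel = vapply(seq_len(K), function(k)
      max(abs(fitted[[p[k]]]$b_weights - truth[[k]]$b_weights) /
            pmax(abs(truth[[k]]$b_weights), 0.05)), numeric(1)))
}
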