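# basis value exp(-a (t - c)^m); exponents below ~ -745 underflow to 0,
# which is the intended guard for far-from-center evaluation
bump_basis <- function(t, a, c, m) {
  exp(-a * (t - c)^m)
}

#' One underlying-field factor
#'
#' A bump-shaped factor kinetic `u(t) = b exp(-a (t - c)^m)`: `a` sets the
#' width (the value falls to `b/e` at `|t - c| = a^(-1/m)`), `c` the center
#' position on the time axis, even `m` the sharpness (m = 6 gives the
#' near-trapezoid plateau shape used throughout), and the six per-channel
#' amplitudes `b_weights` its influence on each probability channel.  The
#' reported height `b_k = max_i |b_ik|` is the concentration-like proxy of
#' the factor.
#'
#' @param a Width coefficient (> 0, per time^m).
#' @param c Center position (time units).
#' @param m Even shape exponent >= 2 (default 6).
#' @param b_weights Numeric length-6 amplitudes (may be negative), ordered
#'   `p1, p2, p3, p4, q1, q2`.
#' @return An object of class `field_factor`.
#' @export
field_factor <- function(a, c, m = 6, b_weights = rep(0, 6)) {
  if (!is.finite(a) || a <= 0) stop("width a must be > 0", call. = FALSE)
  if (!is.finite(c)) stop("center c must be finite", call. = FALSE)
  if (m < 2 || m %% 2 != 0) stop("m must be even and >= 2", call. = FALSE)
  if (length(b_weights) != 6 || any(!is.finite(b_weights)))
    stop("b_weights must be 6 finite amplitudes", call. = FALSE)
  b_weights <- stats::setNames(as.numeric(b_weights), prob_channels)
  structure(list(a = a, c = c, m = m, b_weights = b_weights,
                 b_k = max(abs(b_weights))),
            class = "field_factor")
}

#' Collection of fitted underlying-field factors
#'
#' @param factors List of [field_factor()].
#' @param epsilon Mean absolute deviation of the fit, percent of the unit
#'   probability scale.
#' @param times Fit grid.
#' @param converged Logical; did the relaxation reach stationarity.
#' @param objective Final value of the quadratic objective.
#' @return An object of class `factor_set`.
#' @export
factor_set <- function(factors, epsilon = NA_real_, times = NULL,
                       converged = NA, objective = NA_real_) {
  stopifnot(is.list(factors),
            all(vapply(factors, inherits, logical(1), "field_factor")))
  structure(list(factors = factors, K = length(factors),
                 epsilon = epsilon, times = times, converged = converged,
                 objective = objective),
            class = "factor_set")
}

#' @export
print.factor_set <- function(x, ...) {
  cat(sprintf("<factor_set> K = %d, epsilon = %s%%\n", x$K,
              format(x$epsilon, digits = 4)))
  for (fc in x$factors)
    cat(sprintf("  a = %-10.4g c = %-8.4g m = %d  b_k = %.4f\n",
                fc$a, fc$c, fc$m, fc$b_k))
  invisible(x)
}

#' Evaluate one factor kinetic
#'
#' `b exp(-a (t - c)^m)` with height `b` defaulting to the factor's
#' concentration proxy `b_k`; pass a channel amplitude for per-channel
#' prediction.
#'
#' @param factor A [field_factor()].
#' @param t Times (vectorized).
#' @param b Height (default `factor$b_k`).
#' @return Numeric vector.
#' @export
factor_value <- function(factor, t, b = factor$b_k) {
  stopifnot(inherits(factor, "field_factor"))
  b * bump_basis(t, factor$a, factor$c, factor$m)
}

#' Predicted probability channels from a factor set
#'
#' Exact evaluation of the decomposition
#' `y_i(t) = sum_k b_ik exp(-a_k (t - c_k)^m)`; no clipping to \[0, 1\]
#' (fit residuals may stray outside).
#'
#' @param fset A [factor_set()].
#' @param times Evaluation grid.
#' @return Matrix `length(times) x 6`, columns `p1..q2`.
#' @export
predict_probabilities <- function(fset, times) {
  stopifnot(inherits(fset, "factor_set"))
  y <- make_probability_curves_from_factors(fset, times)
  attr(y, "valid") <- NULL
  y
}

#' Mean absolute deviation between channel sets, in percent
#'
#' `epsilon = sum_n sum_i |y_i(t_n) - y_in| / (6 N) * 100` — the average
#' absolute miss over all six channels and all N time points, expressed as
#' percent of the unit probability scale.
#'
#' @param predicted,observed Equal-shape numeric matrices (N x 6).
#' @return Scalar percent deviation.
#' @export
epsilon_deviation <- function(predicted, observed) {
  predicted <- as.matrix(predicted)
  observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed)) || length(observed) < 1)
    stop("predicted and observed must have equal nonzero shape",
         call. = FALSE)
  mean(abs(predicted - observed)) * 100
}

#' Relaxation settings for the factor fit
#'
#' The stationarity system of the quadratic objective is solved by
#' pseudo-time gradient relaxation: each pseudo-time step moves the width,
#' center and amplitude blocks down their objective gradients.  Step sizes
#' are adapted by backtracking (a step that would increase the objective
#' is halved) rather than fixed, so the objective is non-increasing across
#' accepted iterations by construction.
#'
#' @param max_iters Iteration cap (>= 1).
#' @param tol Stationarity tolerance on the scale-adjusted gradient
#'   magnitudes (widths are measured on their own scale, i.e. the width
#'   gradient is weighted by `a`).
#' @param n_restarts Extra randomly jittered initializations (0 keeps the
#'   fully deterministic default path).
#' @param seed RNG seed used only when `n_restarts > 0`.
#' @return An object of class `relaxation_config`.
#' @export
relaxation_config <- function(max_iters = 3000, tol = 1e-6,
                              n_restarts = 0, seed = 1) {
  if (max_iters < 1) stop("max_iters must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  structure(list(max_iters = max_iters, tol = tol,
                 n_restarts = n_restarts, seed = seed),
            class = "relaxation_config")
}

# gradient of the quadratic objective wrt (a, c, B) under an optional
# per-factor modulation W (N x K); E = W * exp(-a (t-c)^m)
fit_eval <- function(times, a, c, B, m, W) {
  Tc <- outer(times, c, "-")
  E0 <- exp(-sweep(Tc^m, 2, a, "*"))
  E <- if (is.null(W)) E0 else W * E0
  list(Tc = Tc, E = E)
}

fit_objective <- function(observed, ev, B) {
  R <- ev$E %*% t(B) - observed
  list(R = R, f = sum(R * R))
}

fit_gradients <- function(observed, times, a, c, B, m, W, ev = NULL) {
  if (is.null(ev)) ev <- fit_eval(times, a, c, B, m, W)
  ob <- fit_objective(observed, ev, B)
  RB <- ob$R %*% B                      # N x K
  grad_B <- 2 * crossprod(ob$R, ev$E)   # 6 x K
  grad_a <- -2 * colSums(ev$Tc^m * ev$E * RB)
  grad_c <- 2 * a * m * colSums(ev$Tc^(m - 1) * ev$E * RB)
  list(f = ob$f, grad_a = grad_a, grad_c = grad_c, grad_B = grad_B,
       ev = ev)
}

ls_amplitudes <- function(observed, E) {
  cf <- tryCatch(qr.coef(qr(E), observed), error = function(e) NULL)
  if (is.null(cf)) cf <- matrix(0, ncol(E), ncol(observed))
  cf[!is.finite(cf)] <- 0
  t(cf)                                 # 6 x K
}

relax_factors <- function(observed, times, a, c, B, m, W, config) {
  span <- diff(range(times))
  a_min <- 1e-10
  K <- length(a)
  f <- fit_objective(observed, fit_eval(times, a, c, B, m, W), B)$f
  eta_a <- rep(NA_real_, K)
  eta_c <- rep(NA_real_, K)
  stall <- 0L
  converged <- FALSE
  iters <- 0L
  # one-coordinate descent move with backtracking (step memory per
  # coordinate, regrowth by restarting at twice the last accepted step)
  coord_step <- function(block, k, g) {
    if (g == 0) return(invisible(NULL))
    scale <- if (block == "a") a[k] else span
    eta <- if (block == "a") eta_a[k] else eta_c[k]
    if (!is.finite(eta))
      eta <- (if (block == "a") 0.05 * a[k] else 0.02 * span) / abs(g)
    step <- eta * 2
    for (try in 1:20) {
      if (abs(step * g) < 1e-14 * max(1, scale)) break  # converged coord
      a2 <- a; c2 <- c
      if (block == "a") a2[k] <- max(a[k] - step * g, a_min)
      else c2[k] <- c[k] - step * g
      f2 <- fit_objective(observed, fit_eval(times, a2, c2, B, m, W), B)$f
      if (is.finite(f2) && f2 < f) {
        a <<- a2; c <<- c2; f <<- f2
        break
      }
      step <- step / 2
    }
    if (block == "a") eta_a[k] <<- step else eta_c[k] <<- step
    invisible(NULL)
  }
  amplitude_step <- function() {
    # the amplitude subproblem is quadratic, so the move along its
    # gradient direction has a closed-form exact minimizer
    gr <- fit_gradients(observed, times, a, c, B, m, W)
    g <- gr$grad_B
    EG <- gr$ev$E %*% t(g)
    den <- sum(EG * EG)
    if (den > 0) {
      R <- gr$ev$E %*% t(B) - observed
      B <<- B - (sum(R * EG) / den) * g
      f <<- fit_objective(observed, gr$ev, B)$f
    }
    invisible(NULL)
  }
  for (it in seq_len(config$max_iters)) {
    iters <- it
    gr <- fit_gradients(observed, times, a, c, B, m, W)
    gmax <- max(abs(gr$grad_B), abs(gr$grad_a * a), abs(gr$grad_c))
    if (gmax < config$tol * (1 + gr$f)) {
      converged <- TRUE
      break
    }
    f_before <- f
    for (k in seq_len(K)) {
      coord_step("a", k,
                 fit_gradients(observed, times, a, c, B, m, W)$grad_a[k])
      coord_step("c", k,
                 fit_gradients(observed, times, a, c, B, m, W)$grad_c[k])
    }
    amplitude_step()
    if (f_before - f <= 1e-15 * (1 + f)) {
      stall <- stall + 1L
      if (stall >= 20L) {
        gr <- fit_gradients(observed, times, a, c, B, m, W)
        gmax <- max(abs(gr$grad_B), abs(gr$grad_a * a), abs(gr$grad_c))
        converged <- gmax < config$tol * (1 + gr$f)
        break
      }
    } else stall <- 0L
  }
  list(a = a, c = c, B = B, f = f, converged = converged, iters = iters)
}

as_channel_matrix <- function(observed) {
  if (inherits(observed, "probability_trajectory")) {
    times <- observed$time
    observed <- as.matrix(as.data.frame(observed)[, prob_channels])
    attr(observed, "times") <- times
  }
  as.matrix(observed)
}

#' Fit underlying-field factors to six probability channels
#'
#' Minimizes the total quadratic deviation between the factor decomposition
#' and the observed channels over widths `a_k`, centers `c_k` and
#' amplitudes `b_ik` by pseudo-time gradient relaxation (see
#' [relaxation_config()]).  The default initialization is deterministic:
#' centers equispaced over the time span, widths such that each bump covers
#' `span / K`, amplitudes from per-channel linear least squares given the
#' initial basis; optional seeded random restarts jitter this start.
#'
#' @param observed N x 6 matrix of channel values (columns `p1..q2`), or a
#'   `probability_trajectory`.
#' @param times Time grid (taken from `observed` when it is a trajectory).
#' @param K Number of factors (>= 1).
#' @param m Even shape exponent (default 6).
#' @param config A [relaxation_config()].
#' @param init Optional [factor_set()] warm start for widths and centers.
#' @param basis_weights Optional N x K modulation matrix multiplying each
#'   factor's basis column (used by the attribution stage).
#' @return A [factor_set()] ordered by center, carrying `epsilon`, the
#'   final objective, iteration count and convergence flag.
#' @export
fit_factors <- function(observed, times = NULL, K, m = 6,
                        config = relaxation_config(), init = NULL,
                        basis_weights = NULL) {
  observed <- as_channel_matrix(observed)
  if (is.null(times)) times <- attr(observed, "times")
  if (is.null(times) || length(times) != nrow(observed))
    stop("times must match the rows of observed", call. = FALSE)
  if (ncol(observed) != 6)
    stop("observed must have 6 channels", call. = FALSE)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (m < 2 || m %% 2 != 0) stop("m must be even and >= 2", call. = FALSE)
  span <- diff(range(times))
  starts <- list()
  if (is.null(init)) {
    a0 <- rep((span / (2 * K))^(-m), K)
    c0 <- min(times) + span * (seq_len(K) - 0.5) / K
  } else {
    stopifnot(inherits(init, "factor_set"))
    if (init$K != K)
      stop("warm start must have K factors", call. = FALSE)
    a0 <- vapply(init$factors, `[[`, numeric(1), "a")
    c0 <- vapply(init$factors, `[[`, numeric(1), "c")
  }
  starts[[1]] <- list(a = a0, c = c0)
  if (config$n_restarts > 0) {
    rng <- local({
      set.seed(config$seed)
      lapply(seq_len(config$n_restarts), function(i)
        list(a = a0 * exp(stats::runif(K, -1, 1)),
             c = c0 + stats::runif(K, -span / (4 * K), span / (4 * K))))
    })
    starts <- c(starts, rng)
  }
  best <- NULL
  for (st in starts) {
    E <- fit_eval(times, st$a, st$c, NULL, m, basis_weights)$E
    B0 <- ls_amplitudes(observed, E)
    res <- relax_factors(observed, times, st$a, st$c, B0, m,
                         basis_weights, config)
    if (is.null(best) || res$f < best$f) best <- res
  }
  ord <- order(best$c)
  factors <- lapply(ord, function(k)
    field_factor(best$a[k], best$c[k], m, best$B[, k]))
  pred <- fit_eval(times, best$a, best$c, NULL, m, basis_weights)$E %*%
    t(best$B)
  fs <- factor_set(factors, epsilon = epsilon_deviation(pred, observed),
                   times = times, converged = best$converged,
                   objective = best$f)
  fs$iterations <- best$iters
  fs$basis_weights <- basis_weights
  fs
}

#' Smallest factor count satisfying the deviation criterion
#'
#' Starting from `K_start` factors, fits and increments K until the mean
#' absolute deviation falls below the permissible variation `epsilon_p`
#' (percent).  Once accepted, factors whose concentration proxy `b_k`
#' falls below `prune_threshold` are dropped as non-essential and the
#' reduced set is refitted; the pruned set is reported when it still
#' satisfies `epsilon_p`, mirroring the detection of a smaller essential
#' factor set than the starting K.
#'
#' @inheritParams fit_factors
#' @param epsilon_p Permissible mean deviation, percent (> 0).
#' @param K_start Initial factor count (>= 1).
#' @param K_max Search cap (default `K_start + 6`).
#' @param prune_threshold Minimal essential height on the probability
#'   scale (default 0.01).
#' @return A [factor_set()] with extra fields `accepted` (logical: was
#'   `epsilon_p` met within the cap), `K_start`, `pruned` (logical).
#' @export
select_factor_count <- function(observed, times = NULL, epsilon_p,
                                K_start = 4, m = 6,
                                config = relaxation_config(),
                                K_max = K_start + 6,
                                prune_threshold = 0.01) {
  if (epsilon_p <= 0) stop("epsilon_p must be > 0", call. = FALSE)
  if (K_start < 1) stop("K_start must be >= 1", call. = FALSE)
  observed <- as_channel_matrix(observed)
  if (is.null(times)) times <- attr(observed, "times")
  best <- NULL
  for (K in K_start:K_max) {
    fs <- fit_factors(observed, times, K, m, config)
    if (is.null(best) || fs$epsilon < best$epsilon) best <- fs
    if (fs$epsilon < epsilon_p) {
      # backward elimination of non-essential factors: drop negligible
      # heights outright, then keep removing the smallest-height factor
      # while the reduced refit still satisfies epsilon_p
      pruned <- FALSE
      repeat {
        if (fs$K <= 1) break
        bk <- vapply(fs$factors, `[[`, numeric(1), "b_k")
        keep <- if (any(bk < prune_threshold)) {
          bk >= prune_threshold
        } else {
          seq_along(bk) != which.min(bk)
        }
        if (!any(keep)) break
        warm <- factor_set(fs$factors[keep])
        fs2 <- fit_factors(observed, times, sum(keep), m, config,
                           init = warm)
        if (fs2$epsilon < epsilon_p) {
          fs <- fs2
          pruned <- TRUE
        } else break
      }
      fs$accepted <- TRUE
      fs$K_start <- K_start
      fs$pruned <- pruned
      return(fs)
    }
  }
  best$accepted <- FALSE
  best$K_start <- K_start
  best$pruned <- FALSE
  best
}

#' Write a factor set to JSON
#'
#' Schema: `{K, m, epsilon, factors: [{a, c, b_weights, b_k}]}`.
#'
#' @param fset A [factor_set()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_factor_set_json <- function(fset, path) {
  stopifnot(inherits(fset, "factor_set"))
  obj <- list(K = fset$K, m = fset$factors[[1]]$m, epsilon = fset$epsilon,
              factors = lapply(fset$factors, function(f)
                list(a = f$a, c = f$c, b_weights = as.numeric(f$b_weights),
                     b_k = f$b_k)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write factor kinetics to CSV
#'
#' Header `time,u1,...,uK`; each factor drawn at its concentration-proxy
#' height `b_k`.
#'
#' @param fset A [factor_set()].
#' @param times Evaluation grid (default the fit grid).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_factor_curves_csv <- function(fset, path, times = fset$times) {
  stopifnot(inherits(fset, "factor_set"))
  df <- data.frame(time = times)
  for (k in seq_len(fset$K))
    df[[paste0("u", k)]] <- factor_value(fset$factors[[k]], times)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
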