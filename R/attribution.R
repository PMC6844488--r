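attribution_labels <- c("S", "D", "1")

modulation_column <- function(label, curve, t) {
  s <- curve_eval(curve, t)$s
  switch(label,
         S = s,
         D = 1 - s,
         `1` = rep(1, length(t)),
         stop("label must be one of S, D, 1", call. = FALSE))
}

#' Cell-kinetics-modulated factor value
#'
#' Multiplies a factor kinetic by the stem fraction s(t) (production by S
#' cells), the non-stem fraction d(t) = 1 - s(t) (production by D cells)
#' or the constant 1 (no explicit cell-type dependence).
#'
#' @param factor A [field_factor()].
#' @param label One of `"S"`, `"D"`, `"1"`.
#' @param curve A [reference_curve()] covering `t`.
#' @param t Times (vectorized).
#' @param b Height (default the factor's `b_k`).
#' @return Numeric vector.
#' @export
modulated_basis <- function(factor, label, curve, t, b = factor$b_k) {
  factor_value(factor, t, b = b) * modulation_column(label, curve, t)
}

#' Rank cell-type attributions of the fitted factors
#'
#' Enumerates every assignment of the K factors to production by S cells,
#' D cells or neither (3^K variants), refits widths, centers and
#' amplitudes under the correspondingly modulated basis (warm-started from
#' the unmodulated optimum), and returns the variants ranked by their mean
#' absolute deviation.  The all-"1" variant is always present; with
#' refitting from the converged warm start its deviation reproduces the
#' unmodulated fit's.  Variants within `tie_tol` percentage points share a
#' tie group; when s(t) is identically 1/2 the S and D modulations
#' coincide and the ranking is flagged degenerate.
#'
#' @inheritParams fit_factors
#' @param curve The [reference_curve()] the probabilities were inferred
#'   from (supplies s(t) and d(t)).
#' @param warm_start The unmodulated [factor_set()] optimum (defines K).
#' @param refit Refit (a, c, b) per variant (default); `FALSE` keeps the
#'   warm-start parameters and only re-evaluates the modulated deviation
#'   (fast comparison mode).
#' @param tie_tol Tie width in percentage points of epsilon (default
#'   `1e-4`).
#' @param K_cap Refuse enumerations beyond this K (default 8).
#' @return An object of class `attribution_ranking`: a data frame with
#'   label columns `u_1..u_K`, `epsilon` and `tie_group`, sorted by
#'   epsilon; attributes `fsets` (refit per variant, in ranked order) and
#'   `degenerate_SD`.
#' @export
rank_attributions <- function(observed, times = NULL, curve, warm_start,
                              m = 6, config = relaxation_config(),
                              refit = TRUE, tie_tol = 1e-4, K_cap = 8) {
  stopifnot(inherits(curve, "reference_curve"),
            inherits(warm_start, "factor_set"))
  observed <- as_channel_matrix(observed)
  if (is.null(times)) times <- attr(observed, "times")
  K <- warm_start$K
  if (K > K_cap)
    stop(sprintf("K = %d exceeds the %d-factor enumeration cap (3^K variants)",
                 K, K_cap), call. = FALSE)
  grid <- expand.grid(rep(list(attribution_labels), K),
                      stringsAsFactors = FALSE)
  names(grid) <- paste0("u_", seq_len(K))
  mods <- vapply(attribution_labels, modulation_column,
                 numeric(length(times)), curve = curve, t = times)
  eps <- numeric(nrow(grid))
  fsets <- vector("list", nrow(grid))
  for (v in seq_len(nrow(grid))) {
    W <- mods[, unlist(grid[v, ]), drop = FALSE]
    if (refit) {
      fs <- fit_factors(observed, times, K, m, config,
                        init = warm_start, basis_weights = W)
    } else {
      a <- vapply(warm_start$factors, `[[`, numeric(1), "a")
      cc <- vapply(warm_start$factors, `[[`, numeric(1), "c")
      B <- vapply(warm_start$factors, `[[`, numeric(6), "b_weights")
      pred <- fit_eval(times, a, cc, NULL, m, W)$E %*% t(B)
      fs <- warm_start
      fs$epsilon <- epsilon_deviation(pred, observed)
      fs$basis_weights <- W
    }
    fs$assignment <- unlist(grid[v, ], use.names = FALSE)
    eps[v] <- fs$epsilon
    fsets[[v]] <- fs
  }
  ord <- order(eps)
  out <- grid[ord, , drop = FALSE]
  out$epsilon <- eps[ord]
  out$tie_group <- cumsum(c(1, diff(out$epsilon) > tie_tol))
  rownames(out) <- NULL
  structure(out, fsets = fsets[ord],
            degenerate_SD = max(abs(mods[, "S"] - mods[, "D"])) < 1e-12,
            class = c("attribution_ranking", "data.frame"))
}

#' @export
print.attribution_ranking <- function(x, ...) {
  cat(sprintf("<attribution_ranking> %d variants (K = %d)%s\n",
              nrow(x), sum(startsWith(names(x), "u_")),
              if (isTRUE(attr(x, "degenerate_SD")))
                " [degenerate: s = d, S/D labels not identifiable]"
              else ""))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Write an attribution ranking to CSV
#'
#' Header `u_1,...,u_K,epsilon_percent`, sorted by epsilon ascending.
#'
#' @param ranking An `attribution_ranking`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  stopifnot(inherits(ranking, "attribution_ranking"))
  df <- as.data.frame(ranking)
  df$tie_group <- NULL
  names(df)[names(df) == "epsilon"] <- "epsilon_percent"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
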