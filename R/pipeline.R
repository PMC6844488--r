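#' Read a sampled stem-fraction curve from CSV
#'
#' Expects a header `time,s` (extra columns are ignored), at least 7 rows
#' and a uniform grid.  Percent-scale input (0-100) is divided by 100 when
#' `percent = "yes"`, or automatically when the column maximum exceeds 1.5
#' (`percent = "auto"`, the default).  Decimal commas are normalized when
#' `decimal_comma = TRUE`.  Derivatives are estimated via
#' [differentiate_sampled_curve()].
#'
#' @param path CSV file path.
#' @param percent `"auto"`, `"yes"` or `"no"`.
#' @param smoothing Passed to [differentiate_sampled_curve()].
#' @param decimal_comma Normalize `","` decimals before parsing.
#' @return A [reference_curve()].
#' @export
read_curve <- function(path, percent = c("auto", "yes", "no"),
                       smoothing = NULL, decimal_comma = FALSE) {
  percent <- match.arg(percent)
  df <- if (decimal_comma) {
    utils::read.csv2(path, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("time", "s") %in% names(df)))
    stop("curve CSV must have header columns 'time' and 's'",
         call. = FALSE)
  if (nrow(df) < 7)
    stop("too few samples: need at least 7 rows", call. = FALSE)
  s <- as.numeric(df$s)
  if (percent == "yes" || (percent == "auto" && max(s) > 1.5))
    s <- s / 100
  if (any(s < -1e-9 | s > 1 + 1e-9))
    stop("fractions out of range after scaling", call. = FALSE)
  differentiate_sampled_curve(as.numeric(df$time), s,
                              smoothing = smoothing)
}

#' Write a reference curve to CSV
#'
#' Header `time,s,sdot,sddot`, fractions on the 0-1 scale.
#'
#' @param curve A [reference_curve()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "reference_curve"))
  df <- data.frame(time = curve$times, s = curve$s, sdot = curve$sdot,
                   sddot = curve$sddot)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' @param rates A [rate_params()] or list of the four rates.
#' @param curve Curve source: a [reference_curve()], a path to a curve
#'   CSV, or a list of [make_reference_curve()] parameters.
#' @param stages Character subset of
#'   `c("curve", "corridor", "extremal", "decompose", "attribute")`.
#' @param grid_step,dt Sweep resolution and scheme step.
#' @param epsilon_p,K_start,m Decomposition settings.
#' @param relaxation A [relaxation_config()].
#' @param output_dir Directory for stage artifacts (created if missing).
#' @param seed Integer seed threaded to every stochastic path.
#' @return An object of class `run_config`.
#' @export
run_config <- function(rates, curve,
                       stages = c("curve", "corridor", "extremal",
                                  "decompose", "attribute"),
                       grid_step = 0.05, dt = 0.01, epsilon_p = 1,
                       K_start = 4, m = 6,
                       relaxation = relaxation_config(),
                       output_dir = tempfile("cscstab_run_"), seed = 1) {
  if (is.list(rates) && !inherits(rates, "rate_params"))
    rates <- do.call(rate_params, rates)
  stopifnot(inherits(rates, "rate_params"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(curve)) {
    if (!file.exists(curve))
      stop(sprintf("curve file does not exist: %s", curve), call. = FALSE)
  } else if (is.list(curve) && !inherits(curve, "reference_curve")) {
    curve <- do.call(make_reference_curve, curve)
  }
  structure(list(rates = rates, curve = curve, stages = stages,
                 grid_step = grid_step, dt = dt, epsilon_p = epsilon_p,
                 K_start = K_start, m = m, relaxation = relaxation,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' The file maps directly onto [run_config()] arguments; `rates` is a
#' mapping of the four rate names and `curve` either a file path or a
#' mapping of curve-family parameters.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$relaxation))
    cfg$relaxation <- do.call(relaxation_config, cfg$relaxation)
  do.call(run_config, cfg)
}

#' Run the full inference pipeline
#'
#' Chains the enabled stages: curve preparation, corridor sweep (plus the
#' two extremal trajectories, q20 -> min and p10 -> max), factor
#' decomposition of the q20-minimizing trajectory, and attribution
#' ranking.  Every stage writes its CSV/JSON artifact into
#' `config$output_dir`, and a `manifest.json` records the configuration,
#' seed, per-stage counts and deviations.  Reruns with an identical
#' configuration reproduce identical numeric outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  manifest <- list(
    package_version = as.character(utils::packageVersion("cscstab")),
    seed = config$seed,
    rates = unclass(config$rates),
    grid_step = config$grid_step, dt = config$dt,
    epsilon_p = config$epsilon_p, K_start = config$K_start, m = config$m,
    stages = list())
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      reason = conditionMessage(e))
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  curve <- config$curve
  if (is.character(curve)) curve <- read_curve(curve)
  if ("curve" %in% config$stages) {
    tryCatch({
      write_curve(curve, file.path(config$output_dir, "curve.csv"))
      manifest$stages$curve <- list(status = "ok",
                                    n_points = length(curve$times),
                                    provenance = curve$provenance)
    }, error = function(e) fail("curve", e))
    out$curve <- curve
  }
  corridors <- NULL
  if ("corridor" %in% config$stages) {
    tryCatch({
      corridors <- scan_corridors(curve, config$rates,
                                   config$grid_step, config$dt)
      if (!corridors$empty)
        write_corridor_csv(corridors,
                           file.path(config$output_dir, "corridors.csv"))
      write_triples_csv(corridors,
                        file.path(config$output_dir,
                                  "admissible_triples.csv"))
      manifest$stages$corridor <- list(
        status = "ok", n_swept = corridors$n_swept,
        n_admissible = nrow(corridors$admissible_triples),
        empty = corridors$empty)
    }, error = function(e) fail("corridor", e))
    out$corridors <- corridors
  }
  traj <- NULL
  if ("extremal" %in% config$stages) {
    tryCatch({
      if (is.null(corridors))
        corridors <- scan_corridors(curve, config$rates,
                                    config$grid_step, config$dt)
      tq <- extremal_trajectory(curve, config$rates, "min_q20",
                                corridors = corridors, dt = config$dt)
      tp <- extremal_trajectory(curve, config$rates, "max_p10",
                                corridors = corridors, dt = config$dt)
      write_prob_trajectory_csv(tq, file.path(config$output_dir,
                                              "trajectory_q20_min.csv"))
      write_prob_trajectory_csv(tp, file.path(config$output_dir,
                                              "trajectory_p10_max.csv"))
      manifest$stages$extremal <- list(
        status = "ok",
        q20_min_triple = as.numeric(attr(tq, "triple")),
        p10_max_triple = as.numeric(attr(tp, "triple")))
      traj <- tq
    }, error = function(e) fail("extremal", e))
    out$extremal <- list(q20_min = traj)
  }
  fset <- NULL
  if ("decompose" %in% config$stages) {
    tryCatch({
      if (is.null(traj))
        stop("decomposition needs the extremal stage", call. = FALSE)
      fset <- select_factor_count(traj, epsilon_p = config$epsilon_p,
                                   K_start = config$K_start, m = config$m,
                                   config = config$relaxation)
      write_factor_set_json(fset, file.path(config$output_dir,
                                            "factors.json"))
      write_factor_curves_csv(fset, file.path(config$output_dir,
                                              "factor_curves.csv"))
      manifest$stages$decompose <- list(
        status = "ok", K = fset$K, epsilon = fset$epsilon,
        accepted = fset$accepted, iterations = fset$iterations)
    }, error = function(e) fail("decompose", e))
    out$factors <- fset
  }
  if ("attribute" %in% config$stages) {
    tryCatch({
      if (is.null(fset))
        stop("attribution needs the decomposition stage", call. = FALSE)
      ranking <- rank_attributions(traj, curve = curve, warm_start = fset,
                                   m = config$m,
                                   config = config$relaxation)
      write_ranking_csv(ranking, file.path(config$output_dir,
                                           "attribution.csv"))
      manifest$stages$attribute <- list(
        status = "ok", n_variants = nrow(ranking),
        best = unlist(ranking[1, startsWith(names(ranking), "u_")]),
        best_epsilon = ranking$epsilon[1])
      out$attribution <- ranking
    }, error = function(e) fail("attribute", e))
  }
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out$manifest <- manifest
  invisible(out)
}
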