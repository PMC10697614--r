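config_defaults <- function() {
  list(
    parameter_file = system.file("extdata", "baseline_params.yaml",
                                 package = "eldergame"),
    modes = game_modes(),
    agents = c("elderly", "government"),
    output_dir = "eldergame-results",
    cost_grid = seq(0, 5, by = 0.1),
    state_grid = seq(-2, 10, by = 1),
    x0 = c(1, 1),
    horizon = 50,
    step = 0.1,
    tolerance = 1e-8,
    seed = 1L,
    digits = 2L)
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration, fills unspecified fields with the
#' package defaults (each applied default is reported via [message()] unless
#' `quiet = TRUE`) and validates: the parameter file must exist, grids must
#' be non-empty, tolerances positive. Unknown keys are an error.
#'
#' @param path config file path, or `NULL` for an all-defaults config.
#' @param quiet suppress default-reporting messages?
#' @return An object of class `run_config`.
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  defaults <- config_defaults()
  user <- if (is.null(path)) list() else parse_config_file(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(user)] <- user
  defaulted <- setdiff(names(defaults), names(user))
  if (!quiet && length(defaulted))
    message("config defaults applied for: ", paste(defaulted, collapse = ", "))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!file.exists(cfg$parameter_file))
    stop("parameter file not found: ", cfg$parameter_file)
  cfg$modes <- vapply(cfg$modes, match_mode, character(1), USE.NAMES = FALSE)
  cfg$agents <- vapply(cfg$agents, match_agent, character(1),
                       USE.NAMES = FALSE)
  for (g in c("cost_grid", "state_grid")) {
    if (length(cfg[[g]]) == 0 || !all(is.finite(cfg[[g]])))
      stop(g, " must be a non-empty finite numeric vector")
  }
  if (any(cfg$cost_grid < 0)) stop("cost_grid values must be nonnegative")
  if (!(cfg$tolerance > 0)) stop("tolerance must be positive")
  if (!(cfg$horizon > 0 && cfg$step > 0)) stop("horizon and step must be positive")
  if (length(cfg$x0) != 2) stop("x0 must have two components")
  cfg$seed <- as.integer(cfg$seed)
  cfg$digits <- as.integer(cfg$digits)
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#'
#' Round-trips through [load_config()]: a written config reloads equal.
#'
#' @param config a `run_config`.
#' @param path output path (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 17L)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported config file extension: .", ext)
  invisible(path)
}

#' Run the full comparison and write a report
#'
#' End-to-end driver: loads the parameter set named by the config, computes
#' the equilibrium table, the value-versus-extra-cost curves and affine
#' decompositions for the special-care modes, the stationarity residual
#' reports, and the mode ranking, then writes everything through
#' [write_report()]. Deterministic: the same config yields byte-identical
#' output files.
#'
#' @param config a `run_config` from [load_config()].
#' @return The manifest from [write_report()], invisibly.
#' @export
run_report <- function(config = load_config(quiet = TRUE)) {
  params <- read_parameters(config$parameter_file)
  results <- list(seed = config$seed, digits = config$digits,
                  equilibria = equilibrium_summary(params, x0 = config$x0))
  curves <- list(); decomps <- list()
  for (mode in setdiff(config$modes, "N")) {
    for (agent in config$agents) {
      x <- if (agent == "elderly") config$x0[[1]] else config$x0[[2]]
      key <- paste(mode, agent, sep = "_")
      curves[[key]] <- cost_curve(params, mode, agent,
                                  grid = config$cost_grid, x0 = x)
      decomps[[key]] <- affine_in_inverse_cost(params, mode, agent, x0 = x)
    }
  }
  results$curves <- curves
  results$decompositions <- decomps
  results$residuals <- verify_equilibrium(params, x_grid = config$state_grid)
  results$ranking <- recommend_mode(params, x0 = config$x0)
  results$welfare_check <- lapply(stats::setNames(config$modes, config$modes),
    function(m) {
      W <- discounted_welfare(params, m, x0 = config$x0)
      V1 <- evaluate_value(value_function(params, m, "elderly"),
                           config$x0[[1]])
      V2 <- evaluate_value(value_function(params, m, "government"),
                           config$x0[[2]])
      c(W, V1 = V1, V2 = V2, gap = max(abs(W[["W1"]] - V1),
                                       abs(W[["W2"]] - V2)))
    })
  invisible(write_report(results, config$output_dir))
}

#' Write analysis results to disk
#'
#' Serializes a results list: one CSV per cost curve and trajectory, JSON
#' for decompositions, residual reports and rankings, the equilibrium table
#' as CSV, and a human-readable `summary.txt` collecting the key computed
#' numbers and the internal cross-check gaps. Writing is deterministic for
#' identical inputs.
#'
#' @param results a list with any of the elements `equilibria` (data.frame),
#'   `curves` (named list of [cost_curve()]s), `decompositions` (named list
#'   of [affine_in_inverse_cost()]s), `residuals` (named list of
#'   [hjb_residual()] reports), `trajectories` (named list of
#'   [simulate_trajectory()] frames), `ranking`, `welfare_check`, `seed`,
#'   `digits`.
#' @param output_dir directory to create/write into.
#' @return Character vector of written file paths (the manifest), invisibly.
#' @export
write_report <- function(results, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  emit_csv <- function(df, name) {
    f <- file.path(output_dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(df), f, row.names = FALSE)
    manifest <<- c(manifest, f)
  }
  emit_json <- function(x, name) {
    f <- file.path(output_dir, paste0(name, ".json"))
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <<- c(manifest, f)
  }
  if (!is.null(results$equilibria)) emit_csv(results$equilibria, "equilibria")
  for (key in names(results$curves))
    emit_csv(results$curves[[key]], paste0("curve_", key))
  for (key in names(results$trajectories))
    emit_csv(results$trajectories[[key]], paste0("trajectory_", key))
  if (length(results$decompositions))
    emit_json(lapply(results$decompositions, unclass), "decompositions")
  if (length(results$residuals))
    emit_json(lapply(results$residuals, function(r)
      r[c("mode", "agent", "max_abs_residual", "argmax_gap")]), "residuals")
  if (!is.null(results$ranking)) emit_json(results$ranking, "ranking")

  digits <- if (is.null(results$digits)) 2L else results$digits
  lines <- c("eldergame analysis summary", "")
  if (!is.null(results$seed)) lines <- c(lines, paste("seed:", results$seed), "")
  if (!is.null(results$equilibria)) {
    lines <- c(lines, "Equilibrium (controls, value coefficients, values):",
               utils::capture.output(print(
                 equilibrium_round(results$equilibria, digits))), "")
  }
  for (key in names(results$decompositions)) {
    d <- results$decompositions[[key]]
    lines <- c(lines, sprintf(
      "decomposition %s: V(c) = %.*f + %.*f / (%g + c)",
      key, digits, d$K0, digits, d$K1, d$base_cost))
  }
  for (key in names(results$curves)) {
    cr <- attr(results$curves[[key]], "crossover")
    lines <- c(lines, sprintf("crossover %s: %s", key,
      if (is.na(cr)) "none (curve never reaches the no-special-care value)"
      else sprintf("extra cost %.4f", cr)))
  }
  if (length(results$residuals)) {
    worst <- max(vapply(results$residuals, `[[`, numeric(1),
                        "max_abs_residual"))
    lines <- c(lines, "",
               sprintf("stationarity check: worst |residual| = %.3e", worst))
  }
  if (length(results$welfare_check)) {
    worst <- max(vapply(results$welfare_check, `[[`, numeric(1), "gap"))
    lines <- c(lines, sprintf(
      "welfare-integral vs closed-form value: worst gap = %.3e", worst))
  }
  f <- file.path(output_dir, "summary.txt")
  writeLines(lines, f)
  manifest <- c(manifest, f)
  invisible(manifest)
}

equilibrium_round <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
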