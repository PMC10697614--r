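#' Reference (baseline) parameter scenario
#'
#' The pinned scenario used throughout the package's numerical analysis:
#' `rho = 0.9`, `delta1 = delta2 = 0.1`, `b = 3`, `l1 = l2 = 1`,
#' `c_I = 1.5`, `c_M = c_F = 2`, `beta = 3.49`, `lambda1 = lambda2 = 1`,
#' `lambda3 = lambda4 = 2`, `beta_H = 28.7`, `beta_G = 7.71`, together with
#' the reference settings of the mode-specific knobs (`alpha1 = 0.5`,
#' `b_G = 1`, `lambda_H = lambda_G = 0.3`, `c_H = c_G = 1`). Identical to
#' `game_parameters()` with all defaults; also shipped as
#' `inst/extdata/baseline_params.yaml`.
#'
#' @return A validated `game_parameters` object.
#' @export
baseline_parameters <- function() {
  game_parameters()
}

#' Sampling specification for random admissible scenarios
#'
#' @param seed integer RNG seed; generation is reproducible per seed.
#' @param count number of scenarios to draw.
#' @param ranges named list of `c(lo, hi)` sampling intervals per parameter;
#'   defaults to [default_scenario_ranges()].
#' @param max_tries rejection-sampling cap per scenario.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1L, count = 10L,
                          ranges = default_scenario_ranges(),
                          max_tries = 1000L) {
  stopifnot(length(seed) == 1, is.finite(seed),
            count >= 1, max_tries >= 1)
  fields <- parameter_fields()
  if (!setequal(names(ranges), fields))
    stop("ranges must name exactly the game parameter fields")
  for (f in fields) {
    r <- ranges[[f]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2] || r[1] < 0)
      stop("invalid range for ", f)
  }
  structure(list(seed = as.integer(seed), count = as.integer(count),
                 ranges = ranges, max_tries = as.integer(max_tries)),
            class = "scenario_spec")
}

#' Default sampling ranges: half to double the reference value
#'
#' Each parameter is drawn uniformly from `[0.5, 2]` times its reference
#' value, with `rho` capped at 1; wide enough to exercise every sign
#' constraint, narrow enough to avoid numerical extremes.
#'
#' @return Named list of `c(lo, hi)` intervals.
#' @export
default_scenario_ranges <- function() {
  base <- unlist(unclass(baseline_parameters()))
  ranges <- lapply(base, function(v) c(0.5 * v, 2 * v))
  ranges$rho <- c(0.5 * base[["rho"]], min(1, 2 * base[["rho"]]))
  ranges
}

#' Draw random admissible parameter scenarios
#'
#' Samples each parameter uniformly from its range and keeps only sets that
#' pass [validate_parameters()] (rejection sampling; infeasible ranges are
#' reported once the per-scenario try cap is exceeded). Output is
#' reproducible: the same spec yields the same list, and the caller's RNG
#' state is left untouched.
#'
#' @param spec a [scenario_spec()].
#' @return A list of `spec$count` validated `game_parameters` objects.
#' @export
#' @examples
#' ps <- random_scenarios(scenario_spec(seed = 42, count = 3))
random_scenarios <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  fields <- parameter_fields()
  draw_one <- function() {
    for (i in seq_len(spec$max_tries)) {
      vals <- lapply(fields, function(f) {
        r <- spec$ranges[[f]]
        stats::runif(1, r[1], r[2])
      })
      names(vals) <- fields
      p <- structure(vals, class = "game_parameters")
      ok <- tryCatch({ validate_parameters(p); TRUE },
                     error = function(e) FALSE)
      if (ok) return(p)
    }
    stop("rejection rate too high: no admissible scenario in ",
         spec$max_tries, " tries; check the ranges")
  }
  lapply(seq_len(spec$count), function(i) draw_one())
}
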