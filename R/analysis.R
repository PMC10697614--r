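extra_cost_field <- function(mode) {
  mode <- match_mode(mode)
  if (mode == "N")
    stop("mode N has no extra cost; use mode H or G")
  if (mode == "H") "c_H" else "c_G"
}

set_extra_cost <- function(params, mode, extra) {
  params[[extra_cost_field(mode)]] <- extra
  params
}

value_at_extra <- function(params, mode, agent, extra, x0) {
  vapply(extra, function(ci) {
    vf <- value_function(set_extra_cost(params, mode, ci), mode, agent)
    evaluate_value(vf, x0)
  }, numeric(1))
}

#' Affine-in-inverse-cost decomposition of a value function
#'
#' Viewed as a function of the extra cost `c` of a special-care mode, each
#' equilibrium value is exactly `K0 + K1 / (base + c)`: the quadratic control
#' costs make every cost-dependent term scale with the reciprocal of the
#' total cost coefficient. Closed forms, with `a1 = l1/(rho + delta1)`,
#' `a2 = l2/(rho + delta2)` and `S = b_eff + a1 log_efficacy`:
#' \describe{
#'   \item{elderly}{`K0 = a1 x0 + c_inf_eff^2 / (4 lambda1 a1 rho)`,
#'     `K1 = S^2 / (2 rho)`, base `c_M`.}
#'   \item{government}{`K0 = a2 x0`, `K1 = a2^2 kappa^2 / (2 rho)`,
#'     base `c_F`.}
#' }
#' `K1 > 0` always, so the value is strictly decreasing and convex in the
#' extra cost, with horizontal asymptote `K0`.
#'
#' @inheritParams optimal_controls
#' @param mode `"H"` or `"G"` (mode N has no extra cost and is rejected).
#' @param agent `"elderly"` or `"government"`.
#' @param x0 the agent's own initial state (scalar).
#' @return An object of class `affine_decomp`: `mode`, `agent`, `K0`, `K1`,
#'   `base_cost`.
#' @export
#' @examples
#' p <- game_parameters(alpha1 = 0.5)
#' affine_in_inverse_cost(p, "H", "elderly")  # K0 = 1.2778, K1 = 23.488
affine_in_inverse_cost <- function(params, mode, agent, x0 = 1) {
  agent <- match_agent(agent)
  base <- if (agent == "elderly") params$c_M else params$c_F
  field <- extra_cost_field(mode)  # rejects mode N
  validate_parameters(params)
  eff <- effective_params(params, mode)
  rho <- eff$rho
  if (agent == "elderly") {
    a1 <- value_slope(eff, "elderly")
    S <- eff$b_eff + a1 * eff$log_efficacy
    K0 <- a1 * x0 + eff$c_inf_eff^2 / (4 * eff$lambda1 * a1 * rho)
    K1 <- S^2 / (2 * rho)
  } else {
    a2 <- value_slope(eff, "government")
    K0 <- a2 * x0
    K1 <- a2^2 * eff$kappa^2 / (2 * rho)
  }
  structure(list(mode = eff$mode, agent = agent, K0 = K0, K1 = K1,
                 base_cost = base, x0 = x0),
            class = "affine_decomp")
}

#' @export
print.affine_decomp <- function(x, digits = 4, ...) {
  cat(sprintf("value decomposition [mode %s, %s]: V(c) = %.*g + %.*g / (%g + c)\n",
              x$mode, x$agent, digits, x$K0, digits, x$K1, x$base_cost))
  invisible(x)
}

#' Predict a value from its decomposition
#'
#' @param decomp an [affine_in_inverse_cost()] result.
#' @param extra extra-cost value(s), >= 0.
#' @return `K0 + K1 / (base_cost + extra)`.
#' @export
predict_decomposition <- function(decomp, extra) {
  decomp$K0 + decomp$K1 / (decomp$base_cost + extra)
}

#' Value-versus-extra-cost curve
#'
#' Evaluates a special-care mode's equilibrium value on a grid of extra
#' costs, together with the no-special-care value at the same state as the
#' horizontal reference and, when the curve crosses it, the crossover cost.
#'
#' @inheritParams affine_in_inverse_cost
#' @param grid nonnegative extra-cost values (non-empty).
#' @return A data.frame of class `cost_curve` with columns `extra_cost`,
#'   `value`, `baseline`; attributes `mode`, `agent`, `crossover`.
#' @export
cost_curve <- function(params, mode, agent, grid = seq(0, 5, by = 0.1),
                       x0 = 1) {
  if (length(grid) == 0) stop("empty extra-cost grid")
  if (any(grid < 0)) stop("extra costs must be nonnegative")
  agent <- match_agent(agent)
  values <- value_at_extra(params, mode, agent, grid, x0)
  baseline <- evaluate_value(value_function(params, "N", agent), x0)
  out <- data.frame(extra_cost = grid, value = values, baseline = baseline)
  class(out) <- c("cost_curve", "data.frame")
  attr(out, "mode") <- match_mode(mode)
  attr(out, "agent") <- agent
  attr(out, "crossover") <- crossover_cost(params, mode, agent, x0)
  out
}

#' Crossover extra cost against no special care
#'
#' The unique extra cost at which a special-care mode's value falls to the
#' no-special-care value: the root of `K0 + K1/(base + c) = V_N`. In closed
#' form `c* = K1 / (V_N - K0) - base` when `V_N > K0`; when `V_N <= K0` the
#' strictly decreasing curve never reaches the reference and `NA` is
#' returned. A bisection root ([stats::uniroot()] on a bracket grown from the
#' closed form) is available as an independent cross-check.
#'
#' @inheritParams affine_in_inverse_cost
#' @param method `"closed_form"` or `"bisection"`.
#' @return The crossover extra cost (possibly negative if the mode is already
#'   dominated at zero extra cost), or `NA_real_` if no crossing exists.
#' @export
crossover_cost <- function(params, mode, agent, x0 = 1,
                           method = c("closed_form", "bisection")) {
  method <- match.arg(method)
  agent <- match_agent(agent)
  dc <- affine_in_inverse_cost(params, mode, agent, x0)
  V_N <- evaluate_value(value_function(params, "N", agent), x0)
  if (V_N <= dc$K0) return(NA_real_)
  root <- dc$K1 / (V_N - dc$K0) - dc$base_cost
  if (method == "closed_form") return(root)
  f <- function(c) predict_decomposition(dc, c) - V_N
  lo <- root - max(1, abs(root)); hi <- root + max(1, abs(root))
  lo <- max(lo, -dc$base_cost + 1e-9)  # keep total cost positive
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Sensitivity of a value decomposition to one model parameter
#'
#' Recomputes the affine decomposition along a sweep of one of the
#' mode-defining parameters and reports the direction of the trend, making
#' the comparative statics of the model checkable at equation level: the
#' elderly constant `K0` falls as home care removes more cross-infection
#' harm (`alpha1`), and the government coefficient `K1` grows with the
#' mode's extra credibility rate (`lambda_H`, `lambda_G`) or the elderly
#' coefficient with the green-channel benefit (`b_G`).
#'
#' @inheritParams affine_in_inverse_cost
#' @param parameter_name one of `"alpha1"`, `"lambda_H"`, `"lambda_G"`,
#'   `"b_G"`.
#' @param values sweep values for that parameter.
#' @return A data.frame with columns `parameter`, `value` (of the swept
#'   parameter), `K0`, `K1`, `value_at_zero_extra`; attributes `K0_trend`
#'   and `K1_trend` in `c(-1, 0, 1)`.
#' @export
sensitivity_table <- function(params, mode, agent, parameter_name, values,
                              x0 = 1) {
  parameter_name <- match.arg(parameter_name,
                              c("alpha1", "lambda_H", "lambda_G", "b_G"))
  stopifnot(length(values) >= 1)
  rows <- lapply(values, function(v) {
    p <- params
    p[[parameter_name]] <- v
    dc <- affine_in_inverse_cost(p, mode, agent, x0)
    data.frame(parameter = parameter_name, value = v,
               K0 = dc$K0, K1 = dc$K1,
               value_at_zero_extra = predict_decomposition(dc, 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  trend <- function(y) {
    d <- diff(y)
    if (all(d > 0)) 1L else if (all(d < 0)) -1L else 0L
  }
  if (nrow(out) > 1) {
    attr(out, "K0_trend") <- trend(out$K0)
    attr(out, "K1_trend") <- trend(out$K1)
  }
  out
}

#' Rank the three modes per agent at given extra costs
#'
#' Computes each agent's equilibrium value under all three modes with the
#' stated extra costs and returns the modes in decreasing value order, ties
#' broken by the fixed order N < H < G.
#'
#' @inheritParams optimal_controls
#' @param c_H,c_G extra costs to evaluate at (default: those in `params`).
#' @param x0 initial state `c(x1, x2)`.
#' @return A list with one data.frame per agent (`elderly`, `government`),
#'   columns `mode`, `value`, `rank`.
#' @export
recommend_mode <- function(params, c_H = params$c_H, c_G = params$c_G,
                           x0 = c(1, 1)) {
  p <- params
  p$c_H <- c_H
  p$c_G <- c_G
  validate_parameters(p)
  out <- list()
  for (agent in c("elderly", "government")) {
    x <- if (agent == "elderly") x0[[1]] else x0[[2]]
    vals <- vapply(game_modes(), function(m)
      evaluate_value(value_function(p, m, agent), x), numeric(1))
    # order by value descending; ties resolved by the fixed N < H < G order,
    # which is the natural ordering of game_modes()
    ord <- order(-vals, seq_along(vals))
    out[[agent]] <- data.frame(mode = game_modes()[ord],
                               value = vals[ord],
                               rank = seq_along(vals),
                               row.names = NULL,
                               stringsAsFactors = FALSE)
  }
  out
}
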