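#' Hamiltonian of one agent at fixed value-function slope
#'
#' Instantaneous utility plus `slope` times the own-state drift. For the
#' elderly the controls are (M, I); for the government, F. The state terms
#' (`l x` and `-delta x`) are included so the residual check can exercise the
#' full stationary equation.
#' @keywords internal
hamiltonian_value <- function(eff, slope, agent, controls, state) {
  if (agent == "elderly") {
    elderly_utility_rate(eff, controls, state) +
      slope * health_drift(eff, controls, state)
  } else {
    government_utility_rate(eff, controls, state) +
      slope * credibility_drift(eff, controls, state)
  }
}

argmax_brackets <- function(eff, slope, agent) {
  # By concavity the optimum is interior to any bracket containing the
  # analytic stationary point; widen it fourfold plus a unit margin.
  if (agent == "elderly") {
    M_star <- (eff$b_eff + slope * eff$log_efficacy) / eff$c_treat_eff
    I_star <- -eff$c_inf_eff / (2 * eff$lambda1 * slope)
    list(M = c(0, 4 * abs(M_star) + 1),
         I = c(-4 * abs(I_star) - 1, 4 * abs(I_star) + 1))
  } else {
    F_star <- eff$kappa * slope / eff$c_gov_eff
    list(F = c(min(0, 4 * F_star - 1), 4 * abs(F_star) + 1))
  }
}

#' Numeric maximizer of the Hamiltonian
#'
#' Independent check on the closed-form first-order conditions: maximizes
#' instantaneous utility plus `slope` times the drift over the agent's own
#' controls by bounded one-dimensional optimization (the Hamiltonian is
#' additively separable and strictly concave in each control). A dense-grid
#' scan is available as a slower second oracle.
#'
#' @param eff [effective_params()] for one mode.
#' @param slope value-function slope to use as the costate.
#' @param agent `"elderly"` or `"government"`.
#' @param method `"optimize"` (Brent-type bounded search) or `"grid"`
#'   (dense scan, step `grid_step`).
#' @param tol convergence tolerance passed to [stats::optimize()].
#' @param grid_step scan step for `method = "grid"`.
#' @return A [game_controls()] triple (unused control is 0 for the
#'   government's, NA-free for convenience).
#' @export
hamiltonian_argmax <- function(eff, slope, agent,
                               method = c("optimize", "grid"),
                               tol = .Machine$double.eps^0.5,
                               grid_step = 1e-4) {
  agent <- match_agent(agent)
  method <- match.arg(method)
  stopifnot(slope > 0)
  br <- argmax_brackets(eff, slope, agent)
  state <- state_point(0, 0)
  maximize <- function(f, bracket) {
    if (method == "optimize") {
      opt <- stats::optimize(f, interval = bracket, maximum = TRUE, tol = tol)
      opt$maximum
    } else {
      grid <- seq(bracket[1], bracket[2], by = grid_step)
      grid[which.max(vapply(grid, f, numeric(1)))]
    }
  }
  if (agent == "elderly") {
    M_hat <- maximize(function(m)
      hamiltonian_value(eff, slope, agent, game_controls(M = m), state),
      br$M)
    I_hat <- maximize(function(i)
      hamiltonian_value(eff, slope, agent, game_controls(I = i), state),
      br$I)
    game_controls(M = M_hat, I = I_hat)
  } else {
    F_hat <- maximize(function(f)
      hamiltonian_value(eff, slope, agent, game_controls(F = f), state),
      br$F)
    game_controls(F = F_hat)
  }
}

#' Residual of the stationary dynamic-programming equation
#'
#' For each state value `x` in `x_grid`, computes
#' `rho V(x) - max over controls of [utility rate + V'(x) * drift]`
#' with the analytic affine value function `V`. For the correct slope and
#' intercept the residual is identically zero (both sides are affine in `x`
#' with equal slope), so the maximum absolute residual over the grid is a
#' sharp correctness check. The inner maximization is numeric
#' ([hamiltonian_argmax()]), keeping the check independent of the closed-form
#' controls; `argmax_gap` reports the worst distance between the numeric and
#' analytic optimal controls.
#'
#' @inheritParams optimal_controls
#' @param agent `"elderly"` or `"government"`.
#' @param x_grid numeric vector of state values (non-empty).
#' @return An object of class `residual_report`: `mode`, `agent`, `grid`,
#'   `residuals`, `max_abs_residual`, `argmax_gap`.
#' @export
hjb_residual <- function(params, mode, agent, x_grid = seq(-2, 10)) {
  agent <- match_agent(agent)
  stopifnot(length(x_grid) >= 1, all(is.finite(x_grid)))
  validate_parameters(params)
  eff <- effective_params(params, mode)
  vf <- value_function(params, mode, agent)
  ctl_num <- hamiltonian_argmax(eff, vf$slope, agent)
  ctl_ana <- optimal_controls(params, mode)
  gap <- if (agent == "elderly") {
    max(abs(ctl_num$M - ctl_ana$M), abs(ctl_num$I - ctl_ana$I))
  } else {
    abs(ctl_num$F - ctl_ana$F)
  }
  residuals <- vapply(x_grid, function(x) {
    state <- if (agent == "elderly") state_point(x1 = x, x2 = 0)
             else state_point(x1 = 0, x2 = x)
    h <- hamiltonian_value(eff, vf$slope, agent, ctl_num, state)
    eff$rho * evaluate_value(vf, x) - h
  }, numeric(1))
  structure(list(mode = eff$mode, agent = agent, grid = x_grid,
                 residuals = residuals,
                 max_abs_residual = max(abs(residuals)),
                 argmax_gap = gap),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf(
    "HJB residual [mode %s, %s]: max|residual| = %.3e over %d grid points; argmax gap = %.3e\n",
    x$mode, x$agent, x$max_abs_residual, length(x$grid), x$argmax_gap))
  invisible(x)
}

#' Residual reports for every (mode, agent) pair
#'
#' @inheritParams hjb_residual
#' @return A list of six `residual_report`s, named `"N.elderly"`, ...
#' @export
verify_equilibrium <- function(params, x_grid = seq(-2, 10)) {
  out <- list()
  for (mode in game_modes())
    for (agent in c("elderly", "government"))
      out[[paste(mode, agent, sep = ".")]] <-
        hjb_residual(params, mode, agent, x_grid)
  out
}
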