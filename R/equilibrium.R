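#' Marginal value of the own state
#'
#' Under the affine value ansatz `V(x) = a x + k`, the slope solves the
#' linear part of the stationary dynamic-programming equation:
#' `rho a = l - a delta`, i.e. `a = l / (rho + delta)` with the
#' agent-appropriate welfare weight and decay rate.
#' @keywords internal
value_slope <- function(eff, agent) {
  agent <- match_agent(agent)
  if (agent == "elderly") eff$l1 / (eff$rho + eff$delta1)
  else eff$l2 / (eff$rho + eff$delta2)
}

#' Feedback Nash equilibrium controls
#'
#' Closed-form maximizers of each agent's Hamiltonian under the affine value
#' ansatz, with `a1 = l1 / (rho + delta1)` and `a2 = l2 / (rho + delta2)`:
#' \deqn{M^* = (b_{eff} + a_1 \ln(\cdot)) / c_{treat},\quad
#'       I^* = -c_{inf} / (2 \lambda_1 a_1),\quad
#'       F^* = \kappa a_2 / c_{gov}.}
#' The controls are constant in time and state; stationarity follows from the
#' affine value functions, whose state-derivative is a constant. The
#' equilibrium infection level is negative whenever the effective infection
#' harm is positive; it is reported exactly as the closed form gives it,
#' without clipping.
#'
#' @param params validated [game_parameters()].
#' @param mode one of `"N"`, `"H"`, `"G"`.
#' @param allow_degenerate passed to [validate_parameters()].
#' @return A [game_controls()] triple with attribute `mode`.
#' @export
#' @examples
#' optimal_controls(game_parameters(), "N")  # M ~ 2.2509, I = -0.75, F = 0.5
optimal_controls <- function(params, mode, allow_degenerate = FALSE) {
  validate_parameters(params, allow_degenerate = allow_degenerate)
  eff <- effective_params(params, mode)
  a1 <- value_slope(eff, "elderly")
  a2 <- value_slope(eff, "government")
  ctl <- game_controls(
    M = (eff$b_eff + a1 * eff$log_efficacy) / eff$c_treat_eff,
    I = -eff$c_inf_eff / (2 * eff$lambda1 * a1),
    F = eff$kappa * a2 / eff$c_gov_eff)
  attr(ctl, "mode") <- eff$mode
  ctl
}

#' Equilibrium value function
#'
#' The affine value function `V(x) = slope * x + intercept` of one agent in
#' one mode. The slope is `l / (rho + delta)`; the intercept capitalizes the
#' state-independent part of the equilibrium flow:
#' \deqn{k_1 = \frac{1}{\rho}\left[b_{eff} M^* - c_{inf} I^*
#'   - \tfrac{c_{treat}}{2} M^{*2}
#'   + a_1(-\lambda_1 I^{*2} + \ln(\cdot) M^*)\right]}
#' for the elderly and
#' \deqn{k_2 = \frac{1}{\rho}\left[-\tfrac{c_{gov}}{2} F^{*2}
#'   + a_2 \kappa F^*\right]}
#' for the government. Computing intercepts from this generic
#' effective-parameter formula (rather than a mode-by-mode transcription)
#' keeps all three modes on one code path; the closed forms simplify to
#' \eqn{k_1 = [S^2/(2 c_{treat}) + c_{inf}^2/(4\lambda_1 a_1)]/\rho} with
#' \eqn{S = b_{eff} + a_1 \ln(\cdot)}, and
#' \eqn{k_2 = a_2^2 \kappa^2 / (2 \rho c_{gov})}.
#'
#' @inheritParams optimal_controls
#' @param agent `"elderly"` or `"government"`.
#' @return An object of class `value_function` with fields `mode`, `agent`,
#'   `slope`, `intercept`.
#' @export
value_function <- function(params, mode, agent,
                           allow_degenerate = FALSE) {
  agent <- match_agent(agent)
  validate_parameters(params, allow_degenerate = allow_degenerate)
  eff <- effective_params(params, mode)
  ctl <- optimal_controls(params, mode, allow_degenerate = allow_degenerate)
  slope <- value_slope(eff, agent)
  if (agent == "elderly") {
    flow <- eff$b_eff * ctl$M - eff$c_inf_eff * ctl$I -
      (eff$c_treat_eff / 2) * ctl$M^2 +
      slope * (-eff$lambda1 * ctl$I^2 + eff$log_efficacy * ctl$M)
  } else {
    flow <- -(eff$c_gov_eff / 2) * ctl$F^2 + slope * eff$kappa * ctl$F
  }
  structure(list(mode = eff$mode, agent = agent,
                 slope = slope, intercept = flow / eff$rho),
            class = "value_function")
}

#' @export
print.value_function <- function(x, ...) {
  cat(sprintf("value function [mode %s, %s]: V(x) = %.6g x + %.6g\n",
              x$mode, x$agent, x$slope, x$intercept))
  invisible(x)
}

#' Evaluate an affine value function
#'
#' @param vf a [value_function()].
#' @param state a [state_point()], or a single number taken as the
#'   agent-appropriate state coordinate.
#' @return `slope * x + intercept`.
#' @export
evaluate_value <- function(vf, state) {
  x <- if (inherits(state, "state_point")) {
    if (vf$agent == "elderly") state$x1 else state$x2
  } else {
    stopifnot(is.numeric(state))
    state
  }
  vf$slope * x + vf$intercept
}

#' Tabulate the equilibrium across modes and agents
#'
#' One row per (mode, agent) with the equilibrium controls, the value-function
#' coefficients and the value at the given initial state. Suitable for JSON
#' or CSV serialization at full precision; set `digits` for a rounded view.
#'
#' @inheritParams optimal_controls
#' @param x0 initial state, `c(x1, x2)`.
#' @param digits optional rounding for reporting (half-even, as in [round()]).
#' @return A data.frame with columns `mode`, `agent`, `M`, `I`, `F`, `slope`,
#'   `intercept`, `value`.
#' @export
equilibrium_summary <- function(params, x0 = c(1, 1), digits = NULL) {
  rows <- list()
  for (mode in game_modes()) {
    ctl <- optimal_controls(params, mode)
    for (agent in c("elderly", "government")) {
      vf <- value_function(params, mode, agent)
      x <- if (agent == "elderly") x0[[1]] else x0[[2]]
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, agent = agent, M = ctl$M, I = ctl$I, F = ctl$F,
        slope = vf$slope, intercept = vf$intercept,
        value = evaluate_value(vf, x),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out
}
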