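#' Control triple
#'
#' The three instantaneous decisions of the game: the medical-service level
#' `M` received by the elderly, the infection level `I` chosen (tolerated) by
#' the elderly, and the government resource input `F`. In the feedback
#' equilibrium all three are constants because the value functions are affine
#' in the state.
#'
#' @param M medical-service level (>= 0 at validated equilibria).
#' @param I infection level; the equilibrium closed form is negative and is
#'   reported as-is.
#' @param F government resource input (>= 0 at validated equilibria).
#' @return An object of class `game_controls`.
#' @export
game_controls <- function(M = 0, I = 0, F = 0) {
  stopifnot(is.finite(M), is.finite(I), is.finite(F))
  structure(list(M = M, I = I, F = F), class = "game_controls")
}

#' @export
print.game_controls <- function(x, ...) {
  cat(sprintf("controls: M = %.6g, I = %.6g, F = %.6g\n", x$M, x$I, x$F))
  invisible(x)
}

#' State point
#'
#' @param x1 elderly health / satisfaction state.
#' @param x2 government credibility state.
#' @param t time (>= 0).
#' @return An object of class `state_point`.
#' @export
state_point <- function(x1 = 1, x2 = 1, t = 0) {
  stopifnot(is.finite(x1), is.finite(x2), is.finite(t), t >= 0)
  structure(list(x1 = x1, x2 = x2, t = t), class = "state_point")
}

#' Instantaneous elderly welfare rate
#'
#' `b_eff * M - c_inf_eff * I - (c_treat_eff / 2) * M^2 + l1 * x1`:
#' service benefit, minus infection harm, minus quadratic treatment cost,
#' plus the psychological value of the current health state.
#'
#' @param eff [effective_params()] for one mode.
#' @param controls a [game_controls()] triple (only `M` and `I` enter).
#' @param state a [state_point()] (only `x1` enters).
#' @return Utility per unit time (scalar).
#' @export
elderly_utility_rate <- function(eff, controls, state = state_point()) {
  eff$b_eff * controls$M - eff$c_inf_eff * controls$I -
    (eff$c_treat_eff / 2) * controls$M^2 + eff$l1 * state$x1
}

#' Instantaneous government welfare rate
#'
#' `-(c_gov_eff / 2) * F^2 + l2 * x2`: quadratic resource cost against the
#' value of current credibility.
#'
#' @inheritParams elderly_utility_rate
#' @return Utility per unit time (scalar).
#' @export
government_utility_rate <- function(eff, controls, state = state_point()) {
  -(eff$c_gov_eff / 2) * controls$F^2 + eff$l2 * state$x2
}

#' Drift of the elderly health state
#'
#' `-lambda1 * I^2 + log_efficacy * M - delta1 * x1`: infection damage,
#' treatment gain (logarithmic in total efficacy), exponential satisfaction
#' decay.
#'
#' @inheritParams elderly_utility_rate
#' @return d x1 / dt (scalar).
#' @export
health_drift <- function(eff, controls, state = state_point()) {
  -eff$lambda1 * controls$I^2 + eff$log_efficacy * controls$M -
    eff$delta1 * state$x1
}

#' Drift of the government credibility state
#'
#' `kappa * F - delta2 * x2`: credibility gained from resource input against
#' exponential credibility decay.
#'
#' @inheritParams elderly_utility_rate
#' @return d x2 / dt (scalar).
#' @export
credibility_drift <- function(eff, controls, state = state_point()) {
  eff$kappa * controls$F - eff$delta2 * state$x2
}
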