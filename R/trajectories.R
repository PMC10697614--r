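#' Steady states under equilibrium play
#'
#' With constant equilibrium controls both state equations are linear with
#' decay `delta`, so each state relaxes exponentially to
#' `x1_ss = (-lambda1 I*^2 + log_efficacy M*) / delta1` and
#' `x2_ss = kappa F* / delta2`.
#'
#' @inheritParams optimal_controls
#' @return Named numeric vector `c(x1_ss, x2_ss)`.
#' @export
steady_states <- function(params, mode) {
  eff <- effective_params(validate_parameters(params), mode)
  ctl <- optimal_controls(params, mode)
  c(x1_ss = (-eff$lambda1 * ctl$I^2 + eff$log_efficacy * ctl$M) / eff$delta1,
    x2_ss = eff$kappa * ctl$F / eff$delta2)
}

# x(t) = x_ss + (x0 - x_ss) exp(-delta t), per state coordinate
closed_form_states <- function(params, mode, x0, times) {
  eff <- effective_params(params, mode)
  ss <- steady_states(params, mode)
  list(x1 = ss[["x1_ss"]] + (x0[[1]] - ss[["x1_ss"]]) * exp(-eff$delta1 * times),
       x2 = ss[["x2_ss"]] + (x0[[2]] - ss[["x2_ss"]]) * exp(-eff$delta2 * times))
}

#' Simulate the state under equilibrium controls
#'
#' Integrates the two linear state equations with the constant equilibrium
#' controls, either via the exact exponential solution (`method = "exact"`,
#' the default fast path) or with adaptive ODE integration
#' (`method = "ode"`, [deSolve::ode()] with `lsoda`, relative tolerance
#' `1e-9`); both paths agree to integrator tolerance and the second guards
#' the first.
#'
#' @inheritParams optimal_controls
#' @param x0 initial state `c(x1, x2)`.
#' @param horizon final time (> 0).
#' @param step output grid spacing (> 0).
#' @param method `"exact"` or `"ode"`.
#' @return A data.frame of class `game_trajectory` with columns `t`, `x1`,
#'   `x2`, `M`, `I`, `F`; the constant controls are repeated per row so the
#'   table serializes directly to CSV.
#' @export
simulate_trajectory <- function(params, mode, x0 = c(1, 1),
                                horizon = 50, step = 0.1,
                                method = c("exact", "ode")) {
  method <- match.arg(method)
  if (!(is.numeric(horizon) && horizon > 0))
    stop("horizon must be positive")
  if (!(is.numeric(step) && step > 0 && step <= horizon))
    stop("step must be positive and no larger than horizon")
  validate_parameters(params)
  eff <- effective_params(params, mode)
  ctl <- optimal_controls(params, mode)
  times <- seq(0, horizon, by = step)
  if (method == "exact") {
    st <- closed_form_states(params, mode, x0, times)
    x1 <- st$x1; x2 <- st$x2
  } else {
    rhs <- function(t, y, parms) {
      s <- state_point(x1 = y[1], x2 = y[2], t = t)
      list(c(health_drift(eff, ctl, s), credibility_drift(eff, ctl, s)))
    }
    sol <- deSolve::ode(y = c(x1 = x0[[1]], x2 = x0[[2]]), times = times,
                        func = rhs, parms = NULL, method = "lsoda",
                        rtol = 1e-9, atol = 1e-12)
    x1 <- sol[, "x1"]; x2 <- sol[, "x2"]
  }
  out <- data.frame(t = times, x1 = x1, x2 = x2,
                    M = ctl$M, I = ctl$I, F = ctl$F)
  class(out) <- c("game_trajectory", "data.frame")
  attr(out, "mode") <- eff$mode
  out
}

#' Discounted welfare along the equilibrium path
#'
#' Numerically integrates each agent's discounted utility rate along the
#' exact state trajectory:
#' \deqn{W = \int_0^\infty e^{-\rho t}\, u(M^*, I^*, F^*, x(t))\, dt.}
#' Quadrature runs on `[0, T]` with `T` chosen so `exp(-rho T) <
#' tolerance / 10`; the tail beyond `T` is geometric plus a single
#' exponential and is added as an analytic correction, so the truncation
#' error is bounded by the quadrature tolerance alone. By construction of
#' the affine value functions, `W` equals [evaluate_value()] at the initial
#' state; the agreement is the package's headline internal-consistency
#' check.
#'
#' @inheritParams optimal_controls
#' @param x0 initial state `c(x1, x2)`.
#' @param tolerance truncation/quadrature tolerance (> 0).
#' @return Named numeric vector `c(W1, W2)` (elderly, government).
#' @export
discounted_welfare <- function(params, mode, x0 = c(1, 1),
                               tolerance = 1e-10) {
  stopifnot(is.numeric(tolerance), tolerance > 0)
  validate_parameters(params)
  eff <- effective_params(params, mode)
  ctl <- optimal_controls(params, mode)
  ss <- steady_states(params, mode)
  T_end <- -log(tolerance / 10) / eff$rho

  u1_const <- elderly_utility_rate(eff, ctl, state_point(0, 0))
  u2_const <- government_utility_rate(eff, ctl, state_point(0, 0))

  one_agent <- function(u_const, l, x0i, x_ss, delta) {
    f <- function(t) {
      x <- x_ss + (x0i - x_ss) * exp(-delta * t)
      exp(-eff$rho * t) * (u_const + l * x)
    }
    head_part <- stats::integrate(f, 0, T_end, rel.tol = tolerance,
                                  abs.tol = tolerance,
                                  subdivisions = 1000L)$value
    # analytic tail: constant part + decaying exponential part
    tail_part <- exp(-eff$rho * T_end) * (u_const + l * x_ss) / eff$rho +
      l * (x0i - x_ss) * exp(-(eff$rho + delta) * T_end) / (eff$rho + delta)
    head_part + tail_part
  }
  c(W1 = one_agent(u1_const, eff$l1, x0[[1]], ss[["x1_ss"]], eff$delta1),
    W2 = one_agent(u2_const, eff$l2, x0[[2]], ss[["x2_ss"]], eff$delta2))
}
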