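test_that("closed-form equilibrium controls match the reference scenario", {
  p <- baseline_parameters()
  ctl <- optimal_controls(p, "N")
  expect_equal(ctl$M, (3 + log(4.49)) / 2, tolerance = 1e-12)
  expect_equal(ctl$I, -0.75)
  expect_equal(ctl$F, 0.5)
  # home care with alpha1 = c_I removes all effective infection harm
  expect_equal(optimal_controls(game_parameters(alpha1 = 1.5), "H")$I, 0)
  # no credibility gain, no resource spend (degenerate regime on request)
  p0 <- game_parameters(lambda_H = 0, lambda2 = 1e-300, validate = FALSE)
  expect_equal(optimal_controls(p0, "H", allow_degenerate = TRUE)$F, 0,
               tolerance = 1e-290)
})

test_that("controls satisfy the first-order conditions of the Hamiltonian", {
  p <- baseline_parameters()
  for (mode in game_modes()) {
    eff <- effective_params(p, mode)
    ctl <- optimal_controls(p, mode)
    a1 <- eff$l1 / (eff$rho + eff$delta1)
    a2 <- eff$l2 / (eff$rho + eff$delta2)
    s0 <- state_point(0, 0)
    H1 <- function(m, i) elderly_utility_rate(eff, game_controls(m, i), s0) +
      a1 * health_drift(eff, game_controls(m, i), s0)
    H2 <- function(f) government_utility_rate(eff, game_controls(F = f), s0) +
      a2 * credibility_drift(eff, game_controls(F = f), s0)
    expect_lt(abs(fd(function(m) H1(m, ctl$I), ctl$M)), 1e-8)
    expect_lt(abs(fd(function(i) H1(ctl$M, i), ctl$I)), 1e-8)
    expect_lt(abs(fd(H2, ctl$F)), 1e-8)
  }
})

test_that("value functions have slope l/(rho+delta) and the right intercepts", {
  p <- baseline_parameters()
  for (mode in game_modes()) {
    v1 <- value_function(p, mode, "elderly")
    v2 <- value_function(p, mode, "government")
    expect_equal(v1$slope, p$l1 / (p$rho + p$delta1))
    expect_equal(v2$slope, p$l2 / (p$rho + p$delta2))
  }
  # frozen reference values
  expect_equal(evaluate_value(value_function(p, "N", "government"), 1),
               1.277778, tolerance = 1e-6)
  expect_equal(evaluate_value(value_function(p, "N", "elderly"), 1),
               7.254633, tolerance = 1e-6)
  # with no state weight the value is the capitalized flow only
  v0 <- value_function(game_parameters(l1 = 1e-12), "N", "elderly")
  expect_equal(v0$slope, 1e-12 / (0.9 + 0.1))
})

test_that("evaluate_value is affine and reads the agent's own coordinate", {
  vf <- structure(list(mode = "N", agent = "elderly", slope = 1,
                       intercept = 0), class = "value_function")
  expect_equal(evaluate_value(vf, 1), 1)
  p <- baseline_parameters()
  for (agent in both_agents) {
    vf <- value_function(p, "G", agent)
    for (d in c(-3, 0.5, 7))
      expect_equal(evaluate_value(vf, 2 + d) - evaluate_value(vf, 2),
                   vf$slope * d)
    st <- state_point(x1 = 4, x2 = -1)
    expect_equal(evaluate_value(vf, st),
                 evaluate_value(vf, if (agent == "elderly") 4 else -1))
  }
})

test_that("comparative statics of the controls have the predicted signs", {
  scen <- random_scenarios(scenario_spec(seed = 11, count = 10))
  for (p in scen) {
    M_of <- function(field) function(v) {
      q <- p; q[[field]] <- v
      optimal_controls(q, "N")$M
    }
    expect_gt(fd(M_of("b"), p$b), 0)
    expect_lt(fd(M_of("c_M"), p$c_M), 0)
    expect_gt(fd(M_of("l1"), p$l1), 0)
    absI_of <- function(field) function(v) {
      q <- p; q[[field]] <- v
      abs(optimal_controls(q, "N")$I)
    }
    expect_gt(fd(absI_of("c_I"), p$c_I), 0)
    expect_lt(fd(absI_of("lambda1"), p$lambda1), 0)
    F_of <- function(field) function(v) {
      q <- p; q[[field]] <- v
      optimal_controls(q, "N")$F
    }
    expect_gt(fd(F_of("lambda2"), p$lambda2), 0)   # raises kappa
    expect_lt(fd(F_of("c_F"), p$c_F), 0)
  }
})

test_that("equal effective parameters give identical equilibria across modes", {
  p <- game_parameters(c_H = 0, beta_H = 0, alpha1 = 0,
                       lambda_H = with(baseline_parameters(),
                                       lambda3 - lambda4))
  cN <- optimal_controls(p, "N"); cH <- optimal_controls(p, "H")
  expect_identical(unclass(cN)[c("M", "I", "F")],
                   unclass(cH)[c("M", "I", "F")])
  for (agent in both_agents) {
    vN <- value_function(p, "N", agent); vH <- value_function(p, "H", agent)
    expect_identical(vN$slope, vH$slope)
    expect_identical(vN$intercept, vH$intercept)
  }
})

test_that("equilibrium summary tabulates all six (mode, agent) pairs", {
  tab <- equilibrium_summary(baseline_parameters())
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$mode), game_modes())
  r <- tab[tab$mode == "N" & tab$agent == "government", ]
  expect_equal(r$value, 1.277778, tolerance = 1e-6)
  tab2 <- equilibrium_summary(baseline_parameters(), digits = 2)
  expect_equal(tab2$value[tab2$mode == "N" & tab2$agent == "government"], 1.28)
})
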