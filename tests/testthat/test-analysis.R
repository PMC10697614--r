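test_that("values decompose exactly as K0 + K1/(base + extra cost)", {
  p <- baseline_parameters()
  grid <- seq(0, 10, length.out = 50)
  for (mode in c("H", "G")) {
    for (agent in both_agents) {
      dc <- affine_in_inverse_cost(p, mode, agent, x0 = 1)
      expect_gt(dc$K1, 0)
      direct <- vapply(grid, function(ci) {
        q <- p
        q[[if (mode == "H") "c_H" else "c_G"]] <- ci
        evaluate_value(value_function(q, mode, agent), 1)
      }, numeric(1))
      expect_lt(max(abs(direct - predict_decomposition(dc, grid))), 1e-10)
    }
  }
  expect_error(affine_in_inverse_cost(p, "N", "elderly"), "no extra cost")
})

test_that("decomposition constants match the frozen reference values", {
  expect_equal(affine_in_inverse_cost(game_parameters(alpha1 = 0.5),
                                      "H", "elderly")$K0,
               1.277778, tolerance = 1e-6)
  expect_equal(affine_in_inverse_cost(game_parameters(alpha1 = 1),
                                      "H", "elderly")$K0,
               1.069444, tolerance = 1e-6)
  expect_equal(affine_in_inverse_cost(baseline_parameters(),
                                      "H", "elderly")$K1,
               (3 + log(33.19))^2 / 1.8, tolerance = 1e-12)
  expect_equal(affine_in_inverse_cost(game_parameters(lambda_H = 0.3),
                                      "H", "government")$K1,
               1.3^2 / 1.8, tolerance = 1e-12)
})

test_that("cost curves fall strictly, start above the reference and level off at K0", {
  p <- baseline_parameters()
  for (mode in c("H", "G")) {
    for (agent in both_agents) {
      cc <- cost_curve(p, mode, agent, grid = seq(0, 5, by = 0.25), x0 = 1)
      expect_true(all(diff(cc$value) < 0))
      expect_gt(cc$value[1], cc$baseline[1])  # special care worth it when free
      dc <- affine_in_inverse_cost(p, mode, agent, x0 = 1)
      far <- predict_decomposition(dc, 1e8)
      expect_equal(far, dc$K0, tolerance = 1e-6)
    }
  }
  expect_error(cost_curve(p, "H", "elderly", grid = numeric(0)), "empty")
  expect_error(cost_curve(p, "H", "elderly", grid = -1), "nonnegative")
})

test_that("crossover cost: closed form, bisection and frozen values agree", {
  p5 <- game_parameters(alpha1 = 0.5)
  c_star <- crossover_cost(p5, "H", "elderly")
  expect_equal(c_star, 1.929904, tolerance = 1e-6)
  expect_equal(crossover_cost(p5, "H", "elderly", method = "bisection"),
               c_star, tolerance = 1e-9)
  expect_equal(crossover_cost(game_parameters(lambda_H = 0.3),
                              "H", "government"),
               1.38, tolerance = 1e-9)
  # at the crossover the curve meets the no-special-care value
  dc <- affine_in_inverse_cost(p5, "H", "elderly")
  V_N <- evaluate_value(value_function(p5, "N", "elderly"), 1)
  expect_equal(predict_decomposition(dc, c_star), V_N, tolerance = 1e-9)
  # when no special care dominates even at zero extra cost the formal root
  # is negative (the curve sits below the reference on the whole grid)
  p_big <- game_parameters(lambda3 = 8, lambda4 = 2, lambda_H = 0.01)
  expect_lt(crossover_cost(p_big, "H", "government"), 0)
  cc <- cost_curve(p_big, "H", "government", grid = seq(0, 5, 0.5))
  expect_true(all(cc$value < cc$baseline))
})

test_that("crossover agrees with a dense grid scan of the two value curves", {
  p <- game_parameters(alpha1 = 0.5)
  V_N <- evaluate_value(value_function(p, "N", "elderly"), 1)
  grid <- seq(0, 5, by = 1e-4)
  vals <- affine_in_inverse_cost(p, "H", "elderly")
  scan <- grid[which(predict_decomposition(vals, grid) < V_N)[1]]
  expect_equal(scan, crossover_cost(p, "H", "elderly"), tolerance = 2e-4)
})

test_that("sensitivity sweeps report the equation-level trends", {
  p <- baseline_parameters()
  st <- sensitivity_table(p, "H", "elderly", "alpha1", c(0.5, 0.75, 1))
  expect_equal(attr(st, "K0_trend"), -1L)   # less infection harm, lower K0
  expect_equal(round(st$K0[c(1, 3)], 2), c(1.28, 1.07))
  st <- sensitivity_table(p, "H", "government", "lambda_H", c(0.3, 0.4, 0.5))
  expect_equal(attr(st, "K1_trend"), 1L)
  expect_equal(round(st$K1[c(1, 3)], 2), c(0.94, 1.25))
  st <- sensitivity_table(p, "G", "government", "lambda_G", c(0.3, 0.4))
  expect_equal(attr(st, "K1_trend"), 1L)
  expect_equal(round(st$K1, 2), c(0.94, 1.09))
  st <- sensitivity_table(p, "G", "elderly", "b_G", c(0.5, 1))
  expect_equal(attr(st, "K1_trend"), 1L)
  expect_equal(st$K1, c((3.5 + log(12.2))^2 / 1.8, (4 + log(12.2))^2 / 1.8),
               tolerance = 1e-12)
  expect_error(sensitivity_table(p, "H", "elderly", "rho", 0.5), "arg")
})

test_that("mode ranking orders by value with fixed-order tie breaking", {
  p <- baseline_parameters()
  rk <- recommend_mode(p, c_H = 0, c_G = 0)
  expect_true(all(rk$elderly$mode[rk$elderly$rank <= 2] %in% c("H", "G")))
  expect_equal(rk$elderly$mode[3], "N")
  # beyond both crossovers N wins for both agents
  far <- 50
  rk2 <- recommend_mode(p, c_H = far, c_G = far)
  expect_equal(rk2$elderly$mode[1], "N")
  expect_equal(rk2$government$mode[1], "N")
  # identical effective params for H and G: tie broken H before G
  q <- game_parameters(alpha1 = 0, beta_G = baseline_parameters()$beta_H,
                       b_G = 0, lambda_G = baseline_parameters()$lambda_H)
  rk3 <- recommend_mode(q, c_H = 1, c_G = 1)
  vH <- rk3$elderly$value[rk3$elderly$mode == "H"]
  vG <- rk3$elderly$value[rk3$elderly$mode == "G"]
  expect_equal(vH, vG)
  expect_lt(which(rk3$elderly$mode == "H"), which(rk3$elderly$mode == "G"))
})
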