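test_that("stability metrics vanish where perturbations cannot act", {
  X <- data.frame(x = rnorm(20))
  expect_equal(stbl_x(node_const(5), X), 0)          # input-invariant
  expect_equal(stbl_c(parse_formula("x + x"), X), 0) # no constants to perturb
  # a lone constant IS a coefficient: perturbing it shifts the output
  expect_equal(stbl_c(node_const(5), X), 0.1 * 5)
})

test_that("closed forms hold for a linear tree c1*x", {
  set.seed(21)
  X <- data.frame(x = runif(37, -2, 5))
  c1 <- -1.7
  t <- node_op("*", list(node_const(c1), node_var("x")))
  cfg <- stability_config("FITNESS_XC")
  expect_equal(stbl_x(t, X, cfg), abs(c1) * 0.1 * sd(X$x),
               tolerance = 1e-10)
  expect_equal(stbl_c(t, X, cfg), 0.1 * abs(c1) * sqrt(mean(X$x^2)),
               tolerance = 1e-10)
  # homogeneity in the perturbation scale
  cfg2 <- stability_config("FITNESS_XC", delta_c_scale = 0.2)
  expect_equal(stbl_c(t, X, cfg2), 2 * stbl_c(t, X, cfg), tolerance = 1e-10)
})

test_that("stbl_x agrees with a per-row finite-difference oracle", {
  set.seed(22)
  X <- data.frame(x = runif(30, 0.5, 3))
  cfg <- stability_config("FITNESS_X")
  for (f in c("2*x^2", "0.5*x + 1", "exp(0.4*x)")) {
    t <- parse_formula(f)
    d <- 0.1 * sd(X$x)
    fx <- evaluate(t, X)$values
    oracle <- (sqrt(mean((evaluate(t, data.frame(x = X$x + d))$values - fx)^2)) +
               sqrt(mean((evaluate(t, data.frame(x = X$x - d))$values - fx)^2))) / 2
    expect_equal(stbl_x(t, X, cfg), oracle, tolerance = 1e-12)
  }
  # steeper local slopes give larger stbl_x
  expect_gt(stbl_x(parse_formula("2*x^2"), X, cfg),
            stbl_x(parse_formula("0.5*x + 1"), X, cfg))
})

test_that("both metrics are scale-covariant in the tree's output", {
  set.seed(24)
  X <- data.frame(x = runif(25, 0.2, 2))
  t <- parse_formula("1.3*x^2 + 0.7")
  tk <- parse_formula("3*(1.3*x^2 + 0.7)")  # k = 3 via an extra constant
  cfg <- stability_config("FITNESS_XC")
  expect_equal(stbl_x(tk, X, cfg), 3 * stbl_x(t, X, cfg), tolerance = 1e-9)
})

test_that("fitness metrics combine RMSE and penalties as configured", {
  set.seed(25)
  X <- data.frame(x = runif(30, -1, 3))
  y <- 1.2 * X$x + 5 + rnorm(30, 0, 0.2)
  t <- fit_constants(parse_formula("1*x + 4"), X, y)$fitted_tree

  f0 <- compute_fitness(t, X, y, stability_config("FITNESS_0"))
  expect_equal(f0$combined, f0$rmse_train)

  fxc <- compute_fitness(t, X, y, stability_config("FITNESS_XC"))
  expect_equal(fxc$lambda_x, 0.5)
  expect_equal(fxc$combined,
               fxc$rmse_train + 0.5 * stbl_x(t, X) + 0.5 * stbl_c(t, X),
               tolerance = 1e-12)
  expect_gte(fxc$combined, f0$combined)

  fx <- compute_fitness(t, X, y, stability_config("FITNESS_X"))
  expect_equal(fx$lambda_x, 1); expect_equal(fx$lambda_c, 0)

  # perfect linear fit on noiseless data still pays the stability cost
  y0 <- 1.2 * X$x + 5
  tfit <- fit_constants(parse_formula("1*x + 4"), X, y0)$fitted_tree
  fp <- compute_fitness(tfit, X, y0, stability_config("FITNESS_XC"))
  expect_lt(fp$rmse_train, 1e-8)
  expect_gt(fp$combined, 0)

  # invalid training row -> worst-fitness sentinel
  Xb <- data.frame(x = c(-1, 1, 2))
  fb <- compute_fitness(parse_formula("ln(x)"), Xb, c(0, 0, 0.7),
                        stability_config("FITNESS_0"))
  expect_true(fb$penalized)
  expect_equal(fb$combined, figp2:::.WORST_FITNESS)
})

test_that("a lambda sweep is expressible through the config grid", {
  X <- data.frame(x = seq(0.1, 2, length.out = 15))
  y <- X$x^2
  t <- parse_formula("x^2")
  lambdas <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1.0)
  vals <- vapply(lambdas, function(l)
    compute_fitness(t, X, y,
                    stability_config("FITNESS_X", lambda_x = l))$combined,
    numeric(1))
  expect_true(all(diff(vals) > 0))  # monotone in lambda for fixed tree
})
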