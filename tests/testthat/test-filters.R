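test_that("V-filter passes single-occurrence and rejects repeats", {
  expect_true(v_filter(parse_formula("0.5*logp + 6.9"))$passed)
  r <- v_filter(parse_formula("logp + ln(logp)"))
  expect_false(r$passed)
  expect_match(r$detail, "logp")
  # structural: constant values are irrelevant
  expect_true(v_filter(parse_formula("1e6*logp - 1e-9"))$passed)
})

test_that("F-filter rejects nesting within groups, allows siblings", {
  expect_false(f_filter(parse_formula("sqrt(sqrt(x))"))$passed)
  expect_true(f_filter(parse_formula("x^2 + y^3"))$passed)
  expect_false(f_filter(parse_formula("ln(1 + exp(x))"))$passed)
  expect_false(f_filter(parse_formula("(x^2 + y)^3"))$passed)
  expect_true(f_filter(parse_formula("sqrt(exp(x))"))$passed)
})

test_that("D-filter checks validity and target containment on probes", {
  probes <- data.frame(logp = seq(0, 4, length.out = 50))
  expect_true(d_filter(node_const(7), probes, c(5, 10))$passed)

  pole <- parse_formula("1/(logp - 2)")
  expect_false(d_filter(pole, data.frame(logp = 2), c(-10, 10))$passed)

  big <- parse_formula("10*logp")
  r <- d_filter(big, probes, c(5, 10))
  expect_false(r$passed)
  expect_match(r$detail, "outside target")
})

test_that("range estimation matches endpoints and dense-grid oracle", {
  est <- estimate_range(parse_formula("x^2"), list(x = c(0, 3)))
  expect_equal(est$min_value, 0, tolerance = 1e-6)
  expect_equal(est$max_value, 9, tolerance = 1e-6)

  set.seed(2)
  est <- estimate_range(parse_formula("(x - 1)^2 + (y + 2)^2"),
                        list(x = c(-5, 5), y = c(-5, 5)))
  expect_equal(est$min_value, 0, tolerance = 1e-5)
  expect_equal(unname(est$argmin[c("x", "y")]), c(1, -2), tolerance = 1e-3)

  # monotone single-variable trees: exact endpoint evaluation
  est <- estimate_range(parse_formula("2*x + 1"), list(x = c(0, 3)))
  expect_equal(c(est$min_value, est$max_value), c(1, 7))

  # constant tree
  est <- estimate_range(node_const(7), list(x = c(0, 1)))
  expect_equal(c(est$min_value, est$max_value), c(7, 7))
})

test_that("D2-filter certifies containment over the box", {
  spec <- domain_spec(list(logp = c(1.4, 4.2)), c(5.1, 9.0))
  # pole inside the box: divergence must be caught
  set.seed(3)
  r <- d2_filter(parse_formula("7 + 1/(logp - 2.65)"), spec)
  expect_false(r$passed)

  expect_true(d2_filter(node_const(7), spec)$passed)

  # logistic-style ratio: denominator > 1 whenever acc >= 0
  spec2 <- domain_spec(list(acc = c(0, 8)), c(0, 9))
  set.seed(4)
  r2 <- d2_filter(parse_formula("8/(1 + 2*exp(0 - acc))"), spec2)
  expect_true(r2$passed)
})

test_that("a sparse probe grid can miss a pole that D2 catches", {
  # pole at x = 0.55 sits between the probes x = 0.5 and 0.6
  tree <- parse_formula("7 + 0.001/(x - 0.55)")
  probes <- data.frame(x = seq(0, 1, by = 0.1))
  spec <- domain_spec(list(x = c(0, 1)), c(6, 8))
  expect_true(d_filter(tree, probes, spec$target_range)$passed)
  set.seed(5)
  expect_false(d2_filter(tree, spec)$passed)
})

test_that("D2 pass implies D pass on probes from the same box", {
  set.seed(17)
  box <- list(u = c(0.5, 2), v = c(0.5, 2))
  spec <- domain_spec(box, c(-20, 20))
  n_checked <- 0
  for (i in 1:40) {
    t <- random_tree(depth = c(1L, 3L))
    if (!d2_filter(t, spec)$passed) next
    probes <- data.frame(u = runif(500, 0.5, 2), v = runif(500, 0.5, 2))
    expect_true(d_filter(t, probes, spec$target_range)$passed)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 3)
})

test_that("domain spec round-trips through its config-list form", {
  spec <- domain_spec(list(logp = c(-1, 5), tpsa = c(0, 120)), c(5.57, 9.3),
                      source = "from_training")
  spec2 <- domain_spec_from_list(domain_spec_to_list(spec))
  expect_equal(spec2$variable_box, lapply(spec$variable_box, as.numeric))
  expect_equal(spec2$target_range, spec$target_range)
  expect_equal(spec2$source, spec$source)
})
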