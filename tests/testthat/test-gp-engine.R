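small_problem <- function(seed = 1, n = 40) {
  set.seed(seed)
  ds <- generate_synthetic("0.5*logp + 6.9", list(logp = c(-1, 4)), n, 0.05)
  split_train_test(ds, 0.8)
}

test_that("config defaults reproduce the standard hyperparameters", {
  cfg <- gp_config()
  expect_equal(cfg$population_size, 200L)
  expect_equal(cfg$n_generations, 200L)
  expect_equal(cfg$init_depth, c(1L, 2L))
  expect_equal(cfg$crossover_prob, 0.7)
  expect_equal(cfg$mutation_prob, 0.2)
  expect_equal(cfg$mutation_depth, c(0L, 2L))
  expect_equal(cfg$max_depth, 4L)
  expect_equal(cfg$tournament_size, 5L)
  expect_setequal(names(op_table()),
                  c("+", "-", "*", "/", "sqrt", "square", "cube", "exp", "ln"))
  expect_equal(gp_config()$f_filter_groups,
               list("sqrt", c("square", "cube"), c("ln", "exp")))
  expect_error(gp_config(crossover_prob = 0.8, mutation_prob = 0.3))
})

test_that("initialization fills a filter-passing population reproducibly", {
  sp <- small_problem()
  spec <- domain_spec_from_data(sp$train$X, sp$train$y)
  cfg <- gp_preset("FIGP2_D2", population_size = 15, seed = 1)

  set.seed(2)
  pop <- initialize_population(cfg, sp$train, spec)
  expect_length(pop, 15)
  for (ind in pop) {
    expect_true(v_filter(ind$tree)$passed)
    expect_true(f_filter(ind$tree)$passed)
    expect_true(ind$eligible)
  }

  set.seed(2)
  pop2 <- initialize_population(cfg, sp$train, spec)
  expect_identical(lapply(pop, function(i) render_formula(i$tree)),
                   lapply(pop2, function(i) render_formula(i$tree)))

  # V active: no repeated variable anywhere
  set.seed(3)
  popv <- initialize_population(gp_config(population_size = 20,
                                          active_filters = "V"),
                                sp$train, spec)
  for (ind in popv) expect_true(v_filter(ind$tree)$passed)
})

test_that("tournament selection follows the order-statistics law", {
  set.seed(33)
  n <- 20
  pop <- lapply(seq_len(n), function(i) node_const(i))
  fit <- seq_len(n)  # unique fitnesses, individual i has rank i

  # size = population size: always the global best
  picks <- tournament_select(pop, fit, 50, size = n)
  expect_true(all(picks == 1L))

  # distinct-draw tournaments: P(rank i wins) = C(n-i, k-1) / C(n, k)
  k <- 5L; n_draw <- 10000L
  picks <- tournament_select(pop, fit, n_draw, size = k)
  p_rank <- choose(n - seq_len(n), k - 1) / choose(n, k)
  obs <- tabulate(picks, n) / n_draw
  se <- sqrt(p_rank * (1 - p_rank) / n_draw)
  expect_true(all(abs(obs - p_rank) < 3 * se + 1e-4))

  # size = 1: uniform selection
  picks1 <- tournament_select(pop, fit, 5000, size = 1L)
  expect_true(all(abs(tabulate(picks1, n) / 5000 - 1 / n) < 0.02))
})

test_that("crossover and mutation respect structural invariants", {
  set.seed(44)
  a <- parse_formula("x + 2*y")
  kids <- crossover(a, a)
  expect_true(tree_equal(kids[[1]], a) || tree_equal(kids[[2]], a) ||
              tree_depth(kids[[1]]) <= 4)

  t0a <- node_var("x"); t0b <- node_const(2)
  kids <- crossover(t0a, t0b)  # depth-0 parents swap terminals
  expect_setequal(vapply(kids, render_formula, character(1)),
                  c("x", "2"))

  cfg <- gp_config()
  for (i in 1:1000) {
    p1 <- random_tree(c("x", "y"), c(1L, 3L))
    p2 <- random_tree(c("x", "y"), c(1L, 3L))
    kids <- crossover(p1, p2, max_depth = 4L)
    for (kd in kids) expect_lte(oracle_depth(kd), 4L)
    m <- mutate(p1, c("x", "y"), cfg)
    expect_lte(oracle_depth(m), 4L)
  }

  # mutation of a single terminal replaces the whole tree
  set.seed(45)
  m <- mutate(node_var("x"), c("x", "y"), cfg)
  expect_true(is.list(m))
  set.seed(46); m1 <- mutate(parse_formula("x + y"), c("x", "y"), cfg)
  set.seed(46); m2 <- mutate(parse_formula("x + y"), c("x", "y"), cfg)
  expect_identical(render_formula(m1), render_formula(m2))
})

test_that("zero generations returns the best of the initial population", {
  sp <- small_problem()
  cfg <- gp_preset("FIGP2_D2", population_size = 20, n_generations = 0,
                   seed = 5)
  run <- evolve(sp$train, sp$test, cfg)
  expect_equal(nrow(run$generation_log), 1L)
  expect_equal(run$generation_log$best_combined[1],
               run$best_fitness$combined)
})

test_that("evolution is deterministic, monotone, and emits filter-passing bests", {
  sp <- small_problem()
  cfg <- gp_preset("FIGP2", population_size = 20, n_generations = 6, seed = 9)
  r1 <- evolve(sp$train, sp$test, cfg)
  r2 <- evolve(sp$train, sp$test, cfg)
  expect_identical(render_formula(r1$best_tree), render_formula(r2$best_tree))
  expect_identical(r1$generation_log, r2$generation_log)
  expect_equal(r1$test_rmse, r2$test_rmse)

  expect_true(all(diff(r1$generation_log$best_combined) <= 0))

  expect_true(v_filter(r1$best_tree)$passed)
  expect_true(f_filter(r1$best_tree)$passed)
  set.seed(1)
  expect_true(d2_filter(r1$best_tree, r1$spec,
                        start_points = sp$train$X)$passed)
})

test_that("the no-filter preset runs as a conventional GP baseline", {
  sp <- small_problem()
  cfg <- gp_preset("GP", population_size = 15, n_generations = 3, seed = 2)
  expect_length(cfg$active_filters, 0)
  expect_equal(cfg$stability$metric_kind, "FITNESS_0")
  run <- evolve(sp$train, sp$test, cfg)
  expect_true(is.finite(run$test_rmse))
})
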