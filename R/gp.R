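#' Genetic-programming configuration
#'
#' All hyperparameters of the evolutionary search. The defaults are
#' the method's standard settings: population 200, 200 generations,
#' initial tree depth 1-2, crossover probability 0.7, mutation
#' probability 0.2 (remaining 0.1 is reproduction), mutation-subtree
#' depth 0-2, maximum depth 4, tournament size 5, the nine-operator
#' vocabulary and the three function-filter groups.
#'
#' @param population_size,n_generations Integers (defaults 200, 200).
#' @param init_depth Depth interval for the initial population
#'   (default \code{c(1, 2)}).
#' @param crossover_prob,mutation_prob Operator probabilities
#'   (defaults 0.7, 0.2; must sum to at most 1).
#' @param mutation_depth Depth interval of mutation subtrees (default
#'   \code{c(0, 2)}).
#' @param max_depth Maximum tree depth, terminal = depth 0 (default 4).
#' @param tournament_size Tournament size for selection (default 5).
#' @param operators Operator names to search over.
#' @param f_filter_groups Groups for the F-filter.
#' @param active_filters Subset of \code{c("V","F","D","D2")}
#'   (default \code{c("V","F","D2")}, the full method).
#' @param stability A [stability_config()] (default FITNESS_XC).
#' @param seed Integer seed for the run (default 1).
#' @param max_regen_attempts Redraw budget for rejected individuals
#'   (default 50).
#' @param d2_restarts Restarts per direction in the D2 range search.
#' @param d2_slack Containment slack of the domain filters (fraction
#'   of the target-range width, default 0.05).
#' @param d_probe_n,d_probe_expand Probe count and box expansion for
#'   the D-filter when no external probes are given.
#' @param const_range Initialization interval for ephemeral constants.
#' @return A list of class \code{figp_gp_config}.
#' @export
gp_config <- function(population_size = 200L, n_generations = 200L,
                      init_depth = c(1L, 2L),
                      crossover_prob = 0.7, mutation_prob = 0.2,
                      mutation_depth = c(0L, 2L), max_depth = 4L,
                      tournament_size = 5L,
                      operators = names(op_table()),
                      f_filter_groups = default_f_groups(),
                      active_filters = c("V", "F", "D2"),
                      stability = stability_config("FITNESS_XC"),
                      seed = 1L, max_regen_attempts = 50L,
                      d2_restarts = 5L, d2_slack = 0.05,
                      d_probe_n = 10000L, d_probe_expand = 1.5,
                      const_range = c(-10, 10)) {
  stopifnot(crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            crossover_prob + mutation_prob <= 1,
            max_depth >= 1, init_depth[2] <= max_depth,
            all(active_filters %in% c("V", "F", "D", "D2")))
  structure(list(
    population_size = as.integer(population_size),
    n_generations = as.integer(n_generations),
    init_depth = as.integer(init_depth),
    crossover_prob = crossover_prob, mutation_prob = mutation_prob,
    mutation_depth = as.integer(mutation_depth),
    max_depth = as.integer(max_depth),
    tournament_size = as.integer(tournament_size),
    operators = operators, f_filter_groups = f_filter_groups,
    active_filters = active_filters, stability = stability,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    max_regen_attempts = as.integer(max_regen_attempts),
    d2_restarts = as.integer(d2_restarts), d2_slack = d2_slack,
    d_probe_n = as.integer(d_probe_n), d_probe_expand = d_probe_expand,
    const_range = const_range), class = "figp_gp_config")
}

#' Method presets
#'
#' Named filter/metric combinations: \code{"GP"} (no filters, RMSE
#' fitness), \code{"FIGP"} (V-, F- and D-filters, RMSE), \code{"FIGP2_D2"}
#' (V, F, D2, RMSE) and \code{"FIGP2"} (V, F, D2 plus the full
#' stability penalty FITNESS_XC).
#'
#' @param method Preset name.
#' @param ... Overrides passed to [gp_config()].
#' @return A \code{figp_gp_config}.
#' @export
gp_preset <- function(method = c("FIGP2", "FIGP2_D2", "FIGP", "GP"), ...) {
  method <- match.arg(method)
  args <- switch(method,
    GP       = list(active_filters = character(0),
                    stability = stability_config("FITNESS_0")),
    FIGP     = list(active_filters = c("V", "F", "D"),
                    stability = stability_config("FITNESS_0")),
    FIGP2_D2 = list(active_filters = c("V", "F", "D2"),
                    stability = stability_config("FITNESS_0")),
    FIGP2    = list(active_filters = c("V", "F", "D2"),
                    stability = stability_config("FITNESS_XC")))
  do.call(gp_config, utils::modifyList(args, list(...)))
}

# --- node addressing ---------------------------------------------------

# flat preorder list of (index, depth) for subtree surgery
node_depths <- function(tree) {
  out <- integer(0)
  walk <- function(nd, d) {
    out[length(out) + 1L] <<- d
    if (nd$kind == "op") for (ch in nd$children) walk(ch, d + 1L)
  }
  walk(tree, 0L)
  out
}

get_subtree <- function(tree, index) {
  i <- 0L
  found <- NULL
  walk <- function(nd) {
    i <<- i + 1L
    if (i == index) { found <<- nd; return(TRUE) }
    if (nd$kind == "op")
      for (ch in nd$children) if (walk(ch)) return(TRUE)
    FALSE
  }
  walk(tree)
  found
}

replace_subtree <- function(tree, index, sub) {
  i <- 0L
  walk <- function(nd) {
    i <<- i + 1L
    if (i == index) return(sub)
    if (nd$kind == "op") {
      for (j in seq_along(nd$children)) {
        if (i >= index) break
        nd$children[[j]] <- walk(nd$children[[j]])
      }
    }
    nd
  }
  walk(tree)
}

# --- variation operators -----------------------------------------------

#' Subtree crossover
#'
#' One-point subtree exchange at uniformly chosen nodes of the two
#' parents. Offspring exceeding \code{max_depth} are rejected and the
#' crossover points re-drawn up to \code{max_attempts} times; after
#' that the parents are returned unchanged.
#'
#' @param a,b Parent trees.
#' @param max_depth Depth cap (default 4).
#' @param max_attempts Redraw budget (default 50).
#' @return A list of two offspring trees.
#' @export
crossover <- function(a, b, max_depth = 4L, max_attempts = 50L) {
  da <- node_depths(a); db <- node_depths(b)
  for (att in seq_len(max_attempts)) {
    ia <- sample.int(length(da), 1L)
    ib <- sample.int(length(db), 1L)
    sa <- get_subtree(a, ia); sb <- get_subtree(b, ib)
    c1 <- replace_subtree(a, ia, sb)
    c2 <- replace_subtree(b, ib, sa)
    if (tree_depth(c1) <= max_depth && tree_depth(c2) <= max_depth)
      return(list(c1, c2))
  }
  list(a, b)
}

#' Subtree mutation
#'
#' Replaces a uniformly chosen node's subtree with a fresh random tree
#' whose depth lies in \code{cfg$mutation_depth}, clipped so the
#' result respects \code{cfg$max_depth}.
#'
#' @param tree A tree.
#' @param feature_names Active feature set.
#' @param cfg A [gp_config()].
#' @return The mutated tree.
#' @export
mutate <- function(tree, feature_names, cfg) {
  d <- node_depths(tree)
  i <- sample.int(length(d), 1L)
  room <- cfg$max_depth - d[i]
  rng <- c(min(cfg$mutation_depth[1], room), min(cfg$mutation_depth[2], room))
  sub <- build_random_tree(feature_names, rng, operators = cfg$operators,
                           const_range = cfg$const_range)
  replace_subtree(tree, i, sub)
}

#' Tournament selection
#'
#' Each pick draws \code{size} distinct individuals uniformly (with
#' replacement across picks) and keeps the one with the lowest
#' combined fitness; ties are broken by lower node count, then at
#' random. A tournament of the whole population always returns the
#' global best.
#'
#' @param population List of trees.
#' @param fitnesses Numeric vector of combined fitness values.
#' @param k Number of picks.
#' @param size Tournament size (default 5).
#' @return Integer vector of \code{k} selected indices.
#' @export
tournament_select <- function(population, fitnesses, k, size = 5L) {
  stopifnot(length(population) > 0L,
            length(fitnesses) == length(population))
  nc <- vapply(population, function(t) tree_metrics(t)$node_count, integer(1))
  size <- min(size, length(population))
  vapply(seq_len(k), function(j) {
    cand <- sample.int(length(population), size)
    best <- cand[order(fitnesses[cand], nc[cand],
                       stats::runif(length(cand)))[1]]
    best
  }, integer(1))
}

# --- filter plumbing ---------------------------------------------------

structural_ok <- function(tree, cfg) {
  if (tree_depth(tree) > cfg$max_depth) return(FALSE)
  if ("V" %in% cfg$active_filters && !v_filter(tree)$passed) return(FALSE)
  if ("F" %in% cfg$active_filters &&
      !f_filter(tree, cfg$f_filter_groups)$passed) return(FALSE)
  TRUE
}

# fit constants, run domain filters on the fitted tree, compute fitness
evaluate_individual <- function(tree, train, spec, cfg, probes) {
  fit <- fit_constants(tree, train$X, train$y)
  t <- fit$fitted_tree
  domain_ok <- TRUE
  if ("D" %in% cfg$active_filters)
    domain_ok <- d_filter(t, probes, spec$target_range,
                          slack = cfg$d2_slack)$passed
  if (domain_ok && "D2" %in% cfg$active_filters)
    domain_ok <- d2_filter(t, spec, n_restarts = cfg$d2_restarts,
                           start_points = train$X,
                           slack = cfg$d2_slack)$passed
  if (!domain_ok) {
    fitlist <- structure(list(rmse_train = NA_real_, stbl_x = NA_real_,
                              stbl_c = NA_real_,
                              lambda_x = cfg$stability$lambda_x,
                              lambda_c = cfg$stability$lambda_c,
                              combined = .WORST_FITNESS, penalized = TRUE),
                         class = "figp_fitness")
    return(list(tree = t, fitness = fitlist, eligible = FALSE))
  }
  f <- compute_fitness(t, train$X, train$y, cfg$stability)
  list(tree = t, fitness = f, eligible = !f$penalized)
}

#' Initialize a filter-passing population
#'
#' Draws random trees of depth \code{cfg$init_depth}, applies the
#' active structural filters, fits their constants and applies the
#' active domain filters, until \code{cfg$population_size} accepted
#' individuals exist. The total draw budget is
#' \code{population_size * max_regen_attempts}; exhausting it raises
#' an initialization error reporting the rejection statistics.
#'
#' @param cfg A [gp_config()].
#' @param train Training [figp_dataset()].
#' @param spec A [domain_spec()].
#' @param probes D-filter probe points (data.frame), if D is active.
#' @return List of evaluated individuals (\code{tree}, \code{fitness},
#'   \code{eligible}).
#' @export
initialize_population <- function(cfg, train, spec, probes = NULL) {
  stopifnot(nrow(train$X) > 0)
  features <- names(train$X)
  budget <- cfg$population_size * cfg$max_regen_attempts
  pop <- vector("list", cfg$population_size)
  n_ok <- 0L; n_draw <- 0L; n_struct <- 0L; n_domain <- 0L
  domain_active <- any(c("D", "D2") %in% cfg$active_filters)
  while (n_ok < cfg$population_size) {
    if (n_draw >= budget)
      stop("initialization error: could not fill population of ",
           cfg$population_size, " within ", budget, " draws (",
           n_struct, " structural rejections, ", n_domain,
           " domain rejections)")
    n_draw <- n_draw + 1L
    t <- build_random_tree(features, cfg$init_depth,
                           operators = cfg$operators,
                           const_range = cfg$const_range)
    if (!structural_ok(t, cfg)) { n_struct <- n_struct + 1L; next }
    ind <- evaluate_individual(t, train, spec, cfg, probes)
    if (domain_active && !ind$eligible) { n_domain <- n_domain + 1L; next }
    n_ok <- n_ok + 1L
    pop[[n_ok]] <- ind
  }
  attr(pop, "rejections") <- c(structural = n_struct, domain = n_domain)
  pop
}

# --- the evolutionary loop ---------------------------------------------

#' Run the evolutionary symbolic-regression search
#'
#' The four-step loop: initial population (filters applied at
#' creation), tournament selection, subtree crossover / mutation /
#' reproduction (exclusive draws with the configured probabilities),
#' then constant fitting, domain filtering of the fitted expression
#' and fitness evaluation. Generational replacement with elitism of
#' one: the all-time best filter-passing individual survives every
#' generation, so the best combined fitness is non-increasing. The
#' run is fully deterministic given \code{cfg$seed}, the data and the
#' domain spec.
#'
#' @param train Training [figp_dataset()].
#' @param test Optional test [figp_dataset()]; when given, the result
#'   carries the best expression's test RMSE (rows where the
#'   expression is invalid are predicted as the training mean and
#'   counted in \code{n_invalid_test}).
#' @param cfg A [gp_config()] or [gp_preset()].
#' @param spec Optional [domain_spec()]; default derived from the
#'   training split. The stability penalty's invalid-perturbation
#'   displacement is set to the target-range width.
#' @return An object of class \code{figp_run}: \code{best_tree},
#'   \code{best_fitness}, \code{test_rmse}, \code{generation_log}
#'   (data.frame), \code{spec}, \code{cfg}, \code{seed}.
#' @examples
#' set.seed(7)
#' ds <- generate_synthetic("x^2", list(x = c(-2, 2)), 60, 0.01)
#' sp <- split_train_test(ds, 0.8)
#' run <- evolve(sp$train, sp$test,
#'               gp_preset("FIGP2", population_size = 30,
#'                         n_generations = 5, seed = 1))
#' render_formula(run$best_tree)
#' @export
evolve <- function(train, test = NULL, cfg = gp_config(), spec = NULL) {
  stopifnot(inherits(cfg, "figp_gp_config"), nrow(train$X) > 0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(spec)) spec <- domain_spec_from_data(train$X, train$y)
  cfg$stability$invalid_displacement <- diff(spec$target_range)
  features <- names(train$X)
  probes <- if ("D" %in% cfg$active_filters)
    make_probe_points(train$X, cfg$d_probe_n, cfg$d_probe_expand) else NULL

  pop <- initialize_population(cfg, train, spec, probes)
  rej <- attr(pop, "rejections")

  best <- NULL
  update_best <- function(ind) {
    if (ind$eligible &&
        (is.null(best) || ind$fitness$combined < best$fitness$combined))
      best <<- ind
  }
  for (ind in pop) update_best(ind)
  fallback_best <- pop[[which.min(vapply(pop, function(i)
    i$fitness$combined, numeric(1)))]]

  log_rows <- list()
  log_gen <- function(gen, n_struct, n_domain) {
    comb <- vapply(pop, function(i) i$fitness$combined, numeric(1))
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      generation = gen,
      best_combined = if (!is.null(best)) best$fitness$combined
                      else min(comb),
      median_combined = stats::median(comb),
      n_struct_reject = n_struct, n_domain_reject = n_domain)
  }
  log_gen(0L, rej[["structural"]], rej[["domain"]])

  if (cfg$n_generations > 0L) {
    for (gen in seq_len(cfg$n_generations)) {
      comb <- vapply(pop, function(i) i$fitness$combined, numeric(1))
      trees <- lapply(pop, `[[`, "tree")
      n_struct <- 0L; n_domain <- 0L
      elite <- if (!is.null(best)) best else fallback_best
      newpop <- list(elite)
      domain_active <- any(c("D", "D2") %in% cfg$active_filters)

      # one structurally valid offspring from the variation operators
      breed <- function() {
        r <- stats::runif(1)
        if (r < cfg$crossover_prob) {
          ip <- tournament_select(trees, comb, 2L, cfg$tournament_size)
          for (att in seq_len(cfg$max_regen_attempts)) {
            cand <- crossover(trees[[ip[1]]], trees[[ip[2]]],
                              cfg$max_depth, cfg$max_regen_attempts)
            ok <- vapply(cand, structural_ok, logical(1), cfg = cfg)
            if (any(ok)) return(cand[ok][[sample.int(sum(ok), 1L)]])
            n_struct <<- n_struct + sum(!ok)
          }
          return(trees[[ip[1]]])
        }
        ip <- tournament_select(trees, comb, 1L, cfg$tournament_size)
        if (r < cfg$crossover_prob + cfg$mutation_prob) {
          for (att in seq_len(cfg$max_regen_attempts)) {
            cand <- mutate(trees[[ip]], features, cfg)
            if (structural_ok(cand, cfg)) return(cand)
            n_struct <<- n_struct + 1L
          }
        }
        trees[[ip]]  # reproduction / fallback copy
      }

      while (length(newpop) < cfg$population_size) {
        # offspring failing an active domain filter are discarded and
        # bred again; after the budget the slot takes a fresh random
        # structurally valid tree, kept even at worst fitness
        ind <- NULL
        for (att in seq_len(cfg$max_regen_attempts)) {
          cand <- evaluate_individual(breed(), train, spec, cfg, probes)
          if (!domain_active || cand$eligible) { ind <- cand; break }
          n_domain <- n_domain + 1L
        }
        if (is.null(ind)) {
          fresh <- build_random_tree(features, cfg$init_depth,
                                     operators = cfg$operators,
                                     const_range = cfg$const_range)
          for (att in seq_len(cfg$max_regen_attempts)) {
            if (structural_ok(fresh, cfg)) break
            fresh <- build_random_tree(features, cfg$init_depth,
                                       operators = cfg$operators,
                                       const_range = cfg$const_range)
          }
          ind <- evaluate_individual(fresh, train, spec, cfg, probes)
        }
        update_best(ind)
        newpop[[length(newpop) + 1L]] <- ind
      }
      pop <- newpop
      log_gen(gen, n_struct, n_domain)
    }
  }

  final_best <- if (!is.null(best)) best else fallback_best
  test_rmse <- NA_real_; n_invalid_test <- NA_integer_
  if (!is.null(test)) {
    pr <- predict_tree(final_best$tree, test$X, fallback = mean(train$y))
    test_rmse <- sqrt(mean((pr$values - test$y)^2))
    n_invalid_test <- pr$n_invalid
  }
  structure(list(best_tree = final_best$tree,
                 best_fitness = final_best$fitness,
                 best_eligible = !is.null(best),
                 test_rmse = test_rmse, n_invalid_test = n_invalid_test,
                 generation_log = do.call(rbind, log_rows),
                 spec = spec, cfg = cfg, seed = cfg$seed),
            class = "figp_run")
}

#' Predict with an expression tree
#'
#' @param tree An expression tree.
#' @param X Descriptor data.frame.
#' @param fallback Value substituted where the expression evaluates
#'   invalidly (e.g. the training mean); \code{NULL} keeps \code{NaN}.
#' @return List with \code{values} and \code{n_invalid}.
#' @export
predict_tree <- function(tree, X, fallback = NULL) {
  ev <- evaluate(tree, X)
  n_invalid <- sum(!ev$valid_mask)
  if (!is.null(fallback) && n_invalid > 0)
    ev$values[!ev$valid_mask] <- fallback
  list(values = ev$values, n_invalid = n_invalid)
}

#' @export
print.figp_run <- function(x, ...) {
  cat("<figp_run> best expression:\n  ", render_formula(x$best_tree),
      "\n", sep = "")
  print(x$best_fitness)
  if (!is.na(x$test_rmse))
    cat(sprintf("  test RMSE %.4g (%d invalid test row(s))\n",
                x$test_rmse, x$n_invalid_test))
  invisible(x)
}
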