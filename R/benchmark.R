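#' Mean-predictor baseline
#'
#' Always predicts the training mean; the control against which every
#' method's RMSE is normalized (relative RMSE = RMSE / mean-predictor
#' RMSE, computed on the same split).
#'
#' @param train_y Non-empty training response vector.
#' @return A predictor: \code{function(X) -> numeric}.
#' @export
mean_predictor <- function(train_y) {
  stopifnot(length(train_y) > 0)
  m <- mean(train_y)
  function(X) rep(m, nrow(as.data.frame(X)))
}

#' Ordinary least-squares linear baseline
#'
#' Multiple linear regression on the active feature set, on raw
#' descriptor scales.
#'
#' @param train A [figp_dataset()] with more rows than features.
#' @return A predictor function with attribute \code{coefficients}.
#' @export
fit_mlr <- function(train) {
  X <- train$X
  if (nrow(X) <= ncol(X))
    stop("MLR needs more rows than features; use a smaller feature set")
  df <- cbind(X, .y = train$y)
  m <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(m))))
    stop("rank-deficient design; use a smaller feature set")
  f <- function(X_new) unname(stats::predict(m, newdata = as.data.frame(X_new)))
  attr(f, "coefficients") <- stats::coef(m)
  f
}

#' RBF-kernel support-vector-regression baseline
#'
#' Epsilon-SVR with a radial basis kernel; hyperparameters C, epsilon
#' and gamma are chosen by grid search minimizing k-fold
#' cross-validated RMSE on the training set (fold assignment from R's
#' global RNG; features standardized internally with training
#' statistics).
#'
#' @param train A [figp_dataset()] with at least \code{cv_folds} rows.
#' @param cv_folds Number of folds (default 5).
#' @param cost_grid,epsilon_grid,gamma_grid Search grids (logarithmic
#'   defaults spanning the conventional ranges).
#' @return A predictor function with attribute \code{hyperparameters}.
#' @export
fit_svr_rbf <- function(train, cv_folds = 5L,
                        cost_grid = c(0.1, 1, 10, 100, 1000),
                        epsilon_grid = c(0.01, 0.1, 0.5, 1),
                        gamma_grid = c(0.001, 0.01, 0.1, 1, 10)) {
  n <- nrow(train$X)
  if (n < cv_folds) stop("need at least ", cv_folds, " rows for CV")
  folds <- sample(rep_len(seq_len(cv_folds), n))
  grid <- expand.grid(cost = cost_grid, epsilon = epsilon_grid,
                      gamma = gamma_grid)
  cv_rmse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
      m <- e1071::svm(x = as.matrix(train$X[tr, , drop = FALSE]),
                      y = train$y[tr], type = "eps-regression",
                      kernel = "radial", cost = grid$cost[g],
                      epsilon = grid$epsilon[g], gamma = grid$gamma[g],
                      scale = TRUE)
      p <- stats::predict(m, as.matrix(train$X[!tr, , drop = FALSE]))
      mean((p - train$y[!tr])^2)
    }, numeric(1))
    sqrt(mean(errs, na.rm = TRUE))
  }, numeric(1))
  gbest <- which.min(cv_rmse)
  m <- e1071::svm(x = as.matrix(train$X), y = train$y,
                  type = "eps-regression", kernel = "radial",
                  cost = grid$cost[gbest], epsilon = grid$epsilon[gbest],
                  gamma = grid$gamma[gbest], scale = TRUE)
  f <- function(X_new) unname(stats::predict(m, as.matrix(as.data.frame(X_new))))
  attr(f, "hyperparameters") <- c(cost = grid$cost[gbest],
                                  epsilon = grid$epsilon[gbest],
                                  gamma = grid$gamma[gbest],
                                  cv_rmse = cv_rmse[gbest])
  f
}

#' Experiment matrix
#'
#' The benchmarking grid: feature sets x training ratios x random
#' splits. The default 3 x 3 x 5 grid gives 45 executions per method
#' per dataset; the median over them is the headline score.
#'
#' @param feature_sets Named list of feature-name vectors (default the
#'   three presets).
#' @param train_ratios Numeric vector (default \code{c(0.2, 0.5, 0.8)}).
#' @param n_splits Random splits per cell (default 5).
#' @param base_seed Seed from which per-cell split seeds are derived.
#' @return A list of class \code{figp_matrix}.
#' @export
experiment_matrix <- function(feature_sets = list(
                                FEAT4 = feature_set("FEAT4"),
                                FEAT7 = feature_set("FEAT7"),
                                FEAT10 = feature_set("FEAT10")),
                              train_ratios = c(0.2, 0.5, 0.8),
                              n_splits = 5L, base_seed = 1L) {
  structure(list(feature_sets = feature_sets, train_ratios = train_ratios,
                 n_splits = as.integer(n_splits),
                 base_seed = as.integer(base_seed)),
            class = "figp_matrix")
}

.run_one_method <- function(method, train, test, cfg, seed) {
  pred <- switch(method,
    MEAN = mean_predictor(train$y)(test$X),
    MLR  = fit_mlr(train)(test$X),
    SVR  = { set.seed(seed); fit_svr_rbf(train)(test$X) },
    GP   =, FIGP =, FIGP2_D2 =, FIGP2 = {
      cfg2 <- cfg; cfg2$seed <- seed
      preset <- gp_preset(method,
        population_size = cfg$population_size,
        n_generations = cfg$n_generations,
        max_regen_attempts = cfg$max_regen_attempts,
        d2_restarts = cfg$d2_restarts, seed = seed)
      run <- evolve(train, test, preset)
      return(list(rmse = run$test_rmse, run = run))
    },
    stop("unknown method: ", method))
  list(rmse = sqrt(mean((pred - test$y)^2)), run = NULL)
}

#' Run the benchmarking matrix
#'
#' Executes every method on the identical train/test split of every
#' (feature set, training ratio, split) cell, scoring test RMSE and
#' the RMSE relative to the mean predictor on the same split
#' (computed per execution, before aggregation). A cell whose GP
#' initialization fails scores as the mean predictor with a flag.
#'
#' @param ds A [figp_dataset()].
#' @param methods Character vector from \code{c("MEAN", "MLR", "SVR",
#'   "GP", "FIGP", "FIGP2_D2", "FIGP2")}.
#' @param matrix An [experiment_matrix()].
#' @param cfg A [gp_config()] providing the GP budget (population,
#'   generations) for the GP-family methods.
#' @return A list with \code{executions} (tidy data.frame: method,
#'   feature_set, train_ratio, split, seed, rmse, relative_rmse,
#'   failed) and \code{summary} (per-method median and 40th/60th
#'   percentiles of relative RMSE, plus median RMSE).
#' @export
run_matrix <- function(ds, methods = c("MEAN", "MLR", "SVR", "FIGP2"),
                       matrix = experiment_matrix(),
                       cfg = gp_config()) {
  rows <- list()
  for (fs in names(matrix$feature_sets)) {
    dsub <- subset_features(ds, matrix$feature_sets[[fs]])
    for (ratio in matrix$train_ratios) {
      for (s in seq_len(matrix$n_splits)) {
        seed <- matrix$base_seed + 1000L * s +
          round(10000L * ratio) + match(fs, names(matrix$feature_sets)) * 100000L
        set.seed(seed)
        sp <- split_train_test(dsub, ratio)
        rmse_mean <- sqrt(mean((mean(sp$train$y) - sp$test$y)^2))
        for (m in methods) {
          failed <- FALSE
          r <- tryCatch(.run_one_method(m, sp$train, sp$test, cfg, seed),
                        error = function(e) NULL)
          if (is.null(r) || !is.finite(r$rmse)) {
            failed <- TRUE
            r <- list(rmse = rmse_mean)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, feature_set = fs, train_ratio = ratio,
            split = s, seed = seed, rmse = r$rmse,
            relative_rmse = r$rmse / rmse_mean, failed = failed)
        }
      }
    }
  }
  ex <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(ex, ex$method), function(d) {
    q <- stats::quantile(d$relative_rmse, c(0.4, 0.5, 0.6), names = FALSE)
    data.frame(method = d$method[1], n_executions = nrow(d),
               median_rmse = stats::median(d$rmse),
               median_relative_rmse = q[2],
               p40_relative = q[1], p60_relative = q[3],
               n_failed = sum(d$failed))
  }))
  rownames(summ) <- NULL
  list(executions = ex, summary = summ)
}
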