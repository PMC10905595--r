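# sentinel combined fitness for individuals that evaluate invalidly on
# training rows or fail an active domain filter; finite so that
# selection can still order a degenerate population
.WORST_FITNESS <- 1e10

#' Stability / fitness configuration
#'
#' Controls the perturbation-based stability penalty and the choice of
#' fitness metric. The four metrics are: \code{FITNESS_0} (training
#' RMSE only), \code{FITNESS_X} (RMSE + lambda_x * STBL_x),
#' \code{FITNESS_C} (RMSE + lambda_c * STBL_c) and \code{FITNESS_XC}
#' (both penalties). Defaults follow the method's standard settings:
#' perturbation scales \code{(delta_x, delta_c) = (0.1 * std(x),
#' 0.1 * |c|)} and weights \code{(1, 1)} for the single-penalty
#' metrics, \code{(0.5, 0.5)} for \code{FITNESS_XC}.
#'
#' @param metric_kind One of \code{"FITNESS_0"}, \code{"FITNESS_X"},
#'   \code{"FITNESS_C"}, \code{"FITNESS_XC"}.
#' @param delta_x_scale Multiplier on each feature's training standard
#'   deviation (default 0.1).
#' @param delta_c_scale Multiplier on each constant's absolute value
#'   (default 0.1).
#' @param lambda_x,lambda_c Penalty weights; \code{NULL} selects the
#'   metric's default.
#' @param invalid_displacement Displacement charged to a row whose
#'   perturbed evaluation is invalid (default 10 pKi units; the engine
#'   sets it to the target-range width when a domain spec is active).
#' @param n_random_signs If > 0, use that many random sign vectors per
#'   direction instead of the deterministic symmetric scheme (for
#'   sensitivity checks; draws from R's global RNG).
#' @return A list of class \code{figp_stability_config}.
#' @export
stability_config <- function(metric_kind = c("FITNESS_XC", "FITNESS_0",
                                             "FITNESS_X", "FITNESS_C"),
                             delta_x_scale = 0.1, delta_c_scale = 0.1,
                             lambda_x = NULL, lambda_c = NULL,
                             invalid_displacement = 10,
                             n_random_signs = 0L) {
  metric_kind <- match.arg(metric_kind)
  stopifnot(delta_x_scale > 0, delta_c_scale > 0)
  defaults <- switch(metric_kind,
    FITNESS_0  = c(0, 0),
    FITNESS_X  = c(1, 0),
    FITNESS_C  = c(0, 1),
    FITNESS_XC = c(0.5, 0.5))
  if (is.null(lambda_x)) lambda_x <- defaults[1]
  if (is.null(lambda_c)) lambda_c <- defaults[2]
  stopifnot(lambda_x >= 0, lambda_c >= 0)
  structure(list(metric_kind = metric_kind,
                 delta_x_scale = delta_x_scale,
                 delta_c_scale = delta_c_scale,
                 lambda_x = lambda_x, lambda_c = lambda_c,
                 invalid_displacement = invalid_displacement,
                 n_random_signs = as.integer(n_random_signs)),
            class = "figp_stability_config")
}

# RMSD between base values and perturbed values, charging the penalty
# displacement where the perturbed evaluation went invalid
.rmsd_vs <- function(base, pert, penalty) {
  d <- pert - base
  d[!is.finite(d)] <- penalty
  sqrt(mean(d^2))
}

.stbl_core <- function(compiled, base, perturb_eval, cfg) {
  if (cfg$n_random_signs > 0L) {
    p <- length(perturb_eval(NULL, query_len = TRUE))
    vals <- replicate(cfg$n_random_signs, {
      s <- sample(c(-1, 1), p, replace = TRUE)
      .rmsd_vs(base, perturb_eval(s), cfg$invalid_displacement)
    })
    return(mean(vals))
  }
  plus  <- .rmsd_vs(base, perturb_eval(+1), cfg$invalid_displacement)
  minus <- .rmsd_vs(base, perturb_eval(-1), cfg$invalid_displacement)
  (plus + minus) / 2
}

#' Descriptor-perturbation stability STBL_x
#'
#' Root-mean-square displacement between the fitted expression's
#' outputs and its outputs after perturbing every descriptor
#' simultaneously by \code{delta_x_scale} times that descriptor's
#' training standard deviation (denominator n-1; a zero-variance
#' feature gets delta 0). The deterministic symmetric scheme averages
#' the +delta and -delta displacements. Large STBL_x marks expressions
#' whose output moves a lot under small input noise - the signature of
#' overfitting the stability penalty is designed to punish.
#'
#' @param tree A fitted expression tree that evaluates validly on X.
#' @param X Training descriptor data.frame.
#' @param cfg A [stability_config()].
#' @return Non-negative scalar (response units).
#' @export
stbl_x <- function(tree, X, cfg = stability_config()) {
  compiled <- compile_tree(tree)
  Xl <- as.list(X)
  n <- nrow(as.data.frame(X))
  base <- eval_compiled(compiled, Xl, n_rows = n)
  sds <- vapply(Xl, stats::sd, numeric(1))
  sds[!is.finite(sds)] <- 0
  perturb_eval <- function(sign, query_len = FALSE) {
    if (query_len) return(numeric(length(Xl)))
    sgn <- rep_len(sign, length(Xl))
    Xp <- Xl
    for (j in seq_along(Xl))
      Xp[[j]] <- Xl[[j]] + sgn[j] * cfg$delta_x_scale * sds[j]
    eval_compiled(compiled, Xp, n_rows = n)
  }
  .stbl_core(compiled, base, perturb_eval, cfg)
}

#' Coefficient-perturbation stability STBL_c
#'
#' Root-mean-square displacement between the fitted expression's
#' outputs and its outputs after perturbing every constant c_j
#' simultaneously by \code{delta_c_scale * |c_j|} (relative
#' perturbation, so a sign-symmetric scheme is well defined).
#' Trees with no constants return 0.
#'
#' @inheritParams stbl_x
#' @return Non-negative scalar (response units).
#' @export
stbl_c <- function(tree, X, cfg = stability_config()) {
  compiled <- compile_tree(tree)
  if (compiled$n_const == 0L) return(0)
  Xl <- as.list(X)
  n <- nrow(as.data.frame(X))
  base <- eval_compiled(compiled, Xl, n_rows = n)
  cv <- compiled$constants
  perturb_eval <- function(sign, query_len = FALSE) {
    if (query_len) return(numeric(length(cv)))
    sgn <- rep_len(sign, length(cv))
    eval_compiled(compiled, Xl,
                  constants = cv + sgn * cfg$delta_c_scale * abs(cv),
                  n_rows = n)
  }
  .stbl_core(compiled, base, perturb_eval, cfg)
}

#' Combined fitness of a fitted expression
#'
#' Training RMSE plus the weighted stability penalties selected by the
#' metric kind; lower is better. If the tree evaluates invalidly on
#' any training row the individual gets the worst-fitness sentinel.
#'
#' @param tree A fitted expression tree (structural filters assumed
#'   already applied).
#' @param X Training descriptor data.frame.
#' @param y Training response vector.
#' @param cfg A [stability_config()].
#' @return A list (class \code{figp_fitness}) with \code{rmse_train},
#'   \code{stbl_x}, \code{stbl_c}, \code{lambda_x}, \code{lambda_c},
#'   \code{combined} and \code{penalized}.
#' @export
compute_fitness <- function(tree, X, y, cfg = stability_config()) {
  ev <- evaluate(tree, X)
  if (!all(ev$valid_mask)) {
    return(structure(list(rmse_train = NA_real_, stbl_x = NA_real_,
                          stbl_c = NA_real_, lambda_x = cfg$lambda_x,
                          lambda_c = cfg$lambda_c,
                          combined = .WORST_FITNESS, penalized = TRUE),
                     class = "figp_fitness"))
  }
  rmse <- sqrt(mean((ev$values - y)^2))
  sx <- if (cfg$lambda_x > 0) stbl_x(tree, X, cfg) else 0
  sc <- if (cfg$lambda_c > 0) stbl_c(tree, X, cfg) else 0
  structure(list(rmse_train = rmse, stbl_x = sx, stbl_c = sc,
                 lambda_x = cfg$lambda_x, lambda_c = cfg$lambda_c,
                 combined = rmse + cfg$lambda_x * sx + cfg$lambda_c * sc,
                 penalized = FALSE),
            class = "figp_fitness")
}

#' @export
print.figp_fitness <- function(x, ...) {
  cat(sprintf(
    "fitness %.4g = RMSE %.4g + %.2g*STBL_x %.4g + %.2g*STBL_c %.4g%s\n",
    x$combined, x$rmse_train, x$lambda_x, x$stbl_x, x$lambda_c, x$stbl_c,
    if (x$penalized) " [penalized]" else ""))
  invisible(x)
}
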