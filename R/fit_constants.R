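# residual magnitude assigned to rows where the candidate expression
# evaluates invalidly, steering the optimizer away from such regions
.INVALID_RESIDUAL <- 1e6

#' Least-squares optimization of a tree's constants
#'
#' Refines every constant node of a candidate expression by damped
#' (Levenberg-Marquardt) nonlinear least squares against training
#' data, started at the tree's current constants. Rows where the
#' expression evaluates invalidly contribute a large finite penalty
#' residual (1e6). If the optimizer fails to improve on the starting
#' constants, they are kept, so the fit never worsens the tree.
#'
#' @param tree An expression tree.
#' @param X Descriptor data.frame covering the tree's variables.
#' @param y Finite numeric response vector, \code{length(y) == nrow(X)}.
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence tolerance on the sum of squares (default 1e-8).
#' @param retry_from_ones When TRUE (default) and the first fit is no
#'   better than predicting the response mean, a second deterministic
#'   fit is started from all constants = 1 (a scale-neutral start that
#'   avoids poles at typical positive descriptor values) and the
#'   better result kept.
#' @return A list with \code{fitted_tree} (same structure, updated
#'   constants), \code{sse}, \code{converged} and \code{n_iterations}.
#' @examples
#' X <- data.frame(logp = 1:5)
#' y <- 0.5 * X$logp + 6.9
#' t <- node_op("+", list(node_op("*", list(node_const(1), node_var("logp"))),
#'                        node_const(0)))
#' fit_constants(t, X, y)$sse  # ~0
#' @export
fit_constants <- function(tree, X, y, max_iter = 200L, tol = 1e-8,
                          retry_from_ones = TRUE) {
  stopifnot(is_tree(tree))
  if (!all(is.finite(y))) stop("input error: y contains non-finite values")
  n <- nrow(as.data.frame(X))
  if (n != length(y)) stop("input error: nrow(X) != length(y)")

  compiled <- compile_tree(tree)
  Xl <- as.list(X)
  resid_at <- function(cv) {
    v <- eval_compiled(compiled, Xl, constants = cv, n_rows = n)
    r <- v - y
    bad <- !is.finite(v)
    if (any(bad)) r[bad] <- .INVALID_RESIDUAL
    r
  }
  c0 <- compiled$constants
  sse0 <- sum(resid_at(c0)^2)

  if (compiled$n_const == 0L)
    return(list(fitted_tree = tree, sse = sse0, converged = TRUE,
                n_iterations = 0L))

  lm_from <- function(start) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_at,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = tol, ptol = tol)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    res$sse <- sum(resid_at(res$par)^2)
    if (!is.finite(res$sse)) return(NULL)
    res
  }

  best <- lm_from(c0)
  # a fit no better than the response mean suggests a poor local
  # optimum; retry once from the scale-neutral all-ones start
  sse_mean <- sum((y - mean(y))^2)
  if (retry_from_ones &&
      (is.null(best) || best$sse > 0.95 * sse_mean)) {
    alt <- lm_from(rep(1, compiled$n_const))
    if (!is.null(alt) && (is.null(best) || alt$sse < best$sse)) best <- alt
  }

  if (is.null(best) || best$sse > sse0) {  # fall back: never worsen
    return(list(fitted_tree = tree, sse = sse0, converged = FALSE,
                n_iterations = if (is.null(best)) 0L else best$niter))
  }
  list(fitted_tree = set_constants(tree, as.numeric(best$par)),
       sse = best$sse,
       converged = best$info %in% 1:4,
       n_iterations = best$niter)
}
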