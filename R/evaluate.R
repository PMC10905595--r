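# Tree evaluation. Trees are compiled once into an R expression over
# the guarded operator functions, with constants lifted into a
# parameter vector .c so the least-squares fitter can re-evaluate the
# same structure at new constants without recompiling.

#' @keywords internal
compile_tree <- function(tree) {
  i <- 0L
  build <- function(nd) {
    switch(nd$kind,
      const = { i <<- i + 1L; bquote(.c[.(i)]) },
      var   = as.name(nd$name),
      op    = {
        fn <- switch(nd$op,
          "+" = quote(s_add), "-" = quote(s_sub),
          "*" = quote(s_mul), "/" = quote(s_div),
          "sqrt" = quote(s_sqrt), "square" = quote(s_square),
          "cube" = quote(s_cube), "exp" = quote(s_exp), "ln" = quote(s_ln))
        as.call(c(fn, lapply(nd$children, build)))
      }
    )
  }
  expr <- build(tree)
  vars <- unique(tree_metrics(tree)$variables_used)
  list(expr = expr, n_const = i, constants = get_constants(tree), vars = vars)
}

#' @keywords internal
eval_compiled <- function(compiled, X, constants = compiled$constants,
                          n_rows = NULL) {
  env <- list2env(as.list(X), parent = asNamespace("figp2"))
  assign(".c", constants, envir = env)
  v <- eval(compiled$expr, env)
  n <- if (is.null(n_rows)) {
    if (length(compiled$vars)) length(X[[compiled$vars[1]]]) else 1L
  } else n_rows
  if (length(v) == 1L && n > 1L) v <- rep(v, n)
  v
}

#' Evaluate an expression tree on a descriptor table
#'
#' Row-wise evaluation with exact operator semantics. Rows that
#' trigger an invalid operation anywhere in the tree (division by
#' zero, log of a non-positive value, square root of a negative value,
#' overflow past 1e300) are flagged invalid instead of raising; the
#' invalidity propagates through subsequent operations.
#'
#' @param tree An expression tree.
#' @param X A data.frame or named list of numeric columns covering
#'   every variable in the tree.
#' @return A list with \code{values} (numeric; \code{NaN} on invalid
#'   rows) and \code{valid_mask} (logical), both of length
#'   \code{nrow(X)}.
#' @examples
#' t <- node_op("ln", list(node_var("logp")))
#' evaluate(t, data.frame(logp = c(-1, 0, 2)))$valid_mask
#' @export
evaluate <- function(tree, X) {
  stopifnot(is_tree(tree))
  vars <- unique(tree_metrics(tree)$variables_used)
  missing_cols <- setdiff(vars, names(X))
  if (length(missing_cols))
    stop("input error: X is missing feature column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- if (is.data.frame(X)) nrow(X) else
    if (length(X)) length(X[[1]]) else 1L
  compiled <- compile_tree(tree)
  v <- eval_compiled(compiled, X, n_rows = n)
  valid <- is.finite(v)
  v[!valid] <- NaN
  list(values = v, valid_mask = valid)
}
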