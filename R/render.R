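#' Render an expression tree as a human-readable formula
#'
#' Infix rendering with minimal parentheses and constants printed with
#' \code{digits} significant digits (default 3). Operands of the
#' commutative operators are put in canonical order first (see
#' [tree_canonical()]), so structurally equal trees always render to
#' the same string: products lead with their constant
#' (\code{0.547*logp}) and sums trail with it (\code{... + 6.9}).
#' \code{square} and \code{cube} render as \code{^2} and \code{^3},
#' \code{ln} as \code{ln(...)}.
#'
#' @param tree An expression tree.
#' @param digits Significant digits for constants.
#' @return A single string; [parse_formula()] of it reproduces the
#'   canonical tree (with constants at the printed precision).
#' @examples
#' t <- node_op("+", list(node_const(6.90),
#'        node_op("*", list(node_var("logp"), node_const(0.547)))))
#' render_formula(t)  # "0.547*logp + 6.9"
#' @export
render_formula <- function(tree, digits = 3) {
  stopifnot(is_tree(tree))
  tree <- tree_canonical(tree)
  prec <- c("+" = 1, "-" = 1, "*" = 2, "/" = 2)
  fmt_const <- function(v) sprintf("%.*g", digits, v)
  walk <- function(nd) {
    switch(nd$kind,
      const = list(s = fmt_const(nd$value),
                   prec = if (nd$value < 0) 0 else 4),
      var   = list(s = nd$name, prec = 4),
      op    = {
        if (.OP_TABLE[[nd$op]]$arity == 1L) {
          a <- walk(nd$children[[1]])
          if (nd$op %in% c("square", "cube")) {
            base <- if (a$prec < 4) paste0("(", a$s, ")") else a$s
            list(s = paste0(base, if (nd$op == "square") "^2" else "^3"),
                 prec = 3)
          } else {
            list(s = paste0(nd$op, "(", a$s, ")"), prec = 4)
          }
        } else {
          p <- prec[[nd$op]]
          l <- walk(nd$children[[1]]); r <- walk(nd$children[[2]])
          ls <- if (l$prec < p) paste0("(", l$s, ")") else l$s
          # right operand keeps parens at equal precedence so the
          # parser cannot reassociate the shape
          rs <- if (r$prec <= p) paste0("(", r$s, ")") else r$s
          sep <- if (p == 2) "" else " "  # tight products, spaced sums
          list(s = paste0(ls, sep, nd$op, sep, rs), prec = p)
        }
      }
    )
  }
  walk(tree)$s
}

#' Parse a formula string into an expression tree
#'
#' Accepts the syntax emitted by [render_formula()] (a subset of R
#' expression syntax): \code{+ - * /}, \code{^2}/\code{^3} powers,
#' \code{sqrt()}, \code{exp()}, \code{ln()} (or \code{log()}), numeric
#' literals and variable names. A unary minus on a constant folds into
#' the constant; on any other expression it becomes multiplication by
#' -1.
#'
#' @param text Formula string.
#' @return An expression tree in canonical form.
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lang <- tryCatch(str2lang(text),
                   error = function(e) stop("cannot parse formula: ", text))
  walk <- function(e) {
    if (is.numeric(e)) return(node_const(e))
    if (is.name(e)) return(node_var(as.character(e)))
    if (!is.call(e)) stop("unsupported element in formula: ", deparse(e))
    head <- as.character(e[[1]])
    args <- as.list(e)[-1]
    if (head == "(") return(walk(args[[1]]))
    if (head == "-" && length(args) == 1L) {
      inner <- walk(args[[1]])
      if (inner$kind == "const") return(node_const(-inner$value))
      return(node_op("*", list(node_const(-1), inner)))
    }
    if (head == "+" && length(args) == 1L) return(walk(args[[1]]))
    if (head == "^") {
      pw <- args[[2]]
      if (!is.numeric(pw) || !pw %in% c(2, 3))
        stop("only ^2 and ^3 powers are representable, got: ", deparse(e))
      return(node_op(if (pw == 2) "square" else "cube", list(walk(args[[1]]))))
    }
    if (head == "log") head <- "ln"
    if (!head %in% names(.OP_TABLE))
      stop("unknown operator in formula: ", head)
    node_op(head, lapply(args, walk))
  }
  tree_canonical(walk(lang))
}
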