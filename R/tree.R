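#' Expression-tree node constructors
#'
#' An expression tree is the individual of the genetic-programming
#' search and the model form of symbolic regression: a rooted tree
#' whose internal nodes are operators from [op_table()] and whose
#' leaves are descriptor variables or real constants. A single
#' terminal has depth 0.
#'
#' @param value Real value of a constant node.
#' @param name Feature name of a variable node, or operator name.
#' @param children List of child nodes; length must equal the
#'   operator's arity.
#' @return A node (a list with class \code{figp_node}); the tree is
#'   identified with its root node.
#' @examples
#' t <- node_op("+", list(node_op("*", list(node_const(0.5), node_var("logp"))),
#'                        node_const(6.9)))
#' render_formula(t)
#' @name tree-nodes
NULL

#' @rdname tree-nodes
#' @export
node_const <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(kind = "const", value = as.numeric(value)), class = "figp_node")
}

#' @rdname tree-nodes
#' @export
node_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(kind = "var", name = name), class = "figp_node")
}

#' @rdname tree-nodes
#' @export
node_op <- function(name, children) {
  spec <- .OP_TABLE[[name]]
  if (is.null(spec)) stop("unknown operator: ", name)
  if (length(children) != spec$arity)
    stop("operator ", name, " needs ", spec$arity, " children, got ", length(children))
  structure(list(kind = "op", op = name, children = children), class = "figp_node")
}

is_tree <- function(x) inherits(x, "figp_node")

#' Structural metrics of an expression tree
#'
#' @param tree An expression tree.
#' @return A list with \code{depth} (terminal = 0), \code{node_count},
#'   \code{variables_used} (character vector with one entry per
#'   occurrence) and \code{constant_count}.
#' @examples
#' tree_metrics(node_var("logp"))$depth  # 0
#' @export
tree_metrics <- function(tree) {
  stopifnot(is_tree(tree))
  vars <- character(0)
  n_const <- 0L
  n_nodes <- 0L
  depth <- function(nd) {
    n_nodes <<- n_nodes + 1L
    switch(nd$kind,
      const = { n_const <<- n_const + 1L; 0L },
      var   = { vars <<- c(vars, nd$name); 0L },
      op    = 1L + max(vapply(nd$children, depth, integer(1)))
    )
  }
  d <- depth(tree)
  list(depth = d, node_count = n_nodes, variables_used = vars,
       constant_count = n_const)
}

tree_depth <- function(tree) tree_metrics(tree)$depth

#' Random expression-tree construction ("grow" method)
#'
#' Draws a random tree whose depth lies in \code{depth_range}. Nodes
#' above the minimum depth are always operators; below the maximum
#' depth an operator is chosen with probability \code{p_op}, otherwise
#' a terminal. Terminals are a variable (uniform over
#' \code{feature_names}) with probability \code{p_var}, else an
#' ephemeral constant drawn uniformly from \code{const_range}.
#' Randomness comes from R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param feature_names Non-empty character vector of variable names.
#' @param depth_range Integer interval \code{c(min, max)}, both >= 0.
#' @param operators Character vector of operator names to draw from.
#' @param p_op Probability of placing an operator when both choices
#'   are allowed (default 0.5).
#' @param p_var Probability that a terminal is a variable (default 0.5;
#'   forced to 1 when \code{const_range} is NULL).
#' @param const_range Interval for ephemeral constants (default
#'   \code{c(-10, 10)}, covering pKi-scale intercepts; least-squares
#'   refitting makes the initial value nearly irrelevant).
#' @return An expression tree with depth in \code{depth_range}.
#' @export
build_random_tree <- function(feature_names, depth_range = c(1L, 2L),
                              operators = names(op_table()),
                              p_op = 0.5, p_var = 0.5,
                              const_range = c(-10, 10)) {
  if (length(feature_names) == 0L)
    stop("configuration error: feature_names must be non-empty")
  dmin <- as.integer(depth_range[1]); dmax <- as.integer(depth_range[2])
  stopifnot(dmin >= 0L, dmax >= dmin)
  terminal <- function() {
    if (!is.null(const_range) && stats::runif(1) >= p_var)
      node_const(stats::runif(1, const_range[1], const_range[2]))
    else
      node_var(sample(feature_names, 1L))
  }
  grow <- function(d) {
    make_op <- if (d < dmin) TRUE
               else if (d >= dmax) FALSE
               else stats::runif(1) < p_op
    if (!make_op) return(terminal())
    op <- sample(operators, 1L)
    node_op(op, lapply(seq_len(.OP_TABLE[[op]]$arity), function(i) grow(d + 1L)))
  }
  grow(0L)
}

# --- constant plumbing (used by the least-squares fit) -----------------

#' @keywords internal
get_constants <- function(tree) {
  out <- numeric(0)
  walk <- function(nd) {
    if (nd$kind == "const") out <<- c(out, nd$value)
    else if (nd$kind == "op") for (ch in nd$children) walk(ch)
  }
  walk(tree)
  out
}

#' @keywords internal
set_constants <- function(tree, values) {
  i <- 0L
  walk <- function(nd) {
    if (nd$kind == "const") {
      i <<- i + 1L
      nd$value <- values[i]
    } else if (nd$kind == "op") {
      nd$children <- lapply(nd$children, walk)
    }
    nd
  }
  out <- walk(tree)
  if (i != length(values))
    stop("expected ", i, " constants, got ", length(values))
  out
}

# --- canonical form and equality ---------------------------------------

# Deterministic ordering of commutative operands so that structurally
# equal trees render identically: products lead with constants
# (0.547*logp), sums trail with them (logp + 6.9); ties broken by the
# prefix serialization.
.kind_rank <- function(nd, op) {
  r <- switch(nd$kind, const = 1L, var = 2L, op = 3L)
  if (op == "+") r <- 4L - r
  r
}

# serialized form with constants at rendering precision, so canonical
# order is unchanged by printing constants at 3 significant digits
.prefix_rounded <- function(nd) {
  switch(nd$kind,
    const = sprintf("%.3g", nd$value),
    var   = nd$name,
    op    = paste0("(", nd$op, " ",
                   paste(vapply(nd$children, .prefix_rounded, character(1)),
                         collapse = " "), ")"))
}

#' Canonical form of a tree
#'
#' Reorders the operands of the commutative operators \code{+} and
#' \code{*} by a fixed key (node kind, then serialized form, constants
#' compared at rendering precision) so that structurally equal trees
#' compare and render identically.
#'
#' @param tree An expression tree.
#' @return The reordered tree.
#' @export
tree_canonical <- function(tree) {
  walk <- function(nd) {
    if (nd$kind != "op") return(nd)
    nd$children <- lapply(nd$children, walk)
    if (nd$op %in% c("+", "*")) {
      key <- vapply(nd$children, function(ch)
        sprintf("%d|%s|%s", .kind_rank(ch, nd$op), .prefix_rounded(ch),
                tree_to_prefix(ch)), character(1))
      nd$children <- nd$children[order(key, method = "radix")]
    }
    nd
  }
  walk(tree)
}

#' Exact structural equality of two trees
#'
#' @param a,b Expression trees.
#' @param canonical Compare canonical forms (default TRUE), so operand
#'   order of commutative operators is ignored.
#' @param tol Absolute tolerance on constant values (default 0: exact).
#' @return TRUE or FALSE.
#' @export
tree_equal <- function(a, b, canonical = TRUE, tol = 0) {
  if (canonical) { a <- tree_canonical(a); b <- tree_canonical(b) }
  eq <- function(x, y) {
    if (x$kind != y$kind) return(FALSE)
    switch(x$kind,
      const = abs(x$value - y$value) <= tol,
      var   = x$name == y$name,
      op    = x$op == y$op &&
        all(mapply(eq, x$children, y$children))
    )
  }
  eq(a, b)
}

# --- exact prefix serialization ----------------------------------------

#' Prefix (s-expression) serialization of a tree
#'
#' Lossless round-trip form used for logging and exact comparisons;
#' constants are written with 17 significant digits.
#'
#' @param tree An expression tree.
#' @return A single string, e.g. \code{"(+ (* 0.5 logp) 6.9)"}.
#' @seealso [tree_from_prefix()]
#' @export
tree_to_prefix <- function(tree) {
  walk <- function(nd) {
    switch(nd$kind,
      const = sprintf("%.17g", nd$value),
      var   = nd$name,
      op    = paste0("(", nd$op, " ",
                     paste(vapply(nd$children, walk, character(1)),
                           collapse = " "), ")")
    )
  }
  walk(tree)
}

#' @rdname tree_to_prefix
#' @param text A string produced by [tree_to_prefix()].
#' @export
tree_from_prefix <- function(text) {
  toks <- strsplit(gsub("([()])", " \\1 ", text), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  pos <- 1L
  parse1 <- function() {
    tk <- toks[pos]; pos <<- pos + 1L
    if (tk == "(") {
      op <- toks[pos]; pos <<- pos + 1L
      kids <- list()
      while (toks[pos] != ")") kids[[length(kids) + 1L]] <- parse1()
      pos <<- pos + 1L
      node_op(op, kids)
    } else if (grepl("^[-+]?([0-9]|\\.[0-9])", tk)) {
      node_const(as.numeric(tk))
    } else {
      node_var(tk)
    }
  }
  out <- parse1()
  if (pos != length(toks) + 1L) stop("trailing tokens in prefix form")
  out
}

#' @export
print.figp_node <- function(x, ...) {
  cat("<expression tree> ", render_formula(x), "\n", sep = "")
  m <- tree_metrics(x)
  cat("  depth ", m$depth, ", ", m$node_count, " nodes, ",
      m$constant_count, " constants\n", sep = "")
  invisible(x)
}
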