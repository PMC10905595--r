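# Independent brute-force oracles used to cross-check the package's
# structural and numeric operations. These deliberately avoid the
# implementation paths they verify.

# depth/node-count by plain recursion over the raw list structure
oracle_depth <- function(nd) {
  if (nd$kind != "op") return(0L)
  1L + max(vapply(nd$children, oracle_depth, integer(1)))
}
oracle_count <- function(nd) {
  if (nd$kind != "op") return(1L)
  1L + sum(vapply(nd$children, oracle_count, integer(1)))
}

# variable occurrences by walking the raw structure
oracle_var_counts <- function(nd) {
  if (nd$kind == "var") return(stats::setNames(1L, nd$name))
  if (nd$kind != "op") return(integer(0))
  counts <- integer(0)
  for (ch in nd$children) {
    cc <- oracle_var_counts(ch)
    for (nm in names(cc)) counts[nm] <- sum(counts[nm], cc[nm], na.rm = TRUE)
  }
  counts
}

# F-filter oracle: explicit scan of every node's ancestor operator path
oracle_f_ok <- function(tree, groups = default_f_groups()) {
  grp <- function(op) {
    for (i in seq_along(groups)) if (op %in% groups[[i]]) return(i)
    NA_integer_
  }
  ok <- TRUE
  walk <- function(nd, anc_groups) {
    if (nd$kind != "op") return()
    g <- grp(nd$op)
    if (!is.na(g) && g %in% anc_groups) ok <<- FALSE
    for (ch in nd$children) walk(ch, c(anc_groups, g))
  }
  walk(tree, integer(0))
  ok
}

# exhaustive enumeration of variable-only trees of depth <= 2
enumerate_trees_depth2 <- function(features = c("a", "b")) {
  terminals <- lapply(features, node_var)
  ops <- op_table()
  depth1 <- list()
  for (op in names(ops)) {
    if (ops[[op]]$arity == 1L) {
      for (t1 in terminals)
        depth1[[length(depth1) + 1L]] <- node_op(op, list(t1))
    } else {
      for (t1 in terminals) for (t2 in terminals)
        depth1[[length(depth1) + 1L]] <- node_op(op, list(t1, t2))
    }
  }
  le1 <- c(terminals, depth1)
  depth2 <- list()
  for (op in names(ops)) {
    if (ops[[op]]$arity == 1L) {
      for (t1 in depth1)
        depth2[[length(depth2) + 1L]] <- node_op(op, list(t1))
    } else {
      for (t1 in le1) for (t2 in le1) {
        if (oracle_depth(t1) == 0L && oracle_depth(t2) == 0L) next
        depth2[[length(depth2) + 1L]] <- node_op(op, list(t1, t2))
      }
    }
  }
  c(le1, depth2)
}

# dense-grid range oracle over a 2-variable box
grid_range <- function(tree, box, n_grid = 200L) {
  vars <- names(box)
  g <- lapply(box, function(iv) seq(iv[1], iv[2], length.out = n_grid))
  X <- expand.grid(g)
  names(X) <- vars
  ev <- evaluate(tree, X)
  if (!all(ev$valid_mask)) return(NULL)
  range(ev$values)
}

# random tree drawing used across property tests
random_tree <- function(features = c("u", "v"), depth = c(1L, 3L),
                        const_range = c(-3, 3)) {
  build_random_tree(features, depth, const_range = const_range)
}

make_linear_fixture <- function(n = 25) {
  X <- data.frame(logp = seq(-1, 4, length.out = n))
  list(X = X, y = 0.5 * X$logp + 6.9)
}
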