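#' Domain specification for the domain filters
#'
#' A per-variable closed box (descriptor units) and a closed target
#' range for the response (pKi units). The domain filters certify that
#' a candidate expression's outputs stay inside the target range over
#' the box.
#'
#' @param variable_box Named list of \code{c(lo, hi)} intervals, one
#'   per feature.
#' @param target_range \code{c(lo, hi)} interval for y.
#' @param source One of \code{"from_training"},
#'   \code{"from_training_and_test"}, \code{"user_supplied"}.
#' @return An object of class \code{figp_domain_spec}.
#' @export
domain_spec <- function(variable_box, target_range,
                        source = c("user_supplied", "from_training",
                                   "from_training_and_test")) {
  source <- match.arg(source)
  stopifnot(is.list(variable_box), !is.null(names(variable_box)),
            length(target_range) == 2L, target_range[1] <= target_range[2])
  for (nm in names(variable_box)) {
    iv <- variable_box[[nm]]
    if (length(iv) != 2L || iv[1] > iv[2])
      stop("invalid interval for ", nm)
  }
  structure(list(variable_box = variable_box,
                 target_range = as.numeric(target_range),
                 source = source),
            class = "figp_domain_spec")
}

#' Build a DomainSpec from data
#'
#' Per-column min/max of the supplied rows define the box; min/max of
#' y defines the target range. The default uses the training split
#' only; supplying test rows as well reproduces the
#' training-plus-test convention but leaks test information into the
#' filter and is flagged as such in the spec's \code{source} field.
#'
#' @param X Descriptor data.frame (training split).
#' @param y Response vector aligned with \code{X}.
#' @param X_test,y_test Optional test split to widen the ranges.
#' @return A \code{figp_domain_spec}.
#' @export
domain_spec_from_data <- function(X, y, X_test = NULL, y_test = NULL) {
  if (!is.null(X_test)) { X <- rbind(X, X_test); y <- c(y, y_test) }
  box <- lapply(as.list(X), range)
  domain_spec(box, range(y),
              source = if (is.null(X_test)) "from_training"
                       else "from_training_and_test")
}

#' @rdname domain_spec
#' @param x A \code{figp_domain_spec} (or, for
#'   \code{domain_spec_from_list}, a plain list as produced by
#'   \code{domain_spec_to_list}, e.g. read from YAML/JSON).
#' @export
domain_spec_to_list <- function(x) {
  c(lapply(x$variable_box, as.numeric),
    list(target = x$target_range, source = x$source))
}

#' @rdname domain_spec
#' @export
domain_spec_from_list <- function(x) {
  src <- if (is.null(x$source)) "user_supplied" else x$source
  box <- x[setdiff(names(x), c("target", "source"))]
  domain_spec(box, x$target, source = src)
}

filter_report <- function(passed, filter_name, detail = "") {
  if (!passed && !nzchar(detail)) detail <- "rejected"
  structure(list(passed = passed, filter_name = filter_name, detail = detail),
            class = "figp_filter_report")
}

#' @export
print.figp_filter_report <- function(x, ...) {
  cat(sprintf("%s-filter: %s%s\n", x$filter_name,
              if (x$passed) "pass" else "FAIL",
              if (nzchar(x$detail)) paste0(" (", x$detail, ")") else ""))
  invisible(x)
}

#' V-filter: single occurrence of each variable
#'
#' Rejects expressions in which any descriptor appears more than once
#' anywhere in the tree, e.g. \code{logp + ln(logp)}. Purely
#' structural: constant values are irrelevant.
#'
#' @param tree An expression tree.
#' @return A filter report (\code{$passed}, \code{$detail}).
#' @export
v_filter <- function(tree) {
  vars <- tree_metrics(tree)$variables_used
  dup <- unique(vars[duplicated(vars)])
  if (length(dup))
    filter_report(FALSE, "V",
                  paste0("variable(s) appearing more than once: ",
                         paste(dup, collapse = ", ")))
  else filter_report(TRUE, "V")
}

#' F-filter: no nesting within operator groups
#'
#' Rejects expressions where an operator has another operator from the
#' same group anywhere on its ancestor path (default groups
#' \code{{sqrt}}, \code{{square, cube}}, \code{{ln, exp}}):
#' \code{sqrt(sqrt(x))} and \code{ln(1 + exp(x))} fail,
#' \code{x^2 + y^3} passes (siblings, not nested).
#'
#' @param tree An expression tree.
#' @param groups List of character vectors of operator names.
#' @return A filter report.
#' @export
f_filter <- function(tree, groups = default_f_groups()) {
  group_of <- function(op) {
    for (i in seq_along(groups)) if (op %in% groups[[i]]) return(i)
    NA_integer_
  }
  bad <- NULL
  walk <- function(nd, active) {
    if (!is.null(bad) || nd$kind != "op") return()
    g <- group_of(nd$op)
    if (!is.na(g) && !is.null(active[[as.character(g)]])) {
      bad <<- c(active[[as.character(g)]], nd$op)
      return()
    }
    if (!is.na(g)) active[[as.character(g)]] <- nd$op
    for (ch in nd$children) walk(ch, active)
  }
  walk(tree, list())
  if (!is.null(bad))
    filter_report(FALSE, "F",
                  paste0("nested operators from one group: ",
                         bad[1], " > ", bad[2]))
  else filter_report(TRUE, "F")
}

#' D-filter: sample-based domain check
#'
#' Evaluates the expression on a set of probe points and passes only
#' if every evaluation is valid and every output lies within the
#' target range (widened by \code{slack} times its width on each
#' side). Probes between which a pole hides can slip through; the
#' optimization-based [d2_filter()] closes that gap.
#'
#' @param tree An expression tree.
#' @param probe_points Non-empty data.frame of probe rows.
#' @param target_range \code{c(lo, hi)} for the outputs.
#' @param slack Containment tolerance as a fraction of the target
#'   width (default 0.05).
#' @return A filter report.
#' @export
d_filter <- function(tree, probe_points, target_range, slack = 0.05) {
  stopifnot(nrow(probe_points) > 0)
  ev <- evaluate(tree, probe_points)
  if (!all(ev$valid_mask)) {
    i <- which(!ev$valid_mask)[1]
    return(filter_report(FALSE, "D",
      paste0("invalid evaluation at probe row ", i)))
  }
  w <- diff(target_range) * slack
  lo <- target_range[1] - w; hi <- target_range[2] + w
  out <- ev$values < lo | ev$values > hi
  if (any(out)) {
    i <- which(out)[1]
    return(filter_report(FALSE, "D",
      sprintf("output %.4g at probe row %d outside target [%.4g, %.4g]",
              ev$values[i], i, lo, hi)))
  }
  filter_report(TRUE, "D")
}

#' Uniform probe points over an expanded data box
#'
#' Helper for the D-filter when no external compound data is
#' available: uniform draws in a box expanded around the training span
#' of each feature (default 1.5 times the half-width on each side of
#' the midpoint).
#'
#' @param X Training descriptor data.frame.
#' @param n Number of probes (default 10000).
#' @param expand Expansion factor on the half-width (default 1.5).
#' @return A data.frame of probe rows.
#' @export
make_probe_points <- function(X, n = 10000L, expand = 1.5) {
  cols <- lapply(X, function(col) {
    r <- range(col); mid <- mean(r); h <- diff(r) / 2 * expand
    stats::runif(n, mid - h, mid + h)
  })
  as.data.frame(cols)
}

# penalty objective value for invalid evaluations during range search
.RANGE_PENALTY <- 1e12

#' Estimate the range of an expression over a domain box
#'
#' Multi-start bounded minimization of f and of -f (L-BFGS-B with
#' numerical gradients) over the per-variable box. Start points are
#' rows sampled without replacement from the training set when
#' supplied, otherwise uniform in the box; starts are clipped into the
#' box. An invalid evaluation at an in-box query point marks the
#' expression uncertifiable. Uses R's global RNG for start selection.
#'
#' @param tree An expression tree.
#' @param box Named list of \code{c(lo, hi)} intervals covering the
#'   tree's variables.
#' @param n_restarts Number of start points per direction (default 5).
#' @param start_points Optional data.frame of candidate start rows
#'   (e.g. training X).
#' @param maxit Iteration cap per local search (default 200).
#' @return A list with \code{min_value}, \code{max_value},
#'   \code{argmin}, \code{argmax}, \code{n_restarts_used},
#'   \code{invalid_encountered} and \code{ok} (FALSE when no restart
#'   found a valid point in some direction).
#' @export
estimate_range <- function(tree, box, n_restarts = 5L, start_points = NULL,
                           maxit = 200L) {
  vars <- unique(tree_metrics(tree)$variables_used)
  missing_vars <- setdiff(vars, names(box))
  if (length(missing_vars))
    stop("box does not cover variable(s): ",
         paste(missing_vars, collapse = ", "))
  compiled <- compile_tree(tree)

  if (length(vars) == 0L) {  # constant expression
    v <- eval_compiled(compiled, list(), n_rows = 1L)
    ok <- is.finite(v)
    return(list(min_value = v, max_value = v, argmin = numeric(0),
                argmax = numeric(0), n_restarts_used = 0L,
                invalid_encountered = !ok, ok = ok))
  }

  lower <- vapply(box[vars], `[`, numeric(1), 1L)
  upper <- vapply(box[vars], `[`, numeric(1), 2L)
  invalid_seen <- FALSE
  f_at <- function(x) {
    v <- eval_compiled(compiled, stats::setNames(as.list(x), vars), n_rows = 1L)
    if (!is.finite(v)) {
      # only in-box failures make the expression uncertifiable; the
      # finite-difference gradient may step marginally outside bounds
      if (all(x >= lower - 1e-8) && all(x <= upper + 1e-8))
        invalid_seen <<- TRUE
      return(NA_real_)
    }
    v
  }

  starts <- matrix(NA_real_, n_restarts, length(vars))
  if (!is.null(start_points) && nrow(start_points) > 0L) {
    idx <- sample(nrow(start_points), min(n_restarts, nrow(start_points)))
    for (i in seq_along(idx))
      starts[i, ] <- as.numeric(start_points[idx[i], vars])
  }
  for (i in seq_len(n_restarts))
    if (anyNA(starts[i, ]))
      starts[i, ] <- stats::runif(length(vars), lower, upper)
  starts <- pmin(pmax(starts, matrix(lower, n_restarts, length(vars),
                                     byrow = TRUE)),
                 matrix(upper, n_restarts, length(vars), byrow = TRUE))

  search <- function(sign) {
    obj <- function(x) {
      v <- f_at(x)
      if (is.na(v)) .RANGE_PENALTY else sign * v
    }
    best <- NULL
    for (i in seq_len(n_restarts)) {
      res <- tryCatch(
        stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = maxit)),
        error = function(e) NULL)
      if (is.null(res) || res$value >= .RANGE_PENALTY / 2) next
      if (is.null(best) || res$value < best$value) best <- res
    }
    best
  }
  bmin <- search(1); bmax <- search(-1)
  ok <- !is.null(bmin) && !is.null(bmax)
  list(
    min_value = if (ok) bmin$value else NA_real_,
    max_value = if (ok) -bmax$value else NA_real_,
    argmin = if (ok) stats::setNames(bmin$par, vars) else NULL,
    argmax = if (ok) stats::setNames(bmax$par, vars) else NULL,
    n_restarts_used = n_restarts,
    invalid_encountered = invalid_seen,
    ok = ok
  )
}

#' D2-filter: optimization-based domain check
#'
#' Directly estimates the minimum and maximum of the candidate
#' expression over the descriptor box by multi-start bounded
#' optimization (see [estimate_range()]) and passes only if the whole
#' estimated range lies within the target range (with \code{slack}
#' tolerance) and no invalid operation was encountered inside the box.
#' Unlike the sample-based D-filter this needs no external data points
#' and cannot miss a pole between probes.
#'
#' @param tree An expression tree.
#' @param spec A [domain_spec()].
#' @param n_restarts Restarts per direction (default 5).
#' @param start_points Optional data.frame of start rows (training X).
#' @param slack Containment tolerance as a fraction of the target
#'   width (default 0.05).
#' @return A filter report.
#' @export
d2_filter <- function(tree, spec, n_restarts = 5L, start_points = NULL,
                      slack = 0.05) {
  stopifnot(inherits(spec, "figp_domain_spec"))
  est <- estimate_range(tree, spec$variable_box, n_restarts = n_restarts,
                        start_points = start_points)
  if (!est$ok)
    return(filter_report(FALSE, "D2", "range estimation failed on the box"))
  if (est$invalid_encountered)
    return(filter_report(FALSE, "D2",
                         "invalid operation inside the domain box"))
  tr <- spec$target_range
  w <- diff(tr) * slack
  if (est$min_value < tr[1] - w || est$max_value > tr[2] + w)
    return(filter_report(FALSE, "D2",
      sprintf("estimated range [%.4g, %.4g] outside target [%.4g, %.4g]",
              est$min_value, est$max_value, tr[1], tr[2])))
  filter_report(TRUE, "D2")
}
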