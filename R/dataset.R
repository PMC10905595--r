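#' The ten substituent descriptors
#'
#' The standard descriptor vocabulary: arings (aromatic ring count),
#' acc / don (H-bond acceptor / donor counts), a_heavy (heavy atom
#' count), logp (octanol-water partition coefficient), rbc (rotatable
#' bond count), rings (ring count), tpsa (topological polar surface
#' area, A^2), vdw_vol (van der Waals volume, A^3), mw (molecular
#' weight, Da).
#'
#' @return Character vector of the ten descriptor names.
#' @export
descriptor_names <- function() {
  c("arings", "acc", "don", "a_heavy", "logp",
    "rbc", "rings", "tpsa", "vdw_vol", "mw")
}

#' Preset feature sets
#'
#' Three nested descriptor subsets used throughout the benchmarking
#' protocol: FEAT10 (all ten), FEAT7 and FEAT4, chosen to strip
#' descriptors that move together.
#'
#' @param name \code{"FEAT10"}, \code{"FEAT7"} or \code{"FEAT4"}.
#' @return Character vector of descriptor names.
#' @examples
#' feature_set("FEAT4")
#' @export
feature_set <- function(name = c("FEAT10", "FEAT7", "FEAT4")) {
  name <- match.arg(name)
  switch(name,
    FEAT10 = descriptor_names(),
    FEAT7  = c("arings", "acc", "don", "logp", "rbc", "tpsa", "mw"),
    FEAT4  = c("logp", "rbc", "tpsa", "mw"))
}

#' Construct a compound dataset
#'
#' @param X Numeric data.frame of descriptors (no missing values).
#' @param y Numeric potency vector (pKi), aligned with \code{X}.
#' @param ids Optional compound identifiers.
#' @param smiles Optional structure strings.
#' @return An object of class \code{figp_dataset}.
#' @export
figp_dataset <- function(X, y, ids = NULL, smiles = NULL) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("input error: all descriptor columns must be numeric")
  if (anyNA(X) || anyNA(y)) stop("input error: missing values in X or y")
  structure(list(X = X, y = as.numeric(y), ids = ids, smiles = smiles),
            class = "figp_dataset")
}

#' @export
print.figp_dataset <- function(x, ...) {
  cat("<figp_dataset> ", nrow(x$X), " compounds, ",
      ncol(x$X), " descriptors (", paste(names(x$X), collapse = ", "),
      ")\n  pKi range [", sprintf("%.2f", min(x$y)), ", ",
      sprintf("%.2f", max(x$y)), "]\n", sep = "")
  invisible(x)
}

#' Read a delimited descriptor table
#'
#' Reads a CSV/TSV table of compounds (rows) by descriptors (columns)
#' plus a potency column. Rows containing any missing value among the
#' requested columns are dropped with a message.
#'
#' @param path File path.
#' @param target_column Name of the potency column (default
#'   \code{"pKi"}).
#' @param feature_columns Descriptor columns to keep; default: every
#'   member of [descriptor_names()] present in the file.
#' @param sep Field separator (default \code{","}).
#' @return A [figp_dataset()].
#' @export
read_table <- function(path, target_column = "pKi", feature_columns = NULL,
                       sep = ",") {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(feature_columns))
    feature_columns <- intersect(descriptor_names(), names(df))
  missing_cols <- setdiff(c(feature_columns, target_column), names(df))
  if (length(missing_cols))
    stop("input error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cn in c(feature_columns, target_column))
    if (!is.numeric(df[[cn]]))
      stop("input error: non-numeric values in column ", cn)
  keep <- stats::complete.cases(df[, c(feature_columns, target_column)])
  if (any(!keep))
    message("dropped ", sum(!keep), " row(s) with missing values")
  df <- df[keep, , drop = FALSE]
  figp_dataset(df[, feature_columns, drop = FALSE], df[[target_column]],
               ids = if ("id" %in% names(df)) df[["id"]] else NULL,
               smiles = if ("smiles" %in% names(df)) df[["smiles"]] else NULL)
}

#' Write a dataset back to CSV
#'
#' @param ds A [figp_dataset()].
#' @param path Output path.
#' @param target_column Potency column name.
#' @export
write_table <- function(ds, path, target_column = "pKi") {
  df <- ds$X
  df[[target_column]] <- ds$y
  if (!is.null(ds$ids)) df <- cbind(id = ds$ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project a dataset onto a feature subset
#'
#' @param ds A [figp_dataset()].
#' @param features Character vector of column names to keep.
#' @return A [figp_dataset()] with only those columns.
#' @export
subset_features <- function(ds, features) {
  missing_cols <- setdiff(features, names(ds$X))
  if (length(missing_cols))
    stop("input error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  figp_dataset(ds$X[, features, drop = FALSE], ds$y,
               ids = ds$ids, smiles = ds$smiles)
}

#' Random train/test split
#'
#' Uniform random partition with \code{round(n * train_ratio)} training
#' rows; reproducible under a fixed seed of R's global RNG.
#'
#' @param ds A [figp_dataset()].
#' @param train_ratio Fraction in (0, 1).
#' @return A list with \code{train} and \code{test} datasets and the
#'   row indices \code{train_idx}.
#' @export
split_train_test <- function(ds, train_ratio) {
  stopifnot(train_ratio > 0, train_ratio < 1)
  n <- nrow(ds$X)
  n_train <- round(n * train_ratio)
  if (n_train < 2L || n - n_train < 2L)
    stop("split too small: ", n_train, " train / ", n - n_train, " test rows")
  idx <- sort(sample(n, n_train))
  take <- function(i) figp_dataset(ds$X[i, , drop = FALSE], ds$y[i],
                                   ids = ds$ids[i], smiles = ds$smiles[i])
  list(train = take(idx), test = take(setdiff(seq_len(n), idx)),
       train_idx = idx)
}

#' Generate a synthetic ground-truth dataset
#'
#' Draws descriptors uniformly over a per-feature box and computes the
#' response from a known ground-truth expression plus additive
#' Gaussian noise. This emulates the shape of substituent-descriptor
#' QSAR tables while giving recovery tests an exact target. Uses R's
#' global RNG.
#'
#' @param ground_truth An expression tree, or a formula string parsed
#'   by [parse_formula()].
#' @param variable_box Named list of \code{c(lo, hi)} intervals.
#' @param n_samples Number of rows.
#' @param noise_sigma Standard deviation of the additive noise
#'   (response units, default 0).
#' @return A [figp_dataset()] with attributes \code{ground_truth} and
#'   \code{variable_box} attached for recovery comparisons.
#' @examples
#' set.seed(1)
#' ds <- generate_synthetic("0.5*logp + 6.9",
#'                          list(logp = c(-1, 5)), 20, 0.1)
#' @export
generate_synthetic <- function(ground_truth, variable_box, n_samples,
                               noise_sigma = 0) {
  if (is.character(ground_truth)) ground_truth <- parse_formula(ground_truth)
  stopifnot(is_tree(ground_truth), noise_sigma >= 0, n_samples >= 1)
  X <- as.data.frame(lapply(variable_box, function(iv)
    stats::runif(n_samples, iv[1], iv[2])))
  ev <- evaluate(ground_truth, X)
  if (!all(ev$valid_mask))
    stop("generation error: ground truth invalid at ",
         sum(!ev$valid_mask), " sampled point(s)")
  y <- ev$values + stats::rnorm(n_samples, 0, noise_sigma)
  ds <- figp_dataset(X, y)
  attr(ds, "ground_truth") <- ground_truth
  attr(ds, "variable_box") <- variable_box
  ds
}

#' Built-in synthetic ground truths
#'
#' Three canonical formula shapes over descriptor-like variables -
#' linear, rational and saturating exponential - exercising every
#' operator group of the search vocabulary.
#'
#' @param name One of \code{"linear"}, \code{"rational"},
#'   \code{"saturating_exp"}.
#' @return A list with \code{tree} and \code{variable_box}.
#' @export
synthetic_ground_truth <- function(name = c("linear", "rational",
                                            "saturating_exp")) {
  name <- match.arg(name)
  switch(name,
    linear = list(
      tree = parse_formula("0.5*logp + 6.9"),
      variable_box = list(logp = c(-1, 5))),
    rational = list(
      tree = parse_formula("0.5*logp + 2/(tpsa + 1)"),
      variable_box = list(logp = c(-1, 5), tpsa = c(0, 60))),
    saturating_exp = list(
      tree = parse_formula("9 - 2*exp(-0.5*acc)"),
      variable_box = list(acc = c(0, 8))))
}
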