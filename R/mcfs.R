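#' Configuration for Monte-Carlo feature selection
#'
#' Monte-Carlo feature selection (MCFS) draws `s` random subspaces of `m`
#' features (with `m` much smaller than the total feature count `d`), grows
#' `t` decision trees per subspace on independent stratified train/test
#' splits, and scores every feature by its relative importance: a weighted
#' sum, over all nodes of all `s * t` trees that split on the feature, of the
#' node's information gain, weighted by the tree's held-out weighted accuracy
#' raised to `u` and the node's sample coverage raised to `v`.
#'
#' @param s number of random feature subsets.
#' @param t trees grown per subset.
#' @param m features per subset; `NULL` means `ceiling(0.05 * d)`, resolved
#'   when the data are seen.
#' @param u exponent on the tree's weighted accuracy.
#' @param v exponent on the node coverage ratio `n_node / n_tree`.
#' @param train_fraction per-tree training fraction in (0, 1); the remainder
#'   is the held-out split on which weighted accuracy is measured.
#' @param min_leaf minimum samples per leaf; trees are otherwise grown to
#'   purity without pruning.
#' @param seed integer seed controlling subspace draws and splits.
#' @return an object of class `mcfs_config`.
#' @export
mcfs_config <- function(s = 1000, t = 5, m = NULL, u = 1, v = 1,
                        train_fraction = 0.66, min_leaf = 2, seed = 1L) {
  cfg <- structure(
    list(s = as.integer(s), t = as.integer(t),
         m = if (is.null(m)) NULL else as.integer(m),
         u = as.numeric(u), v = as.numeric(v),
         train_fraction = as.numeric(train_fraction),
         min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
    class = "mcfs_config")
  if (cfg$s < 1) stop("invalid mcfs_config: s must be >= 1")
  if (cfg$t < 1) stop("invalid mcfs_config: t must be >= 1")
  if (!is.null(cfg$m) && cfg$m < 1) stop("invalid mcfs_config: m must be >= 1")
  if (cfg$u < 0 || cfg$v < 0) stop("invalid mcfs_config: u, v must be >= 0")
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stop("invalid mcfs_config: train_fraction must lie in (0, 1)")
  cfg
}

#' Weighted classification accuracy of a confusion matrix
#'
#' The mean per-class recall: `(1/c) * sum_i n_ii / sum_j n_ij`, where
#' `n_ij` counts samples of class `i` predicted as class `j`. Classes whose
#' row total is zero (absent from the held-out split) are dropped from the
#' average, so `c` is effectively the number of classes observed.
#'
#' @param cm square numeric matrix of counts, true classes in rows.
#' @return weighted accuracy in `[0, 1]`.
#' @examples
#' weighted_accuracy(matrix(c(3, 0, 1, 2), 2))  # (3/4 + 2/2) / 2 = 0.875
#' @export
weighted_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix counts must be >= 0")
  totals <- rowSums(cm)
  if (all(totals == 0)) stop("confusion matrix is all zero")
  keep <- totals > 0
  mean(diag(cm)[keep] / totals[keep])
}

# Internal: stratified train/test index split. Guarantees at least one
# training sample per class; test split may lose a class for tiny groups
# (weighted_accuracy then averages over observed classes only).
stratified_split <- function(labels, train_fraction) {
  train <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(length(idx) * train_fraction))
    n_tr <- min(n_tr, length(idx))
    train <- c(train, idx[sample.int(length(idx))[seq_len(n_tr)]])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Grow one decision tree on a feature subspace
#'
#' Splits the samples into a stratified train/test partition (consuming the
#' current RNG stream), grows a CART-style binary tree with the
#' information-gain criterion (bits) on the training part, and evaluates
#' weighted accuracy on the held-out part. Per internal node the splitting
#' feature, its information gain and the number of training samples reaching
#' the node are recorded; these drive [relative_importance()].
#'
#' @param x numeric matrix, samples in rows, subspace features in columns
#'   (column names are the feature IDs).
#' @param labels 0/1 (or small-integer) class vector.
#' @param config an [mcfs_config()]; only `train_fraction` and `min_leaf`
#'   are used here.
#' @return an object of class `tree_record`: list with `wacc`, `nodes`
#'   (list with `feature_id`, `ig`, `n_node` for every internal node) and
#'   `n_tree` (training-set size).
#' @export
grow_tree <- function(x, labels, config = mcfs_config()) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  classes <- sort(unique(labels))
  y <- match(labels, classes) - 1L
  sp <- stratified_split(labels, config$train_fraction)
  fit <- cart_grow(x[sp$train, , drop = FALSE], y[sp$train],
                   n_class = length(classes), min_leaf = config$min_leaf)
  if (length(sp$test) > 0) {
    pred <- cart_predict(fit, x[sp$test, , drop = FALSE])
    cm <- table(factor(y[sp$test], levels = seq_along(classes) - 1L),
                factor(pred, levels = seq_along(classes) - 1L))
    wacc <- weighted_accuracy(cm)
  } else {
    wacc <- NA_real_
  }
  internal <- fit$feature >= 0
  structure(list(
    wacc = wacc,
    nodes = list(feature_id = colnames(x)[fit$feature[internal] + 1L],
                 ig = fit$ig[internal],
                 n_node = fit$n_node[internal]),
    n_tree = fit$n_tree,
    fit = fit
  ), class = "tree_record")
}

#' Aggregate tree records into a relative-importance ranking
#'
#' For feature `g`, `RI_g = sum over trees tau of wacc(tau)^u * sum over
#' nodes of tau splitting on g of IG(node) * (n_node / n_tree)^v`. Features
#' never used in any node score 0. Ties (notably shared zeros) are broken by
#' feature ID in C-locale lexicographic order so output is deterministic.
#'
#' @param trees list of `tree_record` objects.
#' @param config an [mcfs_config()] supplying exponents `u` and `v`.
#' @param feature_ids optional universe of feature IDs to include (features
#'   absent from all trees are reported with RI 0); defaults to the features
#'   seen in the trees.
#' @return a `feature_ranking`: data frame with columns `rank`, `feature_id`,
#'   `ri`, sorted by decreasing RI.
#' @export
relative_importance <- function(trees, config = mcfs_config(),
                                feature_ids = NULL) {
  if (length(trees) == 0) stop("trees must be nonempty")
  fid <- unlist(lapply(trees, function(tr) tr$nodes$feature_id),
                use.names = FALSE)
  contrib <- unlist(lapply(trees, function(tr) {
    if (length(tr$nodes$ig) == 0) return(numeric(0))
    tr$wacc^config$u * tr$nodes$ig * (tr$nodes$n_node / tr$n_tree)^config$v
  }), use.names = FALSE)
  agg <- if (length(fid)) rowsum(contrib, fid) else
    matrix(numeric(0), 0, 1)
  if (is.null(feature_ids)) feature_ids <- rownames(agg)
  ri <- setNames(numeric(length(feature_ids)), feature_ids)
  hit <- intersect(rownames(agg), feature_ids)
  ri[hit] <- agg[hit, 1L]
  feature_ranking(names(ri), ri)
}

# Internal constructor: sort by RI descending, feature ID ascending
# (C locale), assign ranks 1..N.
feature_ranking <- function(feature_ids, scores) {
  ord <- order(-scores, feature_ids, method = "radix")
  structure(data.frame(rank = seq_along(ord),
                       feature_id = feature_ids[ord],
                       ri = unname(scores[ord]),
                       stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"))
}

#' Run Monte-Carlo feature selection
#'
#' Draws `s` random subspaces of `m` features from the combined matrix and
#' grows `t` trees per subspace, each on its own stratified train/test split;
#' the records are aggregated by [relative_importance()] over the full
#' feature universe. Deterministic for a fixed config seed: subsets are
#' processed in order and partial importances accumulated in subset order.
#'
#' @param data a `combined_matrix` from [combine_tissues()].
#' @param config an [mcfs_config()].
#' @return a `feature_ranking` over all features of `data`.
#' @export
run_mcfs <- function(data, config = mcfs_config()) {
  stopifnot(inherits(data, "combined_matrix"))
  if (length(unique(data$labels)) < 2)
    stop("both classes must be present")
  d <- ncol(data$x)
  m <- if (is.null(config$m)) min(d, as.integer(ceiling(0.05 * d))) else config$m
  if (m > d) stop(sprintf("configuration error: m (%d) exceeds d (%d)", m, d))
  with_private_seed(config$seed, {
    trees <- vector("list", config$s * config$t)
    k <- 0L
    for (si in seq_len(config$s)) {
      feats <- sample.int(d, m)
      xs <- data$x[, feats, drop = FALSE]
      for (ti in seq_len(config$t)) {
        k <- k + 1L
        trees[[k]] <- grow_tree(xs, data$labels, config)
      }
    }
    relative_importance(trees, config, feature_ids = colnames(data$x))
  })
}

#' Write / read a feature ranking as TSV
#'
#' Columns: `rank`, `feature_id`, `tissue`, `ri` (scores serialized with 17
#' significant digits for exact round trips).
#'
#' @param ranking a `feature_ranking`.
#' @param path file path.
#' @export
write_ranking <- function(ranking, path) {
  out <- data.frame(rank = ranking$rank, feature_id = ranking$feature_id,
                    tissue = feature_tissue(ranking$feature_id),
                    ri = sprintf("%.17g", ranking$ri))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(data.frame(rank = df$rank, feature_id = df$feature_id,
                       ri = as.numeric(df$ri), stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"))
}
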