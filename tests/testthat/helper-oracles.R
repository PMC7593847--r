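# Independent oracle implementations used to cross-check the package's
# computations. These are deliberately written as plain loops / direct
# formula transcriptions, not as calls into the code paths they verify.

# Mean per-class recall of a confusion matrix (rows with zero total dropped).
oracle_weighted_accuracy <- function(cm) {
  recalls <- c()
  for (i in seq_len(nrow(cm))) {
    tot <- sum(cm[i, ])
    if (tot > 0) recalls <- c(recalls, cm[i, i] / tot)
  }
  sum(recalls) / length(recalls)
}

# Literal loop transcription of the relative-importance sum:
# RI_g = sum_tau wacc^u * sum_{nodes on g} ig * (n_node / n_tree)^v
oracle_relative_importance <- function(trees, u, v, feature_ids) {
  ri <- setNames(numeric(length(feature_ids)), feature_ids)
  for (tr in trees) {
    for (idx in seq_along(tr$nodes$feature_id)) {
      g <- tr$nodes$feature_id[idx]
      ri[g] <- ri[g] +
        tr$wacc^u * tr$nodes$ig[idx] * (tr$nodes$n_node[idx] / tr$n_tree)^v
    }
  }
  ri
}

# Build a random tree_record over a feature pool (for RI oracle tests).
random_tree_record <- function(feature_pool) {
  n_tree <- sample(4:12, 1)
  n_nodes <- sample(0:6, 1)
  structure(list(
    wacc = runif(1),
    nodes = list(
      feature_id = sample(feature_pool, n_nodes, replace = TRUE),
      ig = runif(n_nodes, 0, 1),
      n_node = sample.int(n_tree, n_nodes, replace = TRUE)),
    n_tree = n_tree), class = "tree_record")
}

# Explicit per-fold LOOCV: refit with the named R functions directly.
oracle_loocv <- function(x, labels, clf_name, knn_k = 1) {
  n <- nrow(x)
  correct <- 0
  for (i in seq_len(n)) {
    tr <- x[-i, , drop = FALSE]
    te <- x[i, , drop = FALSE]
    ytr <- factor(labels[-i])
    pred <- switch(clf_name,
      svm = {
        fit <- e1071::svm(tr, ytr, kernel = "radial", cost = 1,
                          gamma = 1 / ncol(tr))
        as.character(predict(fit, te))
      },
      tree = {
        df <- data.frame(tr)
        df$y <- ytr
        fit <- rpart::rpart(y ~ ., data = df, method = "class")
        as.character(predict(fit, data.frame(te), type = "class"))
      },
      knn = as.character(class::knn(tr, te, ytr, k = knn_k)),
      nbayes = {
        fit <- e1071::naiveBayes(data.frame(tr), ytr)
        as.character(predict(fit, data.frame(te)))
      })
    if (as.integer(pred) == labels[i]) correct <- correct + 1
  }
  correct / n
}

# Exhaustive ReliefF: explicit neighbor enumeration, per-feature updates.
oracle_relieff <- function(x, labels, k_neighbors) {
  n <- nrow(x)
  p <- ncol(x)
  rng <- numeric(p)
  for (f in seq_len(p)) rng[f] <- max(x[, f]) - min(x[, f])
  rng[rng == 0] <- 1
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) {
      s <- 0
      for (f in seq_len(p)) s <- s + abs(x[i, f] - x[j, f]) / rng[f]
      d[j] <- s
    }
    same <- setdiff(which(labels == labels[i]), i)
    other <- which(labels != labels[i])
    kh <- min(k_neighbors, length(same))
    km <- min(k_neighbors, length(other))
    hits <- same[order(d[same], same)][seq_len(kh)]
    misses <- other[order(d[other], other)][seq_len(km)]
    for (f in seq_len(p)) {
      for (h in hits) w[f] <- w[f] - abs(x[i, f] - x[h, f]) / rng[f] / (kh * n)
      for (ms in misses) w[f] <- w[f] + abs(x[i, f] - x[ms, f]) / rng[f] / (km * n)
    }
  }
  w
}

# A discretized_feature realizing a given bin x class count table, plus the
# matching label vector.
table_to_feature <- function(tab) {
  bins <- integer(0)
  labels <- integer(0)
  for (b in seq_len(nrow(tab))) {
    for (cl in seq_len(ncol(tab))) {
      bins <- c(bins, rep(b, tab[b, cl]))
      labels <- c(labels, rep(cl - 1L, tab[b, cl]))
    }
  }
  list(f = structure(list(bins = bins, B = nrow(tab), cuts = NULL),
                     class = "discretized_feature"),
       labels = labels)
}

# Small planted cohort + combined matrix, for recovery-style tests.
planted_combined <- function(d = 100, planted_tumor = 8, planted_adjacent = 5,
                             effect = 2, seed = 1, n_pos = 28, n_neg = 22,
                             block_rho = 0.3) {
  coh <- generate_cohort(synthetic_spec(
    n_pos = n_pos, n_neg = n_neg, d = d, planted_tumor = planted_tumor,
    planted_adjacent = planted_adjacent, effect = effect,
    block_rho = block_rho, seed = seed))
  list(cohort = coh,
       combined = combine_tissues(coh$tumor, coh$adjacent, coh$annotation))
}
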