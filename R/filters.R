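# Seven classical filter rankers used as comparators for the Monte-Carlo
# ranking: chi-squared, correlation, gain ratio, information gain, OneR,
# ReliefF and symmetrical uncertainty. The entropy- and chi-squared-based
# scorers operate on a supervised MDL discretization of each feature.

# Internal: Shannon entropy in bits of a count vector.
entropy_counts <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(0)
  p <- cnt[cnt > 0] / n
  -sum(p * log2(p))
}

#' Supervised discretization of a numeric feature
#'
#' Recursive binary splitting with the Fayyad-Irani minimum description
#' length (MDL) stopping rule: a cut maximizing the class information gain
#' is accepted iff
#' `gain > (log2(n - 1) + log2(3^k - 2) - k*H(S) + k1*H(S1) + k2*H(S2)) / n`,
#' where `k`, `k1`, `k2` count the classes present in the node and its two
#' halves. A feature with no accepted cut (including a constant feature)
#' yields a single bin.
#'
#' @param x numeric vector (finite).
#' @param labels class vector of the same length.
#' @param method discretization method; only `"mdl"` is implemented.
#' @return an object of class `discretized_feature`: list with `bins`
#'   (1-based bin index per sample, ordered by value), `B` (bin count) and
#'   `cuts` (accepted cut points, ascending).
#' @export
discretize <- function(x, labels, method = "mdl") {
  stopifnot(all(is.finite(x)), length(x) == length(labels))
  method <- match.arg(method, "mdl")
  cuts <- sort(mdl_cuts(x, labels))
  bins <- findInterval(x, cuts) + 1L
  structure(list(bins = bins, B = length(cuts) + 1L, cuts = cuts),
            class = "discretized_feature")
}

# Internal: recursive Fayyad-Irani cut search. Returns accepted cut points.
mdl_cuts <- function(x, y) {
  n <- length(x)
  if (n < 2) return(numeric(0))
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  classes <- unique(ys)
  if (length(classes) < 2) return(numeric(0))
  yi <- match(ys, classes)
  k <- length(classes)
  cnt <- tabulate(yi, k)
  h_s <- entropy_counts(cnt)

  # candidate cuts between distinct adjacent values
  cum <- vapply(seq_len(k), function(c) cumsum(yi == c), numeric(n))
  cand <- which(xs[-n] < xs[-1])
  if (length(cand) == 0) return(numeric(0))

  best_gain <- -Inf
  best_i <- NA_integer_
  best_stats <- NULL
  for (i in cand) {
    lc <- cum[i, ]
    rc <- cnt - lc
    h1 <- entropy_counts(lc)
    h2 <- entropy_counts(rc)
    gain <- h_s - (i * h1 + (n - i) * h2) / n
    if (gain > best_gain) {
      best_gain <- gain
      best_i <- i
      best_stats <- list(h1 = h1, h2 = h2,
                         k1 = sum(lc > 0), k2 = sum(rc > 0))
    }
  }
  # MDL acceptance criterion
  delta <- log2(3^k - 2) -
    (k * h_s - best_stats$k1 * best_stats$h1 - best_stats$k2 * best_stats$h2)
  threshold <- (log2(n - 1) + delta) / n
  if (best_gain <= threshold) return(numeric(0))
  cut <- (xs[best_i] + xs[best_i + 1]) / 2
  left <- ord[seq_len(best_i)]
  right <- ord[(best_i + 1):n]
  c(mdl_cuts(x[left], y[left]), cut, mdl_cuts(x[right], y[right]))
}

# Internal: bin x class contingency table of a discretized feature.
bin_class_table <- function(f, labels) {
  table(factor(f$bins, levels = seq_len(f$B)), factor(labels))
}

#' Entropy- and chi-squared-based feature scores
#'
#' All operate on the bin-by-class contingency table of a discretized
#' feature, with entropies in bits: information gain `H(C) - H(C|X)`,
#' gain ratio `IG / H(X)` (0 when `H(X) = 0`), symmetrical uncertainty
#' `2 IG / (H(C) + H(X))` (0 when the denominator is 0), and the Pearson
#' chi-squared statistic (cells with zero expectation skipped).
#'
#' @param f a [discretize()]d feature.
#' @param labels class vector.
#' @return a single non-negative score.
#' @export
score_infogain <- function(f, labels) {
  tab <- bin_class_table(f, labels)
  n <- sum(tab)
  h_c <- entropy_counts(colSums(tab))
  h_c_given_x <- sum(vapply(seq_len(nrow(tab)), function(b) {
    nb <- sum(tab[b, ])
    if (nb == 0) 0 else nb / n * entropy_counts(tab[b, ])
  }, numeric(1)))
  max(0, h_c - h_c_given_x)
}

#' @rdname score_infogain
#' @export
score_gainratio <- function(f, labels) {
  h_x <- entropy_counts(rowSums(bin_class_table(f, labels)))
  if (h_x == 0) return(0)
  score_infogain(f, labels) / h_x
}

#' @rdname score_infogain
#' @export
score_symuncert <- function(f, labels) {
  tab <- bin_class_table(f, labels)
  h_x <- entropy_counts(rowSums(tab))
  h_c <- entropy_counts(colSums(tab))
  if (h_x + h_c == 0) return(0)
  2 * score_infogain(f, labels) / (h_x + h_c)
}

#' @rdname score_infogain
#' @export
score_chi2 <- function(f, labels) {
  tab <- bin_class_table(f, labels)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  keep <- expected > 0
  sum((tab[keep] - expected[keep])^2 / expected[keep])
}

#' Absolute Pearson correlation with the class
#'
#' `|r|` between the raw feature values and the 0/1 class coding; 0 for a
#' constant feature.
#'
#' @param x numeric feature vector.
#' @param labels 0/1 class vector.
#' @return score in `[0, 1]`.
#' @export
score_correlation <- function(x, labels) {
  if (stats::sd(x) == 0 || stats::sd(labels) == 0) return(0)
  abs(cor(x, as.numeric(labels)))
}

#' OneR single-rule accuracy score
#'
#' Builds a one-feature rule: adjacent bins of the discretized feature are
#' merged left to right until every bucket holds at least `min_bucket`
#' samples (a trailing undersized bucket is merged into its predecessor);
#' each bucket predicts its majority class. The score is the rule's
#' training accuracy. A single bucket scores the majority class prior.
#'
#' @param f a [discretize()]d feature.
#' @param labels class vector.
#' @param min_bucket minimum samples per bucket (default 6).
#' @return accuracy in `[0, 1]`.
#' @export
score_oner <- function(f, labels, min_bucket = 6) {
  tab <- bin_class_table(f, labels)
  sizes <- rowSums(tab)
  bucket <- integer(nrow(tab))
  b <- 1L
  acc_n <- 0
  for (i in seq_len(nrow(tab))) {
    bucket[i] <- b
    acc_n <- acc_n + sizes[i]
    if (acc_n >= min_bucket && i < nrow(tab)) {
      b <- b + 1L
      acc_n <- 0
    }
  }
  if (acc_n > 0 && acc_n < min_bucket && b > 1L)
    bucket[bucket == b] <- b - 1L # trailing undersized bucket
  correct <- 0
  for (bb in unique(bucket)) {
    cls_counts <- colSums(tab[bucket == bb, , drop = FALSE])
    correct <- correct + max(cls_counts)
  }
  correct / sum(tab)
}

#' ReliefF feature weights
#'
#' Standard ReliefF with every sample used as an anchor. For each anchor the
#' `k_neighbors` nearest same-class samples (hits) and nearest other-class
#' samples (misses) are found under Manhattan distance on range-normalized
#' features; a feature's weight decreases with its mean hit difference and
#' increases with its mean miss difference. Weights lie in `[-1, 1]`. A
#' class smaller than `k_neighbors + 1` has its neighbor count reduced (with
#' a message).
#'
#' @param x numeric matrix, samples in rows.
#' @param labels class vector.
#' @param k_neighbors neighbors per class (default 10).
#' @return named numeric vector of per-feature weights.
#' @export
score_relieff <- function(x, labels, k_neighbors = 10) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  n <- nrow(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1 # constant features contribute zero diffs anyway
  xn <- sweep(x, 2, rng, "/")
  dmat <- as.matrix(stats::dist(xn, method = "manhattan"))
  cls_sizes <- table(labels)
  if (any(cls_sizes < k_neighbors + 1))
    message("ReliefF: class smaller than k_neighbors + 1; k reduced for it")
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    same <- same[same != i]
    other <- which(labels != labels[i])
    kh <- min(k_neighbors, length(same))
    km <- min(k_neighbors, length(other))
    hits <- same[order(dmat[i, same], same)][seq_len(kh)]
    misses <- other[order(dmat[i, other], other)][seq_len(km)]
    diff_hit <- abs(sweep(xn[hits, , drop = FALSE], 2, xn[i, ]))
    diff_miss <- abs(sweep(xn[misses, , drop = FALSE], 2, xn[i, ]))
    w <- w + colMeans(diff_miss) / n - colMeans(diff_hit) / n
  }
  names(w) <- colnames(x)
  w
}

#' Rank all features with the seven comparator methods
#'
#' Runs chi-squared, correlation, gain ratio, information gain, OneR,
#' ReliefF and symmetrical uncertainty over every feature of the combined
#' matrix and returns one full `feature_ranking` per method, all sharing the
#' Monte-Carlo tie-break (score descending, then feature ID).
#'
#' @param data a `combined_matrix`.
#' @param k_neighbors ReliefF neighbor count.
#' @param min_bucket OneR minimum bucket size.
#' @return named list of `feature_ranking` objects with elements
#'   `chisquared`, `correlation`, `gainratio`, `infogain`, `oner`,
#'   `relieff`, `symmetricaluncert`.
#' @export
rank_all <- function(data, k_neighbors = 10, min_bucket = 6) {
  stopifnot(inherits(data, "combined_matrix"))
  x <- data$x
  labels <- data$labels
  p <- ncol(x)
  ids <- colnames(x)
  chi2 <- ig <- gr <- su <- oner <- corr <- numeric(p)
  for (j in seq_len(p)) {
    f <- discretize(x[, j], labels)
    chi2[j] <- score_chi2(f, labels)
    ig[j] <- score_infogain(f, labels)
    gr[j] <- score_gainratio(f, labels)
    su[j] <- score_symuncert(f, labels)
    oner[j] <- score_oner(f, labels, min_bucket)
    corr[j] <- score_correlation(x[, j], labels)
  }
  rel <- score_relieff(x, labels, k_neighbors)
  lapply(list(chisquared = setNames(chi2, ids),
              correlation = setNames(corr, ids),
              gainratio = setNames(gr, ids),
              infogain = setNames(ig, ids),
              oner = setNames(oner, ids),
              relieff = setNames(as.numeric(rel), ids),
              symmetricaluncert = setNames(su, ids)),
         function(s) feature_ranking(ids, s))
}
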