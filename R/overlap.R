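# Cross-method rank comparison and pairwise hypergeometric list-overlap
# enrichment (the two-list case of the exact multi-set intersection test).

#' Where do the key features rank under other methods?
#'
#' For each feature of the Monte-Carlo key set, looks up its rank in every
#' comparator ranking and records the best (smallest) rank across methods.
#'
#' @param key a `feature_ranking` restricted to the key features (e.g. the
#'   top `k_final` rows of the Monte-Carlo ranking).
#' @param others named list of full `feature_ranking` objects over the same
#'   feature universe.
#' @return data frame with columns `feature_id`, `mc_rank`, `best_method`,
#'   `best_rank`, and one rank column per comparator method.
#' @export
compare_ranks <- function(key, others) {
  stopifnot(is.list(others), length(others) >= 1, !is.null(names(others)))
  out <- data.frame(feature_id = key$feature_id, mc_rank = key$rank,
                    stringsAsFactors = FALSE)
  ranks <- sapply(others, function(r) {
    idx <- match(key$feature_id, r$feature_id)
    if (anyNA(idx))
      stop("feature missing from a comparator ranking: ",
           key$feature_id[is.na(idx)][1])
    r$rank[idx]
  })
  ranks <- matrix(ranks, nrow = nrow(key),
                  dimnames = list(NULL, names(others)))
  best_j <- apply(ranks, 1, which.min)
  out$best_method <- colnames(ranks)[best_j]
  out$best_rank <- ranks[cbind(seq_len(nrow(ranks)), best_j)]
  cbind(out, as.data.frame(ranks))
}

#' Upper-tail hypergeometric probability, vectorized over the overlap
#'
#' `P(overlap >= x)` when lists of sizes `a` and `b` are drawn uniformly at
#' random from a universe of `N` items. Computed in log space from binomial
#' coefficients (`lchoose`) with a max-shifted sum of the tail terms.
#'
#' @param N universe size.
#' @param a,b list sizes (`a, b <= N`).
#' @param x overlap count(s); may be a vector.
#' @return vector of tail probabilities in `[0, 1]`; `x = 0` gives exactly 1.
#' @export
hypergeom_tail <- function(N, a, b, x) {
  if (a > N || b > N) stop("list sizes must not exceed the universe")
  if (any(x < 0) || any(x > min(a, b)))
    stop("overlap must lie in [0, min(a, b)]")
  m <- min(a, b)
  lo <- max(0L, a + b - N)
  j <- lo:m
  lt <- lchoose(a, j) + lchoose(N - a, b - j) - lchoose(N, b)
  shift <- max(lt)
  u <- exp(lt - shift)
  tail <- rev(cumsum(rev(u))) # tail[i] = sum_{j' >= j[i]}
  p <- numeric(length(x))
  below <- x < lo # tail from below the support is the whole mass
  p[below] <- 1
  p[!below] <- pmin(1, exp(shift) * tail[x[!below] - lo + 1])
  p[x == 0] <- 1
  p
}

#' Pairwise list-overlap enrichment
#'
#' Exact hypergeometric test for the overlap of two gene lists against a
#' common universe, as produced by the pairwise case of exact multi-set
#' intersection testing: the upper-tail probability of seeing at least `x`
#' shared items, and the fold enrichment `x / (a * b / N)` relative to the
#' expected overlap.
#'
#' @param N universe size (e.g. the combined feature count).
#' @param a,b sizes of the two lists.
#' @param x observed overlap.
#' @return an object of class `intersection_result`: list with `N`, `a`,
#'   `b`, `x`, `expected`, `fold`, `p`.
#' @examples
#' hypergeom_overlap(N = 10, a = 5, b = 4, x = 4)$p  # 5/210
#' @export
hypergeom_overlap <- function(N, a, b, x) {
  if (length(N) != 1 || length(a) != 1 || length(b) != 1 || length(x) != 1)
    stop("N, a, b, x must be scalars")
  if (N < 1 || a < 0 || b < 0 || x < 0)
    stop("counts must be non-negative (N >= 1)")
  if (a > N || b > N) stop("list sizes a, b must not exceed N")
  if (x > min(a, b)) stop("overlap x must not exceed min(a, b)")
  expected <- a * b / N
  structure(list(N = N, a = a, b = b, x = x, expected = expected,
                 fold = if (expected > 0) x / expected else NA_real_,
                 p = hypergeom_tail(N, a, b, x)),
            class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf(
    "Overlap %d of lists %d x %d in universe %d: fold %.2f, p = %.3g\n",
    x$x, x$a, x$b, x$N, x$fold, x$p))
  invisible(x)
}

#' Enrichment of the key set against each comparator's top list
#'
#' Takes the top-`k` lists of the Monte-Carlo ranking and of each comparator
#' ranking and computes the pairwise hypergeometric overlap test against the
#' full feature universe.
#'
#' @param key_ranking the Monte-Carlo `feature_ranking`.
#' @param others named list of comparator `feature_ranking` objects.
#' @param k list size to compare (top-`k` of every ranking).
#' @param N universe size; defaults to the ranking length.
#' @return data frame with one row per method: `method`, `overlap`, `p`,
#'   `fold`.
#' @export
enrichment_table <- function(key_ranking, others, k, N = nrow(key_ranking)) {
  key_top <- key_ranking$feature_id[seq_len(k)]
  rows <- lapply(names(others), function(mth) {
    other_top <- others[[mth]]$feature_id[seq_len(k)]
    x <- length(intersect(key_top, other_top))
    res <- hypergeom_overlap(N, k, k, x)
    data.frame(method = mth, overlap = x, p = res$p, fold = res$fold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
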