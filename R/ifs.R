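#' Classifier specification for incremental feature selection
#'
#' The four classifiers mirror the R functions named by common practice for
#' this design: `svm` (e1071, RBF kernel, cost 1, gamma 1/p, features
#' standardized per training fold), `tree` (rpart with default
#' hyperparameters), `knn` (class::knn with k = 1), and `nbayes`
#' (e1071::naiveBayes, Gaussian class-conditionals). A `dummy`
#' majority-class classifier is provided for calibration: its LOOCV accuracy
#' equals the majority class prior exactly.
#'
#' @param name one of `"svm"`, `"tree"`, `"knn"`, `"nbayes"`, `"dummy"`.
#' @param cost SVM cost parameter (> 0).
#' @param gamma SVM RBF width; `NULL` means `1 / ncol(x)`.
#' @param kernel SVM kernel name.
#' @param k neighbor count for `knn` (>= 1).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("svm", "tree", "knn", "nbayes", "dummy"),
                            cost = 1, gamma = NULL, kernel = "radial", k = 1) {
  name <- match.arg(name)
  if (cost <= 0) stop("cost must be positive")
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be positive")
  if (k < 1) stop("k must be >= 1")
  structure(list(name = name, cost = cost, gamma = gamma, kernel = kernel,
                 k = as.integer(k)),
            class = "classifier_spec")
}

# Internal: fit on (train_x, train_y), predict test_x. Labels are 0/1
# integers. A training fold that lost a class predicts the remaining class
# (flagged via message).
predict_heldout <- function(train_x, train_y, test_x, clf) {
  lv <- sort(unique(train_y))
  if (length(lv) < 2) {
    message("training fold contains a single class; predicting it")
    return(rep(lv, nrow(test_x)))
  }
  yf <- factor(train_y, levels = lv)
  if (clf$name == "svm") {
    ctr <- colMeans(train_x)
    scl <- apply(train_x, 2, stats::sd)
    scl[scl == 0] <- 1
    tr <- scale(train_x, center = ctr, scale = scl)
    te <- scale(test_x, center = ctr, scale = scl)
    g <- if (is.null(clf$gamma)) 1 / ncol(train_x) else clf$gamma
    fit <- e1071::svm(tr, yf, kernel = clf$kernel, cost = clf$cost,
                      gamma = g, scale = FALSE)
    as.integer(as.character(predict(fit, te)))
  } else if (clf$name == "tree") {
    df <- as.data.frame(train_x)
    names(df) <- paste0("f", seq_len(ncol(train_x)))
    df$.y <- yf
    fit <- rpart::rpart(.y ~ ., data = df, method = "class")
    nd <- as.data.frame(test_x)
    names(nd) <- paste0("f", seq_len(ncol(test_x)))
    as.integer(as.character(predict(fit, nd, type = "class")))
  } else if (clf$name == "knn") {
    as.integer(as.character(
      class::knn(train_x, test_x, yf, k = clf$k)))
  } else if (clf$name == "nbayes") {
    df <- as.data.frame(train_x)
    names(df) <- paste0("f", seq_len(ncol(train_x)))
    fit <- e1071::naiveBayes(df, yf)
    nd <- as.data.frame(test_x)
    names(nd) <- paste0("f", seq_len(ncol(test_x)))
    as.integer(as.character(predict(fit, nd)))
  } else { # dummy: majority class, ties to the lower label
    tab <- table(train_y)
    rep(as.integer(names(tab)[which.max(tab)]), nrow(test_x))
  }
}

#' Leave-one-out cross-validated accuracy
#'
#' For each sample, the classifier is fitted on the remaining `n - 1`
#' samples and used to predict the held-out one; accuracy is the fraction of
#' correct predictions. Any per-fold standardization (SVM) is fitted on the
#' training samples only. Runs under a private RNG stream so results are
#' reproducible and the caller's RNG state is untouched.
#'
#' @param x numeric matrix, samples in rows.
#' @param labels 0/1 integer vector.
#' @param clf a [classifier_spec()].
#' @return accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(x, labels, clf = classifier_spec("svm")) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  n <- nrow(x)
  if (n < 3) stop("LOOCV needs at least 3 samples")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  with_private_seed(104729L, {
    pred <- integer(n)
    for (i in seq_len(n)) {
      pred[i] <- predict_heldout(x[-i, , drop = FALSE], labels[-i],
                                 x[i, , drop = FALSE], clf)
    }
    mean(pred == labels)
  })
}

#' Incremental feature selection curve
#'
#' Evaluates the nested top-`k` feature sets of a ranking for
#' `k = 1, ..., K`: point `k` is the LOOCV accuracy of the classifier using
#' exactly the `k` top-ranked features.
#'
#' @param data a `combined_matrix`.
#' @param ranking a `feature_ranking` over the features of `data`.
#' @param clf a [classifier_spec()].
#' @param K largest feature-set size scanned (default 500, capped below by
#'   the ranking length at validation).
#' @param verbose print progress every 25 points.
#' @return an `ifs_curve`: data frame with columns `k`, `accuracy` and
#'   attribute `classifier`.
#' @export
ifs_scan <- function(data, ranking, clf = classifier_spec("svm"), K = 500,
                     verbose = FALSE) {
  stopifnot(inherits(data, "combined_matrix"))
  if (K > nrow(ranking))
    stop(sprintf("K (%d) exceeds the number of ranked features (%d)",
                 K, nrow(ranking)))
  feats <- match(ranking$feature_id[seq_len(K)], colnames(data$x))
  if (anyNA(feats)) stop("ranking refers to features absent from the data")
  acc <- numeric(K)
  for (k in seq_len(K)) {
    acc[k] <- loocv_accuracy(data$x[, feats[seq_len(k)], drop = FALSE],
                             data$labels, clf)
    if (verbose && k %% 25 == 0)
      message(sprintf("IFS: k = %d, accuracy = %.3f", k, acc[k]))
  }
  structure(data.frame(k = seq_len(K), accuracy = acc),
            classifier = clf$name,
            class = c("ifs_curve", "data.frame"))
}

#' Select the final feature-set size from an IFS curve
#'
#' `k_peak` is the smallest set size attaining the maximum accuracy;
#' `k_final` is the smallest size whose accuracy is within `delta` of that
#' maximum — the formalization of trading a little accuracy for a much
#' smaller model (e.g. preferring 26 features at 0.94 over 175 at 0.96 when
#' `delta = 0.02`).
#'
#' @param curve an `ifs_curve`.
#' @param delta accepted accuracy sacrifice (>= 0), default 0.02.
#' @return list with `k_peak`, `k_final`, `acc_peak`, `acc_final`.
#' @export
select_key_set <- function(curve, delta = 0.02) {
  if (nrow(curve) == 0) stop("curve is empty")
  if (delta < 0) stop("delta must be >= 0")
  acc_peak <- max(curve$accuracy)
  k_peak <- curve$k[which(curve$accuracy == acc_peak)[1]]
  ok <- curve$accuracy >= acc_peak - delta - 1e-12
  k_final <- curve$k[which(ok)[1]]
  list(k_peak = k_peak, k_final = k_final, acc_peak = acc_peak,
       acc_final = curve$accuracy[which(ok)[1]])
}

#' Tabulate the selected key features
#'
#' @param data a `combined_matrix` (used only to validate feature IDs).
#' @param ranking a `feature_ranking`.
#' @param k_final number of top features to report.
#' @return data frame with columns `rank`, `feature_id`, `tissue`, `ri`;
#'   attribute `tissue_counts` holds the per-tissue feature counts.
#' @export
summarize_key_features <- function(data, ranking, k_final) {
  stopifnot(k_final >= 1, k_final <= nrow(ranking))
  top <- ranking[seq_len(k_final), , drop = FALSE]
  if (!all(top$feature_id %in% colnames(data$x)))
    stop("ranking refers to features absent from the data")
  out <- data.frame(rank = top$rank, feature_id = top$feature_id,
                    tissue = feature_tissue(top$feature_id), ri = top$ri,
                    stringsAsFactors = FALSE)
  counts <- c(tumor = sum(out$tissue == "tumor"),
              adjacent = sum(out$tissue == "adjacent"))
  attr(out, "tissue_counts") <- counts
  out
}
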