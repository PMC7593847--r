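test_that("MDL discretization accepts informative cuts and rejects null ones", {
  # Perfect separation of 4 + 4 samples: gain = 1 bit. The MDL hurdle is
  # (log2(7) + log2(3^2 - 2) - 2 * 1 + 1 * 0 + 1 * 0) / 8 = (2 * log2(7) - 2) / 8
  # = 0.4518 < 1, so the cut at the class boundary is accepted.
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  gain <- 1
  hurdle <- (log2(7) + log2(3^2 - 2) - 2 * 1) / 8
  expect_gt(gain, hurdle)
  f <- discretize(x, y)
  expect_gte(f$B, 2)
  expect_equal(f$cuts[1], 4.5)
  # the two sides are class-pure
  expect_true(all(tapply(y, f$bins, function(v) length(unique(v))) == 1))

  # alternating labels: every cut has zero gain, so no cut passes MDL
  f2 <- discretize(x, c(0, 1, 0, 1, 0, 1, 0, 1))
  expect_equal(f2$B, 1L)

  # constant feature: single bin
  f3 <- discretize(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(f3$B, 1L)
})

test_that("entropy and chi-squared scorers match closed-form arithmetic", {
  # diagonal 2x2 table [[10, 0], [0, 10]]
  tf <- table_to_feature(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(score_chi2(tf$f, tf$labels), 20)
  expect_equal(score_infogain(tf$f, tf$labels), 1)
  expect_equal(score_symuncert(tf$f, tf$labels), 1)
  expect_equal(score_gainratio(tf$f, tf$labels), 1)

  # identical class proportions per bin: independence, all scores zero
  tf0 <- table_to_feature(matrix(c(6, 3, 4, 2), 2, byrow = TRUE))
  expect_equal(score_infogain(tf0$f, tf0$labels), 0)
  expect_equal(score_chi2(tf0$f, tf0$labels), 0, tolerance = 1e-12)
})

test_that("scorers are invariant to sample order and properly bounded", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 40
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    f <- discretize(x, y)
    perm <- sample(n)
    fp <- discretize(x[perm], y[perm])
    expect_equal(score_infogain(f, y), score_infogain(fp, y[perm]))
    expect_equal(score_oner(f, y), score_oner(fp, y[perm]))
    su <- score_symuncert(f, y)
    gr <- score_gainratio(f, y)
    expect_gte(su, 0); expect_lte(su, 1)
    expect_gte(gr, 0); expect_lte(gr, 1)
    expect_gte(score_infogain(f, y), 0)
  }
})

test_that("correlation score is absolute and vanishes for noise", {
  y <- rep(c(0, 1), each = 25)
  expect_equal(score_correlation(as.numeric(y), y), 1.0)
  set.seed(43)
  r <- replicate(30, score_correlation(rnorm(50), y))
  expect_true(mean(r < 3 / sqrt(50)) > 0.9)
  x <- rnorm(50)
  expect_equal(score_correlation(-x, y), score_correlation(x, y))
  expect_equal(score_correlation(rep(1, 50), y), 0)
})

test_that("OneR scores the merged-bin majority rule", {
  # perfectly predictive bins
  tf <- table_to_feature(matrix(c(8, 0, 0, 8), 2, byrow = TRUE))
  expect_equal(score_oner(tf$f, tf$labels), 1.0)
  # a single bin predicts the majority class
  tf1 <- table_to_feature(matrix(c(11, 7), 1))
  expect_equal(score_oner(tf1$f, tf1$labels), 11 / 18)
  # 3-bin worked fixture, min_bucket 6:
  #   bin1 (5, 1) closes a bucket (size 6, majority class 0: 5 correct);
  #   bins 2+3 merge to (3, 7) (majority class 1: 7 correct) -> 12/16
  tf3 <- table_to_feature(matrix(c(5, 1, 2, 2, 1, 5), 3, byrow = TRUE))
  expect_equal(score_oner(tf3$f, tf3$labels, min_bucket = 6), 12 / 16)
})

test_that("ReliefF weights match exhaustive enumeration and basic symmetries", {
  # 1-D two-cluster fixture, 6 points
  x <- matrix(c(0, 0.1, 0.2, 1.0, 1.1, 1.2), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- rep(c(0L, 1L), each = 3)
  w <- score_relieff(x, y, k_neighbors = 2)
  expect_equal(unname(w), oracle_relieff(x, y, 2), tolerance = 1e-12)
  expect_gt(w["f1"], 0)

  set.seed(47)
  x2 <- matrix(rnorm(16 * 3), 16, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y2 <- rep(c(0L, 1L), each = 8)
  # constant feature has weight 0
  x2[, 2] <- 4
  w2 <- score_relieff(x2, y2, k_neighbors = 3)
  expect_equal(unname(w2["f2"]), 0)
  # duplicating a column leaves both copies with equal weight
  x3 <- cbind(x2, f4 = x2[, 1])
  w3 <- score_relieff(x3, y2, k_neighbors = 3)
  expect_equal(unname(w3["f1"]), unname(w3["f4"]))
})

test_that("all seven rankers recover a strong planted feature near the top", {
  pc <- planted_combined(d = 150, planted_tumor = 1, planted_adjacent = 0,
                         effect = 3, seed = 29, block_rho = 0)
  rankings <- rank_all(pc$combined)
  expect_named(rankings, c("chisquared", "correlation", "gainratio",
                           "infogain", "oner", "relieff",
                           "symmetricaluncert"))
  top5pct <- ceiling(0.05 * ncol(pc$combined$x))
  for (m in names(rankings)) {
    rk <- rankings[[m]]
    expect_lte(rk$rank[match(pc$cohort$truth, rk$feature_id)], top5pct)
    expect_equal(nrow(rk), ncol(pc$combined$x))
  }
  # determinism
  again <- rank_all(pc$combined)
  expect_identical(rankings, again)
})

test_that("constant-only data scores zero everywhere but stays ranked", {
  x <- matrix(3, 12, 4, dimnames = list(sprintf("S%d", 1:12),
                                        c(paste0("tumor:p", 1:2),
                                          paste0("adjacent:p", 1:2))))
  comb <- structure(list(x = x, labels = setNames(rep(c(0L, 1L), 6),
                                                  rownames(x))),
                    class = "combined_matrix")
  rankings <- rank_all(comb)
  for (m in setdiff(names(rankings), "oner")) {
    expect_true(all(rankings[[m]]$ri == 0), info = m)
  }
  # OneR degenerates to the class prior for every feature
  expect_true(all(rankings$oner$ri == 0.5))
})
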