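test_that("weighted accuracy is the mean per-class recall", {
  expect_equal(weighted_accuracy(matrix(c(5, 0, 0, 3), 2)), 1.0)
  expect_equal(weighted_accuracy(matrix(c(3, 0, 1, 2), 2)), 0.875)
  # always predicting one class with both classes present
  expect_equal(weighted_accuracy(matrix(c(4, 2, 0, 0), 2)), 0.5)
  # a class absent from the held-out split is dropped from the average
  expect_equal(weighted_accuracy(matrix(c(3, 0, 1, 0), 2)), 0.75)
  expect_error(weighted_accuracy(matrix(0, 2, 2)), "all zero")
})

test_that("a perfectly separable feature yields one root split of IG one bit", {
  x <- matrix(c(1, 2, 3, 4, 11, 12, 13, 14), ncol = 1,
              dimnames = list(NULL, "g"))
  labels <- c(0, 0, 0, 0, 1, 1, 1, 1)
  set.seed(1)
  tr <- grow_tree(x, labels, mcfs_config(train_fraction = 0.66))
  expect_length(tr$nodes$feature_id, 1)
  expect_equal(tr$nodes$feature_id, "g")
  expect_equal(tr$nodes$ig, 1.0)          # balanced training labels: H = 1 bit
  expect_equal(tr$nodes$n_node, tr$n_tree) # root covers all training samples
  expect_equal(tr$wacc, 1.0)
})

test_that("degenerate inputs give leaf-only trees", {
  set.seed(2)
  # single-class labels: pure input, no split, perfect held-out accuracy
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  tr <- grow_tree(x, rep(1, 6))
  expect_length(tr$nodes$feature_id, 0)
  expect_equal(tr$wacc, 1.0)
  # constant features: no admissible split
  xc <- matrix(5, 8, 2, dimnames = list(NULL, c("a", "b")))
  tr2 <- grow_tree(xc, c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_length(tr2$nodes$feature_id, 0)
})

test_that("relative importance reproduces the hand-computed two-tree fixture", {
  tree_a <- structure(list(
    wacc = 1.0,
    nodes = list(feature_id = "g", ig = 0.5, n_node = 6L),
    n_tree = 6L), class = "tree_record")
  tree_b <- structure(list(
    wacc = 0.75,
    nodes = list(feature_id = "g", ig = 0.2, n_node = 2L),
    n_tree = 6L), class = "tree_record")
  rk <- relative_importance(list(tree_a, tree_b), mcfs_config(u = 1, v = 1))
  expect_equal(rk$ri[rk$feature_id == "g"], 0.55)

  # u = v = 0 collapses the weights: plain sum of information gains
  rk0 <- relative_importance(list(tree_a, tree_b), mcfs_config(u = 0, v = 0))
  expect_equal(rk0$ri[rk0$feature_id == "g"], 0.7)

  # a feature absent from every node scores zero and ranks by ID among ties
  rk2 <- relative_importance(list(tree_a, tree_b), mcfs_config(),
                             feature_ids = c("g", "h", "a"))
  expect_equal(rk2$ri[rk2$feature_id == "h"], 0)
  expect_equal(rk2$feature_id, c("g", "a", "h"))
  expect_equal(rk2$rank, 1:3)
})

test_that("relative importance is additive over trees and equivariant to relabeling", {
  set.seed(11)
  pool <- sprintf("f%02d", 1:15)
  cfg <- mcfs_config(u = 1.5, v = 0.7)
  for (rep in 1:10) {
    trees_a <- replicate(4, random_tree_record(pool), simplify = FALSE)
    trees_b <- replicate(3, random_tree_record(pool), simplify = FALSE)
    ri_a <- relative_importance(trees_a, cfg, pool)
    ri_b <- relative_importance(trees_b, cfg, pool)
    ri_ab <- relative_importance(c(trees_a, trees_b), cfg, pool)
    get <- function(r) setNames(r$ri, r$feature_id)[pool]
    expect_equal(get(ri_ab), get(ri_a) + get(ri_b), tolerance = 1e-12)

    # permuting feature names permutes RI identically
    perm <- sample(pool)
    names(perm) <- pool
    trees_p <- lapply(trees_a, function(tr) {
      tr$nodes$feature_id <- unname(perm[tr$nodes$feature_id])
      tr
    })
    ri_p <- relative_importance(trees_p, cfg, unname(perm))
    expect_equal(unname(get(ri_p)[unname(perm[pool])]),
                 unname(get(ri_a)[pool]), tolerance = 1e-12)
  }
})

test_that("run_mcfs is deterministic and ranks planted features above the median", {
  pc <- planted_combined(d = 100, planted_tumor = 8, planted_adjacent = 5,
                         effect = 2, seed = 21)
  cfg <- mcfs_config(s = 100, t = 3, seed = 77)
  rk1 <- run_mcfs(pc$combined, cfg)
  rk2 <- run_mcfs(pc$combined, cfg)
  expect_identical(rk1, rk2)
  n_feat <- ncol(pc$combined$x)
  ranks <- rk1$rank[match(pc$cohort$truth, rk1$feature_id)]
  expect_true(all(ranks <= n_feat / 2))
})

test_that("m larger than the feature count is a configuration error", {
  pc <- planted_combined(d = 10, seed = 3)
  expect_error(run_mcfs(pc$combined, mcfs_config(s = 2, m = 50)), "exceeds")
})

test_that("raising a planted effect does not lower its rank on average", {
  ranks <- sapply(1:20, function(seed) {
    sapply(c(1, 2.5), function(eff) {
      pc <- planted_combined(d = 25, planted_tumor = 1, planted_adjacent = 0,
                             effect = eff, seed = seed, n_pos = 14, n_neg = 11,
                             block_rho = 0)
      cfg <- mcfs_config(s = 40, t = 3, seed = seed)
      rk <- run_mcfs(pc$combined, cfg)
      rk$rank[match(pc$cohort$truth, rk$feature_id)]
    })
  })
  expect_lte(mean(ranks[2, ]), mean(ranks[1, ]))
})

test_that("ranking round trips through its TSV form", {
  pc <- planted_combined(d = 20, seed = 13)
  rk <- run_mcfs(pc$combined, mcfs_config(s = 10, t = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(rk, path)
  back <- read_ranking(path)
  expect_equal(back$feature_id, rk$feature_id)
  expect_equal(back$ri, rk$ri)
})
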