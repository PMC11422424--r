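test_that("Ward.D2 merges match hand computation on tiny instances", {
  # two points at distance 5: single merge at height 5
  D2 <- matrix(c(0, 5, 5, 0), 2, 2)
  h <- hclust_ward2(D2)
  expect_equal(h$height, 5)
  # equilateral triple at distance 1: first merge at height 1
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  h3 <- hclust_ward2(D3)
  expect_equal(h3$height[1], 1)
  expect_error(hclust_ward2(matrix(0, 1, 1)), "at least 2")
})

test_that("Ward.D2 tree equals a naive Lance-Williams agglomeration", {
  set.seed(88)
  for (trial in 1:20) {
    pts <- matrix(rnorm(8 * 3), 8, 3)
    D <- as.matrix(dist(pts))
    dimnames(D) <- NULL
    h <- hclust_ward2(D)
    ref <- naive_ward2(D)
    expect_equal(sort(h$height), sort(ref$heights), tolerance = 1e-10)
    for (k in c(2, 4, 6)) {
      mine <- canon_partition(cutree(h, k))
      theirs <- canon_partition(ref$partitions[[8 - k]])
      expect_equal(mine, theirs)
    }
  }
})

test_that("cutting the tree gives nested first-occurrence-labelled partitions", {
  D <- blob_distance(4, 4, seed = 2)
  tree <- hclust_ward2(D)
  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 8))
  expect_equal(sort(unique(cut_tree(tree, 8))), 1:8)   # singletons
  expect_error(cut_tree(tree, 0), "out of range")
  expect_error(cut_tree(tree, 9), "out of range")
  # nestedness: k-1 clusters only merge clusters of the k-solution
  for (k in 3:8) {
    fine <- cut_tree(tree, k)
    coarse <- cut_tree(tree, k - 1)
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
  # first participant always carries label 1
  expect_equal(unname(cut_tree(tree, 3)[1]), 1L)
})

test_that("both algorithms recover two well-separated blobs at k = 2", {
  D <- blob_distance(6, 10, within = 1, between = 25, seed = 3)
  truth <- rep(1:2, c(6, 10))
  hl <- cut_tree(hclust_ward2(D), 2)
  km <- kmeans_rows(D, 2, seed = 42)
  expect_equal(adjusted_rand_index(hl, truth), 1)
  expect_equal(adjusted_rand_index(km, truth), 1)
  expect_equal(canon_partition(hl), canon_partition(km))
})

test_that("k-means on distance rows is deterministic and handles edge cases", {
  D <- blob_distance(5, 5, seed = 4)
  expect_identical(kmeans_rows(D, 3, seed = 7), kmeans_rows(D, 3, seed = 7))
  expect_error(kmeans_rows(D, 11, seed = 1), "exceeds")
  # k = 1: single cluster, WCSS equals total row scatter
  one <- kmeans_rows(D, 1, seed = 1)
  expect_true(all(one == 1L))
  ctr <- colMeans(D)
  expect_equal(attr(one, "wcss"), sum(sweep(D, 2, ctr)^2))
  # identical rows: any split has zero scatter, labels deterministic
  Did <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  lab <- kmeans_rows(Did, 2, seed = 5)
  expect_identical(lab, kmeans_rows(Did, 2, seed = 5))
  expect_equal(attr(lab, "wcss"), 0)
  expect_equal(sort(unique(unname(lab))), 1:2)
})

test_that("best-of-n-init WCSS never worsens with more restarts", {
  set.seed(12)
  D <- as.matrix(dist(matrix(rnorm(30 * 4), 30, 4)))
  w5 <- attr(kmeans_rows(D, 4, n_init = 5, seed = 99), "wcss")
  w25 <- attr(kmeans_rows(D, 4, n_init = 25, seed = 99), "wcss")
  expect_lte(w25, w5)
})

test_that("relabelling is consistent under participant permutation", {
  D <- blob_distance(5, 7, seed = 6)
  perm <- sample(12)
  Dp <- D[perm, perm]
  a <- cut_tree(hclust_ward2(D), 2)
  b <- cut_tree(hclust_ward2(Dp), 2)
  expect_equal(adjusted_rand_index(a[rownames(Dp)], b), 1)
})

test_that("PAM on the dissimilarities agrees on well-separated blobs", {
  skip_if_not_installed("cluster")
  D <- blob_distance(6, 6, within = 1, between = 25, seed = 13)
  expect_equal(adjusted_rand_index(pam_rows(D, 2), rep(1:2, each = 6)), 1)
})
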