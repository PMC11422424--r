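#' Ward.D2 agglomerative clustering of a DTW distance matrix
#'
#' Agglomerative merging that minimizes within-cluster variance via the
#' Lance-Williams update on squared dissimilarities (`hclust` method
#' `"ward.D2"`).
#'
#' @param D Symmetric distance matrix (zero diagonal, finite entries).
#' @return An [stats::hclust] merge tree.
#' @export
hclust_ward2 <- function(D) {
  check_distance_matrix(D)
  if (nrow(D) < 2) stop("need at least 2 observations")
  hclust(as.dist(D), method = "ward.D2")
}

check_distance_matrix <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (!all(is.finite(D))) stop("distance matrix must be finite")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
  invisible(TRUE)
}

# relabel cluster labels so that label 1 is the cluster of the first
# participant, label 2 the next new cluster encountered, and so on
relabel_first_occurrence <- function(labels) {
  u <- unique(labels)
  out <- match(labels, u)
  names(out) <- names(labels)
  out
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last `k - 1` merges; labels are assigned in first-occurrence
#' order of the participants, making solutions comparable across runs.
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector of labels 1..k.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k out of range")
  relabel_first_occurrence(cutree(tree, k = k))
}

#' k-means on the rows of a distance matrix
#'
#' Each participant is represented by its row of the DTW distance matrix
#' (its distance profile to everyone) and partitioned by k-means with Lloyd
#' iterations from `n_init` seeded random initializations, keeping the best
#' within-cluster sum of squares. If fewer distinct profiles than `k` exist,
#' participants are spread deterministically over the labels (any such
#' partition has zero within-cluster scatter).
#'
#' @param D Symmetric distance matrix.
#' @param k Number of clusters, `k <= n`.
#' @param n_init Random restarts (default 50).
#' @param seed Integer seed.
#' @param iter_max Lloyd iteration cap (default 300).
#' @return Named integer labels 1..k with attribute `wcss` (best total
#'   within-cluster sum of squares).
#' @export
kmeans_rows <- function(D, k, n_init = 50L, seed, iter_max = 300L) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (k > n) stop("k exceeds number of observations")
  if (k == 1) {
    ctr <- colMeans(D)
    lab <- rep(1L, n)
    names(lab) <- rownames(D)
    attr(lab, "wcss") <- sum(sweep(D, 2, ctr)^2)
    return(lab)
  }
  set.seed(seed)
  dup <- duplicated(D)
  if (any(dup)) {
    # kmeans rejects coincident sampled centers; cluster the distinct
    # profiles and propagate their labels to the duplicates
    key <- do.call(paste, c(as.data.frame(D), sep = "\r"))
    if (n - sum(dup) < k) {
      lab <- relabel_first_occurrence(((seq_len(n) - 1L) %% k) + 1L)
      names(lab) <- rownames(D)
      attr(lab, "wcss") <- 0
      return(lab)
    }
    U <- D[!dup, , drop = FALSE]
    km <- suppressWarnings(kmeans(U, centers = k, nstart = n_init,
                                  iter.max = iter_max, algorithm = "Lloyd"))
    full <- km$cluster[match(key, key[!dup])]
    lab <- relabel_first_occurrence(full)
    names(lab) <- rownames(D)
    ctr <- km$centers[full, , drop = FALSE]
    attr(lab, "wcss") <- sum((D - ctr)^2)
    return(lab)
  }
  km <- suppressWarnings(kmeans(D, centers = k, nstart = n_init,
                                iter.max = iter_max, algorithm = "Lloyd"))
  lab <- relabel_first_occurrence(km$cluster)
  names(lab) <- rownames(D)
  attr(lab, "wcss") <- km$tot.withinss
  lab
}

#' Partitioning around medoids on a distance matrix
#'
#' Sensitivity alternative to [kmeans_rows()]: PAM applied to the
#' dissimilarities themselves (no row embedding). Requires the `cluster`
#' package.
#'
#' @inheritParams kmeans_rows
#' @return Named integer labels 1..k.
#' @export
pam_rows <- function(D, k, seed = NULL) {
  if (!requireNamespace("cluster", quietly = TRUE))
    stop("the 'cluster' package is required for PAM")
  check_distance_matrix(D)
  if (k > nrow(D)) stop("k exceeds number of observations")
  fit <- cluster::pam(as.dist(D), k = k, cluster.only = TRUE)
  lab <- relabel_first_occurrence(fit)
  names(lab) <- rownames(D)
  lab
}

#' Cluster a distance matrix with a named algorithm
#'
#' @param D Symmetric distance matrix.
#' @param algorithm `"hierarchical"` (Ward.D2 + cut), `"kmeans"` (distance
#'   profile rows) or `"pam"`.
#' @param k Number of clusters.
#' @param n_init,seed Passed to [kmeans_rows()].
#' @return Named integer labels 1..k.
#' @export
cluster_distance <- function(D, algorithm = c("hierarchical", "kmeans", "pam"),
                             k, n_init = 50L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         hierarchical = cut_tree(hclust_ward2(D), k),
         kmeans = kmeans_rows(D, k, n_init = n_init, seed = seed),
         pam = pam_rows(D, k, seed = seed))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same observations;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
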