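#' Jaccard index between two id sets
#'
#' @param a,b Vectors treated as sets.
#' @return `|a intersect b| / |a union b|` in `[0, 1]`; two empty sets give 0
#'   with a warning.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    warning("jaccard of two empty sets defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Clusterwise stability under repeated subsampling
#'
#' Reclusters random subsamples (drawn without replacement) of the
#' participants and scores, for every cluster of the full-data solution, how
#' well it is recovered: in each resample the cluster's retained members are
#' matched to the subsample cluster maximizing the Jaccard index, and the
#' matches are averaged over resamples. Values above 0.85 are conventionally
#' read as a highly stable cluster. Resamples in which a cluster loses all
#' members are skipped for that cluster; resamples smaller than `k` are
#' skipped entirely.
#'
#' @param D Symmetric distance matrix with participant ids as dimnames.
#' @param algorithm `"hierarchical"`, `"kmeans"` or `"pam"`.
#' @param k Number of clusters.
#' @param B Number of resamples (analysis default 1000).
#' @param fraction Subsample fraction (default 0.5).
#' @param seed Integer seed.
#' @param n_init k-means restarts per reclustering.
#' @return Object of class `stability_report`: list with `algorithm`, `k`,
#'   `B`, `fraction`, `seed`, `jaccard` (per-cluster means), `n_skipped`
#'   (per-cluster skip counts) and `full_assignment`.
#' @export
clusterwise_stability <- function(D, algorithm = c("hierarchical", "kmeans", "pam"),
                                  k, B = 1000L, fraction = 0.5, seed,
                                  n_init = 50L) {
  algorithm <- match.arg(algorithm)
  check_distance_matrix(D)
  stopifnot(B >= 1, fraction > 0, fraction <= 1)
  n <- nrow(D)
  ids <- rownames(D) %||% as.character(seq_len(n))
  rownames(D) <- colnames(D) <- ids
  full <- cluster_distance(D, algorithm, k, n_init = n_init,
                           seed = derive_seed(seed, 0L))
  full_sets <- split(ids, full)
  m <- ceiling(fraction * n)
  sums <- numeric(k)
  counts <- integer(k)
  skipped <- integer(k)
  set.seed(seed)
  for (b in seq_len(B)) {
    sub_ids <- ids[sample.int(n, m)]
    sub_seed <- sample.int(2147483646L, 1L)
    if (m < k) {
      skipped <- skipped + 1L
      next
    }
    subD <- D[sub_ids, sub_ids, drop = FALSE]
    sub <- cluster_distance(subD, algorithm, k, n_init = n_init,
                            seed = sub_seed)
    sub_sets <- split(sub_ids, sub)
    for (ci in seq_len(k)) {
      inter <- intersect(full_sets[[ci]], sub_ids)
      if (!length(inter)) {
        skipped[ci] <- skipped[ci] + 1L
        next
      }
      sums[ci] <- sums[ci] +
        max(vapply(sub_sets, function(s) jaccard(inter, s), 0))
      counts[ci] <- counts[ci] + 1L
    }
  }
  structure(list(algorithm = algorithm, k = k, B = as.integer(B),
                 fraction = fraction, seed = as.integer(seed),
                 jaccard = ifelse(counts > 0, sums / counts, NA_real_),
                 n_skipped = skipped, full_assignment = full),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Clusterwise stability (%s, k = %d, B = %d, fraction = %.2f)\n",
              x$algorithm, x$k, x$B, x$fraction))
  cat("  mean Jaccard per cluster:",
      paste(sprintf("%.3f", x$jaccard), collapse = " "), "\n")
  invisible(x)
}

#' Scan cluster numbers and algorithms for stability
#'
#' Runs [clusterwise_stability()] for every combination of algorithm and
#' cluster number with identical resampling seeds across k, so reports are
#' paired.
#'
#' @inheritParams clusterwise_stability
#' @param algorithms Character vector of algorithms.
#' @param k_range Cluster numbers (analysis default 2..10).
#' @return List of `stability_report` objects, plus a `summary` data frame
#'   attribute via [stability_table()].
#' @export
stability_scan <- function(D, algorithms = c("hierarchical", "kmeans"),
                           k_range = 2:10, B = 1000L, fraction = 0.5, seed,
                           n_init = 50L) {
  reports <- list()
  for (alg in algorithms)
    for (k in k_range)
      reports[[paste(alg, k, sep = "_")]] <-
        clusterwise_stability(D, alg, k, B = B, fraction = fraction,
                              seed = seed, n_init = n_init)
  reports
}

#' Tabulate stability reports
#'
#' @param reports List of `stability_report` objects.
#' @return Data frame: algorithm, k, per-report minimum and mean clusterwise
#'   Jaccard, and total skips.
#' @export
stability_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(algorithm = r$algorithm, k = r$k,
               min_jaccard = min(r$jaccard, na.rm = TRUE),
               mean_jaccard = mean(r$jaccard, na.rm = TRUE),
               n_skipped = sum(r$n_skipped),
               stringsAsFactors = FALSE)))
}

#' Select the number of clusters from stability reports
#'
#' A solution is called highly stable when its clusterwise mean Jaccard
#' indices all exceed the threshold (aggregation by minimum; `"mean"`
#' aggregates less conservatively). All stable (algorithm, k) pairs are
#' returned and the smallest stable k is flagged as primary.
#'
#' @param reports List of `stability_report` objects.
#' @param threshold Stability threshold (default 0.85).
#' @param aggregate `"min"` (default) or `"mean"` over clusterwise indices.
#' @return Data frame with columns algorithm, k, stability, stable, primary;
#'   zero stable rows leaves every `stable` FALSE with a message.
#' @export
select_k <- function(reports, threshold = 0.85,
                     aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "min") function(x) min(x, na.rm = TRUE)
             else function(x) mean(x, na.rm = TRUE)
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(algorithm = r$algorithm, k = r$k,
               stability = agg_fun(r$jaccard), stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  tab$stable <- tab$stability > threshold
  tab$primary <- FALSE
  if (any(tab$stable)) {
    k_min <- min(tab$k[tab$stable])
    tab$primary <- tab$stable & tab$k == k_min
  } else {
    message("no (algorithm, k) reaches the stability threshold ", threshold)
  }
  tab[order(tab$algorithm, tab$k), ]
}
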