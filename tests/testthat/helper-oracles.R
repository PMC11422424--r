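# Independent reference implementations and fixture builders used across the
# suite. They deliberately avoid the code paths they are meant to check.

# Naive O(n^3) Ward.D2 agglomeration: keeps the full inter-cluster distance
# matrix and applies the Lance-Williams update
#   d(ij,k) = sqrt(((n_i+n_k) d_ik^2 + (n_j+n_k) d_jk^2 - n_k d_ij^2) /
#                  (n_i+n_j+n_k))
# at every merge, ties broken by the lexicographically smallest active pair.
# Returns merge heights and the membership partition after each merge.
naive_ward2 <- function(D) {
  n <- nrow(D)
  act <- as.list(seq_len(n))      # member indices per active cluster
  d <- D
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  sizes <- rep(1L, n)
  alive <- rep(TRUE, n)
  labels <- seq_len(n)            # current cluster id per observation
  for (step in seq_len(n - 1)) {
    idx <- which(alive)
    best <- c(NA, NA); bd <- Inf
    for (ai in seq_along(idx))
      for (bi in seq_along(idx))
        if (bi > ai) {
          i <- idx[ai]; j <- idx[bi]
          if (d[i, j] < bd - 1e-12) { bd <- d[i, j]; best <- c(i, j) }
        }
    i <- best[1]; j <- best[2]
    heights[step] <- bd
    ni <- sizes[i]; nj <- sizes[j]
    for (k in idx)
      if (k != i && k != j) {
        nk <- sizes[k]
        d[i, k] <- d[k, i] <- sqrt(((ni + nk) * d[i, k]^2 +
                                    (nj + nk) * d[j, k]^2 -
                                    nk * d[i, j]^2) / (ni + nj + nk))
      }
    sizes[i] <- ni + nj
    alive[j] <- FALSE
    act[[i]] <- c(act[[i]], act[[j]])
    labels[act[[i]]] <- i
    partitions[[step]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition for label-free comparison
canon_partition <- function(labels) match(labels, unique(labels))

# Distance matrix of two well-separated blobs: within-blob distances are
# small, between-blob distances large. Built directly, not via DTW.
blob_distance <- function(n1, n2, within = 1, between = 20, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      same <- (i <= n1) == (j <= n1)
      D[i, j] <- D[j, i] <- if (same) within * runif(1, 0.5, 1.5)
                            else between * runif(1, 0.9, 1.1)
    }
  dimnames(D) <- list(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
  D
}

# Smooth low-rank participant x 42 matrix on the 1-7 scale: row i follows a
# monotone ramp scaled by a row coefficient, values in [1, 7].
smooth_grid <- function(n_rows = 25, n_cols = 42, seed = 1) {
  set.seed(seed)
  ramp <- seq(0, 1, length.out = n_cols)
  coef <- runif(n_rows, 0.3, 1)
  mat <- 1 + 6 * outer(coef, ramp)
  rownames(mat) <- sprintf("R%02d", seq_len(n_rows))
  mat
}

# mask a fraction of cells MCAR, guaranteeing every row keeps >= 2 observed
mask_mcar <- function(mat, rate, seed) {
  set.seed(seed)
  out <- mat
  holes <- matrix(runif(length(mat)) < rate, nrow(mat))
  for (i in seq_len(nrow(mat)))
    if (sum(!holes[i, ]) < 2) holes[i, sample(ncol(mat), 2)] <- FALSE
  out[holes] <- NA
  out
}

# small complete records table for preprocessing tests (one participant,
# explicit times)
records_at <- function(times, ratings, item = "voices", id = "S001",
                       day = 1L, group = "HC", study = "A") {
  data.frame(participant_id = id, study = study, group = group,
             day = day, time = times, item = item, rating = ratings,
             stringsAsFactors = FALSE)
}
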