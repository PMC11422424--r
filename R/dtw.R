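#' Banded dynamic time warping distance
#'
#' Aligns two series by stretching and compression and returns the minimal
#' cumulative cost under the symmetric step pattern known as `symmetricP0`:
#' local cost `d(i,j) = |x_i - y_j|`, recursion
#' `g(i,j) = min(g(i-1,j-1) + 2 d, g(i-1,j) + d, g(i,j-1) + d)` with
#' `g(1,1) = 2 d(1,1)`, restricted to the Sakoe-Chiba band `|i - j| <= w`.
#' The distance is returned unnormalized; for equal-length series (the
#' length-42 composite trajectories) path normalization is a constant factor
#' and cannot change any downstream clustering, but `normalize = TRUE`
#' divides by `n + m` for unequal-length use.
#'
#' @param x,y Numeric series, no missing values.
#' @param window Band half-width `w >= 1`. Endpoints must satisfy
#'   `|length(x) - length(y)| <= w`, else no admissible path exists.
#' @param normalize Divide by `n + m` (default `FALSE`).
#' @return Nonnegative distance.
#' @examples
#' dtw_distance(c(0, 0, 0), c(1, 1, 1), window = 2) # 6
#' dtw_distance(c(1, 3), c(1, 2, 3), window = 2)    # 1
#' @export
dtw_distance <- function(x, y, window, normalize = FALSE) {
  if (!length(x) || !length(y)) stop("empty series")
  if (anyNA(x) || anyNA(y)) stop("series must be complete")
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  if (abs(length(x) - length(y)) > window)
    stop("band excludes endpoint: |n - m| > window")
  d <- dtw_band_cpp(as.numeric(x), as.numeric(y), window)
  if (d < 0) stop("band excludes endpoint")
  if (normalize) d <- d / (length(x) + length(y))
  d
}

#' Pairwise DTW distance matrix between trajectories
#'
#' @param traj Numeric participant x time matrix of complete trajectories
#'   (row names = participant ids).
#' @param window Sakoe-Chiba band half-width; the analysis defaults are
#'   2, 4, 8 and 16.
#' @return Symmetric distance matrix with zero diagonal and the participant
#'   ids as dimnames.
#' @export
pairwise_dtw <- function(traj, window) {
  stopifnot(is.matrix(traj), nrow(traj) >= 2)
  if (anyNA(traj)) stop("trajectories must be complete")
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  D <- pairwise_dtw_cpp(traj, window)
  dimnames(D) <- list(rownames(traj), rownames(traj))
  D
}

#' Exhaustive path-enumeration DTW oracle
#'
#' Recursively enumerates every admissible monotone warping path of the
#' symmetric step pattern within the band and returns the minimal cost. It is
#' deliberately independent of the dynamic-programming implementation and
#' exponential in the instance size, so it is limited to `n * m <= 64`.
#'
#' @inheritParams dtw_distance
#' @return Minimal path cost; equals [dtw_distance()] by construction of the
#'   recursion.
#' @export
dtw_bruteforce_oracle <- function(x, y, window) {
  n <- length(x); m <- length(y)
  if (!n || !m) stop("empty series")
  if (n * m > 64) stop("instance too large for enumeration (n*m > 64)")
  window <- as.integer(window)
  if (abs(n - m) > window) stop("band excludes endpoint")
  best <- function(i, j) {
    if (abs(i - j) > window) return(Inf)
    d <- abs(x[i] - y[j])
    if (i == 1 && j == 1) return(2 * d)
    cand <- Inf
    if (i > 1 && j > 1) cand <- min(cand, best(i - 1, j - 1) + 2 * d)
    if (i > 1) cand <- min(cand, best(i - 1, j) + d)
    if (j > 1) cand <- min(cand, best(i, j - 1) + d)
    cand
  }
  res <- best(n, m)
  if (!is.finite(res)) stop("band excludes endpoint")
  res
}
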