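#' Initial mean imputation of an item matrix
#'
#' Fills each missing cell with the mean of the participant's observed
#' ratings for that item (row mean). A participant with no observed rating at
#' all falls back to the slot-wise (column) mean, and a slot observed for
#' nobody falls back to the grand mean. Observed cells are never altered.
#'
#' @param mat Numeric participant x slot matrix with `NA` for missing.
#' @return The completed matrix.
#' @export
initial_impute <- function(mat) {
  if (all(is.na(mat))) stop("matrix fully missing: nothing to anchor imputation")
  miss <- is.na(mat)
  row_mean <- rowMeans(mat, na.rm = TRUE)
  col_mean <- colMeans(mat, na.rm = TRUE)
  col_mean[is.nan(col_mean)] <- mean(mat, na.rm = TRUE)
  for (i in seq_len(nrow(mat))) {
    if (!any(miss[i, ])) next
    fill <- if (is.nan(row_mean[i])) col_mean[miss[i, ]] else row_mean[i]
    mat[i, miss[i, ]] <- fill
  }
  mat
}

#' Iterative random-forest imputation of an item matrix
#'
#' Starting from [initial_impute()], each slot column with originally missing
#' cells is regressed on all other slots with a random forest fitted on the
#' participants observed for that slot, and its missing cells are replaced by
#' the forest predictions; columns are visited in order of increasing
#' missingness. After each sweep the relative change
#' `delta = sum((new - old)^2) / sum(new^2)` over the imputed cells is
#' evaluated; sweeps repeat until `delta` increases relative to the previous
#' sweep, and the previous iterate (the one before the increase) is returned.
#' Imputed values are clamped to the 1-7 rating range; observed cells are
#' untouched.
#'
#' @param mat Numeric participant x slot matrix, `NA` = missing.
#' @param n_trees Trees per forest (default 100).
#' @param mtry Predictors per split; default `floor(sqrt(ncol - 1))`.
#' @param max_iter Sweep cap (default 10).
#' @param seed Integer seed; forests run single-threaded for determinism.
#' @return List: `matrix` (completed), `iterations` (sweeps kept) and
#'   `delta` (the convergence trace).
#' @export
rf_impute <- function(mat, n_trees = 100L, mtry = NULL, max_iter = 10L, seed) {
  miss <- is.na(mat)
  if (!any(miss))
    return(list(matrix = mat, iterations = 0L, delta = numeric(0)))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(mat) - 1L)))
  cur <- initial_impute(mat)
  cols <- which(colSums(miss) > 0L)
  cols <- cols[order(colSums(miss)[cols], cols)]
  all_missing_cols <- cols[colSums(!miss)[cols] == 0L]
  if (length(all_missing_cols)) {
    warning("column(s) with no observed values kept at initial imputation: ",
            paste(all_missing_cols, collapse = ", "))
    cols <- setdiff(cols, all_missing_cols)
  }
  set.seed(seed)
  delta <- numeric(0)
  prev <- cur
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    prev <- cur
    for (j in cols) {
      obs <- which(!miss[, j])
      dat <- as.data.frame(cur[, -j, drop = FALSE])
      names(dat) <- paste0("p", seq_len(ncol(dat)))
      dat$y <- cur[, j]
      fit <- ranger::ranger(y ~ ., data = dat[obs, , drop = FALSE],
                            num.trees = n_trees, mtry = min(mtry, ncol(dat) - 1L),
                            num.threads = 1L,
                            seed = sample.int(2147483646L, 1L))
      pred <- predict(fit, dat[miss[, j], , drop = FALSE],
                      num.threads = 1L)$predictions
      cur[miss[, j], j] <- pmin(pmax(pred, 1), 7)
    }
    d <- sum((cur[miss] - prev[miss])^2) / sum(cur[miss]^2)
    delta <- c(delta, d)
    if (it >= 2L && d > delta[it - 1L]) {
      return(list(matrix = prev, iterations = it - 1L, delta = delta))
    }
    iterations <- it
  }
  list(matrix = cur, iterations = iterations, delta = delta)
}

#' Impute all five item matrices
#'
#' Runs [rf_impute()] per item on the pooled (both designs) slot grids and
#' reports the missingness and convergence trace per item.
#'
#' @param grids A `slot_grids` list from [build_slot_grids()].
#' @inheritParams rf_impute
#' @return List: `grids` (completed matrices) and `report` (data frame with
#'   per-item percent missing and iterations used).
#' @export
impute_grids <- function(grids, n_trees = 100L, max_iter = 10L, seed) {
  out <- vector("list", length(grids))
  names(out) <- names(grids)
  rep_rows <- vector("list", length(grids))
  for (i in seq_along(grids)) {
    res <- rf_impute(grids[[i]], n_trees = n_trees, max_iter = max_iter,
                     seed = seed + i)
    out[[i]] <- res$matrix
    rep_rows[[i]] <- data.frame(item = names(grids)[i],
                                pct_missing = 100 * mean(is.na(grids[[i]])),
                                iterations = res$iterations,
                                stringsAsFactors = FALSE)
  }
  list(grids = structure(out, class = "slot_grids"),
       report = do.call(rbind, rep_rows))
}

#' Composite psychotic-symptom trajectory
#'
#' The composite rating at each slot is the mean of the five imputed item
#' values at that slot, giving one complete length-42 series per participant.
#'
#' @param grids Named list of five complete item matrices over identical
#'   participants.
#' @return Numeric participant x 42 matrix in `[1, 7]`.
#' @export
composite_score <- function(grids) {
  ids <- rownames(grids[[1]])
  for (g in grids) {
    if (!identical(rownames(g), ids))
      stop("participant sets differ between item matrices")
    if (anyNA(g)) stop("item matrices must be complete")
  }
  Reduce(`+`, grids) / length(grids)
}
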