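#' Pipeline configuration
#'
#' Collects every tunable of the analysis with defaults reproducing the
#' published settings: Sakoe-Chiba windows 2/4/8/16 (window 2 primary),
#' cluster numbers 2..10, 1000 subsamples of 50% without replacement, a 0.85
#' stability threshold, a one-third compliance threshold, and 100-tree
#' random-forest imputation.
#'
#' @param seed Master seed (mandatory); per-stage seeds are derived from it.
#' @param windows Sakoe-Chiba band half-widths to analyze.
#' @param k_range Candidate cluster numbers.
#' @param algorithms Clustering algorithms to scan.
#' @param B Stability resamples.
#' @param fraction Subsample fraction.
#' @param threshold Jaccard stability threshold.
#' @param min_response_rate Compliance retention threshold.
#' @param n_trees,max_iter Random-forest imputation settings.
#' @param n_init k-means restarts.
#' @param fdr_alpha FDR threshold for post-hoc testing.
#' @param synthetic Optional [cohort_spec()]-style list for synthetic input.
#' @param input Optional path to a long-format EMA CSV.
#' @return Object of class `ema_config`.
#' @export
ema_config <- function(seed, windows = c(2L, 4L, 8L, 16L), k_range = 2:10,
                       algorithms = c("hierarchical", "kmeans"),
                       B = 1000L, fraction = 0.5, threshold = 0.85,
                       min_response_rate = 1 / 3, n_trees = 100L,
                       max_iter = 10L, n_init = 50L, fdr_alpha = 0.05,
                       synthetic = NULL, input = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(seed = as.integer(seed), windows = as.integer(windows),
                 k_range = as.integer(k_range), algorithms = algorithms,
                 B = as.integer(B), fraction = fraction, threshold = threshold,
                 min_response_rate = min_response_rate,
                 n_trees = as.integer(n_trees), max_iter = as.integer(max_iter),
                 n_init = as.integer(n_init), fdr_alpha = fdr_alpha,
                 synthetic = synthetic, input = input),
            class = "ema_config")
}

#' Cluster EMA symptom trajectories
#'
#' The central fitting function. Long-format momentary ratings are restricted
#' to the five psychotic-symptom items, non-compliant participants are
#' excluded, ratings are averaged onto the 7x6 slot grid, the grid is
#' completed by iterative random-forest imputation, and the composite
#' trajectories are compared pairwise with banded DTW. Participants are then
#' clustered (Ward.D2 hierarchical and k-means on the distance profiles) for
#' each candidate number of clusters, cluster stability is measured by
#' subsampling Jaccard indices, and the smallest highly stable solution is
#' selected. When several band widths are given, the whole
#' distance/cluster/stability block is repeated per width; the first width is
#' the primary analysis.
#'
#' @param records Long-format EMA records (see [read_ema_csv()] for the
#'   dialect) or the list returned by [simulate_ema_cohort()].
#' @param windows Sakoe-Chiba band half-width(s); first is primary.
#' @param k_range Candidate cluster numbers.
#' @param algorithms Clustering algorithms to scan.
#' @param B,fraction Stability resampling settings.
#' @param threshold Stability threshold.
#' @param min_response_rate Compliance threshold.
#' @param presented Optional presented-beep counts per participant.
#' @param n_trees,max_iter Imputation settings.
#' @param n_init k-means restarts.
#' @param seed Master seed.
#' @return Object of class `ema_clust` with components `trajectories`
#'   (n x 42), `distance` (list by window), `stability` (list by window),
#'   `selection` (list by window of [select_k()] tables), `selected_k`
#'   (per window), `assignment` (primary solution labels), `groups`,
#'   `excluded`, `impute_report` and `config`.
#' @examples
#' sim <- simulate_ema_cohort(cohort_spec(n_hc = 6, n_re = 0, n_pd = 6,
#'                                        high_frac_pd = 1, seed = 1),
#'                            trajectory_params(missing_rate = 0.2))
#' fit <- ema_clust(sim$records, windows = 2, B = 50, seed = 1)
#' print(fit)
#' @export
ema_clust <- function(records, windows = 2L, k_range = 2:10,
                      algorithms = c("hierarchical", "kmeans"),
                      B = 1000L, fraction = 0.5, threshold = 0.85,
                      min_response_rate = 1 / 3, presented = NULL,
                      n_trees = 100L, max_iter = 10L, n_init = 50L,
                      seed = 1L) {
  cl <- match.call()
  if (is.list(records) && !is.data.frame(records) && !is.null(records$records))
    records <- records$records
  if (!nrow(records)) stop("preprocess: empty input")
  pre <- preprocess_records(records, presented = presented,
                            min_response_rate = min_response_rate)
  if (length(pre$included) < 2)
    stop("preprocess: fewer than 2 compliant participants")
  imp <- impute_grids(pre$grids, n_trees = n_trees, max_iter = max_iter,
                      seed = derive_seed(seed, 10L))
  traj <- composite_score(imp$grids)
  groups <- records$group[match(rownames(traj), records$participant_id)]
  names(groups) <- rownames(traj)

  windows <- as.integer(windows)
  distance <- stability <- selection <- vector("list", length(windows))
  names(distance) <- names(stability) <- names(selection) <- paste0("w", windows)
  selected_k <- rep(NA_integer_, length(windows))
  names(selected_k) <- names(distance)
  for (i in seq_along(windows)) {
    D <- pairwise_dtw(traj, windows[i])
    reps <- stability_scan(D, algorithms = algorithms, k_range = k_range,
                           B = B, fraction = fraction,
                           seed = derive_seed(seed, 20L), n_init = n_init)
    sel <- select_k(reps, threshold = threshold)
    distance[[i]] <- D
    stability[[i]] <- reps
    selection[[i]] <- sel
    if (any(sel$stable)) selected_k[i] <- min(sel$k[sel$stable])
  }
  primary_k <- selected_k[1]
  assignment <- NULL
  primary_algorithm <- NA_character_
  if (!is.na(primary_k)) {
    sel1 <- selection[[1]]
    primary_algorithm <- sel1$algorithm[sel1$primary][1]
    assignment <- stability[[1]][[paste(primary_algorithm, primary_k,
                                        sep = "_")]]$full_assignment
  }
  structure(list(call = cl, trajectories = traj, groups = groups,
                 distance = distance, stability = stability,
                 selection = selection, selected_k = selected_k,
                 assignment = assignment,
                 primary_algorithm = primary_algorithm,
                 excluded = pre$excluded, compliance = pre$compliance,
                 impute_report = imp$report,
                 config = list(windows = windows, k_range = k_range,
                               algorithms = algorithms, B = B,
                               fraction = fraction, threshold = threshold,
                               min_response_rate = min_response_rate,
                               n_trees = n_trees, n_init = n_init,
                               seed = seed)),
            class = "ema_clust")
}

#' @export
print.ema_clust <- function(x, ...) {
  cat("EMA symptom-trajectory clustering (banded DTW)\n")
  cat(sprintf("  participants: %d (excluded: %d)\n", nrow(x$trajectories),
              NROW(x$excluded)))
  cat(sprintf("  windows: %s; primary window: %d\n",
              paste(x$config$windows, collapse = ", "), x$config$windows[1]))
  if (is.na(x$selected_k[1])) {
    cat("  no highly stable cluster solution (threshold ",
        x$config$threshold, ")\n", sep = "")
  } else {
    cat(sprintf("  selected k = %d (%s), cluster sizes: %s\n",
                x$selected_k[1], x$primary_algorithm,
                paste(table(x$assignment), collapse = "/")))
    if (length(x$config$windows) > 1)
      cat(sprintf("  selected k per window: %s\n",
                  paste(x$selected_k, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.ema_clust <- function(object, ...) {
  traj <- object$trajectories
  ts <- summarize_trajectory(traj)
  out <- list(n = nrow(traj), selected_k = object$selected_k,
              threshold = object$config$threshold,
              selection = object$selection[[1]],
              trajectory_summary = ts)
  if (!is.null(object$assignment)) {
    a <- object$assignment
    out$cluster_sizes <- table(a)
    out$composition <- table(object$groups[names(a)], a)
    out$mean_rating_by_cluster <- tapply(ts$mean_rating[match(names(a),
                                         ts$participant_id)], a, mean)
    out$corrected_variance_by_cluster <-
      tapply(ts$corrected_variance[match(names(a), ts$participant_id)], a, mean)
    if (length(unique(a)) == 2) {
      sp <- split(ts$mean_rating[match(names(a), ts$participant_id)], a)
      out$mean_rating_test <- welch_t(sp[[1]], sp[[2]])
    }
    if (nrow(out$composition) >= 2)
      out$composition_test <- pearson_chi2(out$composition)
  }
  class(out) <- "summary.ema_clust"
  out
}

#' @export
print.summary.ema_clust <- function(x, ...) {
  cat(sprintf("EMA trajectory clustering: %d participants\n", x$n))
  if (is.na(x$selected_k[1])) {
    cat("no highly stable solution at threshold", x$threshold, "\n")
    return(invisible(x))
  }
  cat(sprintf("selected k = %d; cluster sizes %s\n", x$selected_k[1],
              paste(x$cluster_sizes, collapse = "/")))
  cat("\nstudy-group composition by cluster:\n")
  print(x$composition)
  if (!is.null(x$composition_test))
    cat(sprintf("  chi-square(%d) = %.2f, p = %.3f\n", x$composition_test$df,
                x$composition_test$statistic, x$composition_test$p))
  cat("\nmean composite rating by cluster:",
      paste(sprintf("%.2f", x$mean_rating_by_cluster), collapse = " vs "), "\n")
  if (!is.null(x$mean_rating_test))
    cat(sprintf("  Welch t(%.2f) = %.2f, p = %.3g, 95%% CI [%.2f, %.2f]\n",
                x$mean_rating_test$df, x$mean_rating_test$statistic,
                x$mean_rating_test$p, x$mean_rating_test$ci[1],
                x$mean_rating_test$ci[2]))
  cat("mean corrected rating variance by cluster:",
      paste(sprintf("%.3f", x$corrected_variance_by_cluster),
            collapse = " vs "), "\n")
  invisible(x)
}

#' Plot method for EMA trajectory clusterings
#'
#' `type = "stability"` draws the minimum clusterwise Jaccard stability
#' against the number of clusters per algorithm with the selection threshold
#' as a dashed line; `type = "trajectories"` draws the composite trajectories
#' colored by cluster; `type = "dendrogram"` the Ward.D2 tree of the primary
#' window.
#'
#' @param x An `ema_clust` object.
#' @param type Plot type.
#' @param window Which band width to plot (default the primary).
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.ema_clust <- function(x, type = c("stability", "trajectories",
                                       "dendrogram"),
                           window = x$config$windows[1], ...) {
  type <- match.arg(type)
  wkey <- paste0("w", window)
  if (type == "stability") {
    tab <- stability_table(x$stability[[wkey]])
    algs <- unique(tab$algorithm)
    ks <- sort(unique(tab$k))
    graphics::plot(range(ks), c(0, 1), type = "n", xlab = "number of clusters",
                   ylab = "min clusterwise Jaccard",
                   main = sprintf("Cluster stability (window %d)", window), ...)
    for (i in seq_along(algs)) {
      sub <- tab[tab$algorithm == algs[i], ]
      graphics::lines(sub$k, sub$min_jaccard, type = "b", col = i + 1, pch = 19)
    }
    graphics::abline(h = x$config$threshold, lty = 2)
    graphics::legend("bottomleft", legend = algs, col = seq_along(algs) + 1,
                     pch = 19, bty = "n")
  } else if (type == "trajectories") {
    a <- x$assignment %||% rep(1L, nrow(x$trajectories))
    graphics::matplot(t(x$trajectories), type = "l", lty = 1,
                      col = a[rownames(x$trajectories)] + 1,
                      xlab = "slot (7 days x 6 slots)",
                      ylab = "composite symptom rating", ...)
    graphics::abline(v = seq(6.5, 36.5, by = 6), col = "grey80")
  } else {
    graphics::plot(hclust_ward2(x$distance[[wkey]]), labels = FALSE,
                   main = sprintf("Ward.D2 dendrogram (window %d)", window),
                   xlab = "", sub = "", ...)
  }
  invisible(x)
}

#' Run the end-to-end pipeline and write artifacts
#'
#' Generates a synthetic cohort (or reads a long-format CSV), fits
#' [ema_clust()] for every configured band width, characterizes the primary
#' clusters, and writes every intermediate product plus a manifest into
#' `out_dir`.
#'
#' @param config An [ema_config()]; exactly one of `config$synthetic` (a
#'   [cohort_spec()]) or `config$input` (CSV path) must be set.
#' @param out_dir Output directory, created if needed.
#' @param params [trajectory_params()] for synthetic input.
#' @return The fitted `ema_clust` object, invisibly.
#' @export
run_pipeline <- function(config, out_dir, params = trajectory_params()) {
  stopifnot(inherits(config, "ema_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$synthetic)) {
    sim <- simulate_ema_cohort(config$synthetic, params)
    records <- sim$records
    write_ema_csv(records, file.path(out_dir, "records.csv"))
  } else if (!is.null(config$input)) {
    records <- read_ema_csv(config$input)
  } else stop("input: config must carry either a synthetic spec or a CSV path")

  fit <- ema_clust(records, windows = config$windows,
                   k_range = config$k_range, algorithms = config$algorithms,
                   B = config$B, fraction = config$fraction,
                   threshold = config$threshold,
                   min_response_rate = config$min_response_rate,
                   n_trees = config$n_trees, max_iter = config$max_iter,
                   n_init = config$n_init, seed = config$seed)

  write_trajectories_csv(fit$trajectories,
                         file.path(out_dir, "trajectories.csv"),
                         groups = fit$groups)
  for (w in names(fit$distance))
    write_distance_csv(fit$distance[[w]],
                       file.path(out_dir, paste0("distance_", w, ".csv")))
  stab <- do.call(rbind, lapply(names(fit$stability), function(w) {
    tab <- stability_table(fit$stability[[w]])
    tab$window <- as.integer(sub("w", "", w))
    tab
  }))
  write.csv(stab, file.path(out_dir, "stability.csv"), row.names = FALSE)
  sel <- do.call(rbind, lapply(names(fit$selection), function(w) {
    tab <- fit$selection[[w]]
    tab$window <- as.integer(sub("w", "", w))
    tab
  }))
  write.csv(sel, file.path(out_dir, "selection.csv"), row.names = FALSE)
  if (!is.null(fit$assignment)) {
    write.csv(data.frame(participant_id = names(fit$assignment),
                         algorithm = fit$primary_algorithm,
                         k = unname(fit$selected_k[1]),
                         label = as.integer(fit$assignment)),
              file.path(out_dir, "assignments.csv"), row.names = FALSE)
    ts <- summarize_trajectory(fit$trajectories)
    dat <- data.frame(participant_id = ts$participant_id,
                      mean_rating = ts$mean_rating,
                      corrected_variance = ts$corrected_variance,
                      group = unname(fit$groups[ts$participant_id]),
                      stringsAsFactors = FALSE)
    fams <- c(mean_rating = "cluster_characterization",
              corrected_variance = "cluster_characterization",
              group = "demographics")
    comp <- characterize_clusters(fit$assignment, dat, families = fams,
                                  alpha = config$fdr_alpha)
    write.csv(comp$comparisons, file.path(out_dir, "comparisons.csv"),
              row.names = FALSE)
  }
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "synthetic")],
                               auto_unbox = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(package = "emadtw",
                   version = as.character(packageVersion("emadtw")),
                   r_version = as.character(getRversion()),
                   seed = config$seed,
                   config = config[setdiff(names(config), "synthetic")],
                   config_hash = unname(tools::md5sum(tf)),
                   selected_k = as.list(fit$selected_k))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(fit)
}
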