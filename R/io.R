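#' Read and write long-format EMA records
#'
#' The on-disk dialect is a CSV with header
#' `participant_id, study, group, day, time, item, rating`; one row per item
#' per beep, empty rating field meaning missing.
#'
#' @param path File path.
#' @name ema_csv
NULL

#' @rdname ema_csv
#' @param records Long-format EMA records.
#' @export
write_ema_csv <- function(records, path) {
  stopifnot(all(c("participant_id", "study", "group", "day", "time",
                  "item", "rating") %in% names(records)))
  write.csv(records[, c("participant_id", "study", "group", "day", "time",
                        "item", "rating")],
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname ema_csv
#' @return `read_ema_csv()`: the records data frame with integer `day` and
#'   `rating` (NA = missing).
#' @export
read_ema_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "study", "group", "day", "time", "item", "rating")
  if (length(names(df)) < length(need) ||
      !identical(names(df)[seq_along(need)], need))
    stop("malformed header: expected ", paste(need, collapse = ", "))
  for (col in c("participant_id", "study", "group", "time", "item"))
    df[[col]] <- as.character(df[[col]])
  df$day <- as.integer(df$day)
  df$rating <- suppressWarnings(as.integer(df$rating))
  bad <- which(!is.na(df$rating) & (df$rating < 1L | df$rating > 7L))
  if (length(bad))
    stop(sprintf("rating outside 1..7 at row %d", bad[1] + 1L))
  bad_day <- which(is.na(df$day) | df$day < 1L | df$day > N_DAYS)
  if (length(bad_day))
    stop(sprintf("day outside 1..7 at row %d", bad_day[1] + 1L))
  df
}

#' Write completed trajectories as wide CSV
#'
#' @param traj Numeric participant x 42 matrix.
#' @param groups Optional named group labels.
#' @param path File path.
#' @export
write_trajectories_csv <- function(traj, path, groups = NULL) {
  df <- data.frame(participant_id = rownames(traj), stringsAsFactors = FALSE)
  if (!is.null(groups)) df$group <- unname(groups[rownames(traj)])
  df <- cbind(df, as.data.frame(signif(traj, 6)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a square distance matrix with participant-id header row and column
#'
#' @param D Symmetric distance matrix with row/col names.
#' @param path File path.
#' @export
write_distance_csv <- function(D, path) {
  write.csv(signif(D, 6), path, row.names = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [ema_config()]; `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return An `ema_config` object.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must specify a seed")
  do.call(ema_config, cfg)
}
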