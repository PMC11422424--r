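#' Map a clock time to one of the six two-hour day slots
#'
#' Harmonizes the two sampling windows onto a common grid: slot 1 is
#' everything before noon, slots 2-5 are the two-hour windows 12:00-20:00
#' (lower bound inclusive), and slot 6 collects everything from 20:00 on.
#' Ratings after 22:30 cannot arise from either design and are rejected.
#'
#' @param time Character "HH:MM" or integer minutes since midnight.
#' @return Integer slot index 1..6.
#' @export
slot_of_time <- function(time) {
  m <- if (is.character(time)) hhmm_to_min(time) else as.integer(time)
  if (any(is.na(m) | m < 0L | m >= 1440L))
    stop("time outside 00:00-24:00")
  findInterval(m, c(0L, 720L, 840L, 960L, 1080L, 1200L))
}

#' Annotate records with their day-slot position
#'
#' Adds `slot` (1..6) and `grid_index` ((day-1)*6 + slot, 1..42) columns.
#' Slot 6 is printed as 20:00-22:00, but design A beeps run until 22:30;
#' records after 22:00 are kept in slot 6 rather than discarded and flagged
#' in the `late` attribute of the result.
#'
#' @param records Long-format EMA records (see [generate_ema_records()]).
#' @return The records with `slot` and `grid_index` columns; attribute `late`
#'   holds the row indices of post-22:30 records.
#' @export
assign_slots <- function(records) {
  m <- hhmm_to_min(records$time)
  slot <- slot_of_time(m)
  records$slot <- slot
  records$grid_index <- (records$day - 1L) * N_SLOTS + slot
  if (any(records$day < 1L | records$day > N_DAYS))
    stop("day index outside 1..7")
  attr(records, "late") <- which(m > 1320L)
  records
}

#' Restrict records to the five psychotic-symptom analysis items
#'
#' @param records Long-format EMA records.
#' @return Records containing only the items `voices`, `see_things`,
#'   `dislike`, `suspicious`, `harm`. Other item ids are dropped with a
#'   warning naming them.
#' @export
extract_psychotic_items <- function(records) {
  unknown <- setdiff(unique(records$item), PSYCHOTIC_ITEMS)
  if (length(unknown))
    warning("dropping non-analysis item(s): ", paste(unknown, collapse = ", "))
  records[records$item %in% PSYCHOTIC_ITEMS, , drop = FALSE]
}

#' Exclude non-compliant participants
#'
#' A participant is retained iff the proportion of presented beeps they
#' answered (a beep counts as answered when at least one item rating is
#' present) is at least `min_response_rate`; the boundary is inclusive, so
#' exactly one third answered passes the default threshold.
#'
#' @param records Long-format EMA records; unanswered beeps must be present
#'   as rows with `NA` ratings, or `presented` must be supplied.
#' @param presented Optional named integer vector of presented beep counts per
#'   participant; derived from the records when `NULL`.
#' @param min_response_rate Retention threshold (default 1/3).
#' @return List with `included` (character ids), `excluded` (data frame of
#'   exclusions with reasons) and `compliance` (per-participant rates).
#' @export
filter_compliance <- function(records, presented = NULL,
                              min_response_rate = 1 / 3) {
  ids <- unique(records$participant_id)
  beep_key <- paste(records$participant_id, records$day, records$time)
  if (is.null(presented)) {
    presented_tab <- tapply(beep_key, records$participant_id,
                            function(k) length(unique(k)))
    presented <- as.integer(presented_tab)
    names(presented) <- names(presented_tab)
  }
  miss <- setdiff(ids, names(presented))
  if (length(miss))
    stop("no presented-beep information for participant(s): ",
         paste(miss, collapse = ", "))
  ans <- records[!is.na(records$rating), , drop = FALSE]
  answered <- rep(0L, length(ids)); names(answered) <- ids
  if (nrow(ans)) {
    atab <- tapply(paste(ans$participant_id, ans$day, ans$time),
                   ans$participant_id, function(k) length(unique(k)))
    answered[names(atab)] <- as.integer(atab)
  }
  rate <- answered[ids] / presented[ids]
  keep <- rate >= min_response_rate
  compliance <- data.frame(participant_id = ids,
                           presented = as.integer(presented[ids]),
                           answered = as.integer(answered[ids]),
                           response_rate = as.numeric(rate),
                           stringsAsFactors = FALSE)
  excluded <- compliance[!keep, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf("response rate %.3f below %.3f",
                               excluded$response_rate, min_response_rate)
  list(included = ids[keep], excluded = excluded, compliance = compliance)
}

#' Build per-item slot-grid matrices
#'
#' Averages ratings falling in the same participant-item-day-slot cell and
#' arranges them as one matrix per item with participants in rows and the 42
#' grid positions (day 1 slot 1 .. day 7 slot 6) in columns. Cells with no
#' rating are `NA`.
#'
#' @param records Long-format EMA records restricted to the analysis items.
#' @return Named list (by item) of numeric participant x 42 matrices with
#'   participant ids as row names; class `slot_grids`.
#' @export
build_slot_grids <- function(records) {
  records <- assign_slots(records)
  ids <- unique(records$participant_id)
  obs <- records[!is.na(records$rating), , drop = FALSE]
  grids <- lapply(PSYCHOTIC_ITEMS, function(it) {
    mat <- matrix(NA_real_, nrow = length(ids), ncol = N_GRID,
                  dimnames = list(ids, sprintf("s%02d", seq_len(N_GRID))))
    sub <- obs[obs$item == it, , drop = FALSE]
    if (nrow(sub)) {
      agg <- aggregate(rating ~ participant_id + grid_index, data = sub,
                       FUN = mean)
      mat[cbind(match(agg$participant_id, ids), agg$grid_index)] <- agg$rating
    }
    mat
  })
  names(grids) <- PSYCHOTIC_ITEMS
  structure(grids, class = "slot_grids")
}

#' Preprocess raw records into slot grids
#'
#' Applies item extraction, compliance filtering and slot-grid construction
#' in the order of the analysis pipeline.
#'
#' @inheritParams filter_compliance
#' @return List with `grids` (a [build_slot_grids()] result on retained
#'   participants), `included`, `excluded` and `compliance`.
#' @export
preprocess_records <- function(records, presented = NULL,
                               min_response_rate = 1 / 3) {
  records <- extract_psychotic_items(records)
  comp <- filter_compliance(records, presented, min_response_rate)
  kept <- records[records$participant_id %in% comp$included, , drop = FALSE]
  list(grids = build_slot_grids(kept), included = comp$included,
       excluded = comp$excluded, compliance = comp$compliance)
}
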