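#' Specify a synthetic EMA cohort
#'
#' Defines the composition of a simulated cohort pooled over two momentary
#' assessment designs: healthy controls (HC), healthy first-degree relatives
#' of individuals with psychosis (RE) and outpatients with a psychotic
#' disorder (PD). A latent high-symptom class is planted with a different
#' prevalence in PD than in the other groups, mirroring the concentration of
#' high-symptom individuals among patients.
#'
#' @param n_hc,n_re,n_pd Number of participants per study group.
#' @param high_frac_pd Probability that a PD participant belongs to the latent
#'   high-symptom class. Default 0.22 (roughly 12 of 55).
#' @param high_frac_other Same probability for HC and RE. Default 0.07
#'   (roughly 3 of 45).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_hc = 25L, n_re = 20L, n_pd = 55L,
                        high_frac_pd = 0.22, high_frac_other = 0.07,
                        seed) {
  stopifnot(n_hc >= 0, n_re >= 0, n_pd >= 0)
  if (n_hc + n_re + n_pd < 2) stop("empty cohort: need at least 2 participants")
  stopifnot(high_frac_pd >= 0, high_frac_pd <= 1,
            high_frac_other >= 0, high_frac_other <= 1)
  if (missing(seed)) stop("seed is mandatory")
  structure(list(n_hc = as.integer(n_hc), n_re = as.integer(n_re),
                 n_pd = as.integer(n_pd),
                 high_frac_pd = high_frac_pd,
                 high_frac_other = high_frac_other,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a participant table with latent class labels
#'
#' Draws the latent symptom class of every participant and assigns each to one
#' of the two emulated sampling designs: HC and RE belong to design A
#' (08:00-22:30, up to 10 beeps/day); PD are split between design A and
#' design B (10:00-22:00, up to 6 beeps/day) in roughly the 29:26 proportion
#' of the pooled samples.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with columns `participant_id`, `study` ("A"/"B"),
#'   `group` ("HC"/"RE"/"PD") and `latent_class` ("low"/"high").
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_hc + spec$n_re + spec$n_pd
  if (n < 1) stop("empty cohort")
  group <- rep(c("HC", "RE", "PD"), c(spec$n_hc, spec$n_re, spec$n_pd))
  study <- rep("A", n)
  if (spec$n_pd > 0) {
    n_pd_b <- spec$n_pd - round(spec$n_pd * 29 / 55)
    if (n_pd_b > 0)
      study[group == "PD"][seq(spec$n_pd - n_pd_b + 1L, spec$n_pd)] <- "B"
  }
  set.seed(spec$seed)
  p_high <- ifelse(group == "PD", spec$high_frac_pd, spec$high_frac_other)
  latent <- ifelse(rbinom(n, 1L, p_high) == 1L, "high", "low")
  data.frame(participant_id = sprintf("S%03d", seq_len(n)),
             study = study, group = group, latent_class = latent,
             stringsAsFactors = FALSE)
}

#' Generate a pseudo-random beep schedule
#'
#' Draws beep times uniformly within the design's daily sampling window
#' subject to a minimum 30-minute gap between consecutive beeps, for a block
#' of consecutive study days.
#'
#' @param design "A" (08:00-22:30, at most 10 beeps/day) or "B"
#'   (10:00-22:00, at most 6 beeps/day).
#' @param n_days Number of days (default 7).
#' @param beeps_per_day Beeps per day; must not exceed the design cap.
#' @param seed Integer seed.
#' @return A data frame with columns `day` (1..n_days) and `time` ("HH:MM"),
#'   with attribute `design`.
#' @export
generate_schedule <- function(design = c("A", "B"), n_days = 7L,
                              beeps_per_day, seed) {
  design <- match.arg(design)
  win <- DESIGN_WINDOWS[[design]]
  if (beeps_per_day > win$max_beeps)
    stop(sprintf("design %s allows at most %d beeps/day", design, win$max_beeps))
  stopifnot(beeps_per_day >= 1, n_days >= 1)
  gap <- 30L
  span <- win$end - win$start - gap * (beeps_per_day - 1L)
  if (span < 0) stop("window too short for the requested beeps at 30-min gaps")
  set.seed(seed)
  out <- lapply(seq_len(n_days), function(d) {
    u <- sort(runif(beeps_per_day, 0, span))
    tm <- win$start + round(u) + gap * (seq_len(beeps_per_day) - 1L)
    data.frame(day = d, time = min_to_hhmm(as.integer(tm)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "design") <- design
  res
}

#' Trajectory model parameters for synthetic EMA ratings
#'
#' The latent symptom level of participant follows a stationary AR(1) process
#' over the beep sequence around a class-specific mean; item ratings are an
#' ordinal readout of the positive part of the latent level. Whole-beep
#' ("compliance") or per-item (MCAR) missingness is applied afterwards.
#'
#' Defaults describe a well-separated two-class cohort: a latent gap of 3
#' units, innovation noise 0.5, and 30% missing records.
#'
#' @param mean_low,mean_high Latent class means; `mean_high > mean_low`.
#' @param ar1 AR(1) coefficient in `[0, 1)`.
#' @param loadings Positive loading per item (length 5) mapping the latent
#'   level to the 1-7 rating scale.
#' @param noise_sd Innovation standard deviation, > 0 unless exactly 0 for
#'   noiseless checks.
#' @param missing_rate Proportion of records (or beeps) removed, in `[0, 1)`.
#' @param missing_mechanism "compliance" drops whole beeps (all 5 items),
#'   "MCAR" drops single item records.
#' @return An object of class `trajectory_params`.
#' @export
trajectory_params <- function(mean_low = 0, mean_high = 3, ar1 = 0.6,
                              loadings = c(voices = 0.8, see_things = 0.7,
                                           dislike = 1.1, suspicious = 1.2,
                                           harm = 1.0),
                              noise_sd = 0.5, missing_rate = 0.3,
                              missing_mechanism = c("compliance", "MCAR")) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(mean_high > mean_low, ar1 >= 0, ar1 < 1,
            length(loadings) == length(PSYCHOTIC_ITEMS), all(loadings > 0),
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1)
  names(loadings) <- PSYCHOTIC_ITEMS
  structure(list(mean_low = mean_low, mean_high = mean_high, ar1 = ar1,
                 loadings = loadings, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism),
            class = "trajectory_params")
}

#' Simulate long-format EMA records for a cohort
#'
#' For each participant, a latent trajectory
#' `z_t = mu + ar1 * (z_{t-1} - mu) + e_t` is evolved over that participant's
#' beeps (`mu` the latent class mean, `e_t` Gaussian innovations) and each of
#' the five psychotic-symptom items is rated as
#' `clamp(round(1 + loading * max(z_t, 0)), 1, 7)`. Missingness then blanks
#' ratings at `missing_rate`, either record-wise (MCAR) or beep-wise
#' (compliance). Blanked records are retained with `rating = NA`, so the
#' presented beep schedule stays recoverable from the table.
#'
#' @param cohort Participant table from [generate_cohort()].
#' @param schedules Named list (by participant id) of schedules from
#'   [generate_schedule()].
#' @param params A [trajectory_params()].
#' @param seed Integer seed.
#' @return Long-format data frame: `participant_id`, `study`, `group`, `day`,
#'   `time`, `item`, `rating` (integer 1-7 or NA).
#' @export
generate_ema_records <- function(cohort, schedules, params, seed) {
  stopifnot(inherits(params, "trajectory_params"))
  missing_sched <- setdiff(cohort$participant_id, names(schedules))
  if (length(missing_sched))
    stop("missing schedule for participant(s): ",
         paste(missing_sched, collapse = ", "))
  set.seed(seed)
  items <- PSYCHOTIC_ITEMS
  k <- length(items)
  res <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sch <- schedules[[cohort$participant_id[i]]]
    nb <- nrow(sch)
    mu <- if (cohort$latent_class[i] == "high") params$mean_high else params$mean_low
    z <- numeric(nb)
    z[1] <- mu + rnorm(1, 0, params$noise_sd)
    if (nb > 1)
      for (t in 2:nb)
        z[t] <- mu + params$ar1 * (z[t - 1] - mu) + rnorm(1, 0, params$noise_sd)
    rating <- as.integer(pmin(pmax(round(
      1 + rep(params$loadings, nb) * pmax(rep(z, each = k), 0)), 1), 7))
    if (params$missing_rate > 0) {
      if (params$missing_mechanism == "compliance") {
        drop_beep <- runif(nb) < params$missing_rate
        rating[rep(drop_beep, each = k)] <- NA_integer_
      } else {
        rating[runif(nb * k) < params$missing_rate] <- NA_integer_
      }
    }
    res[[i]] <- data.frame(participant_id = cohort$participant_id[i],
                           study = cohort$study[i], group = cohort$group[i],
                           day = rep(sch$day, each = k),
                           time = rep(sch$time, each = k),
                           item = rep(items, nb),
                           rating = rating, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Simulate a full synthetic EMA cohort in one call
#'
#' Convenience wrapper: draws the cohort table, one beep schedule per
#' participant (design A participants get 10 beeps/day, design B 6), and the
#' long-format records.
#'
#' @param spec A [cohort_spec()].
#' @param params A [trajectory_params()].
#' @return List with elements `cohort`, `schedules` and `records`.
#' @export
simulate_ema_cohort <- function(spec, params = trajectory_params()) {
  cohort <- generate_cohort(spec)
  schedules <- vector("list", nrow(cohort))
  names(schedules) <- cohort$participant_id
  for (i in seq_len(nrow(cohort))) {
    des <- cohort$study[i]
    schedules[[i]] <- generate_schedule(
      design = des, n_days = N_DAYS,
      beeps_per_day = DESIGN_WINDOWS[[des]]$max_beeps,
      seed = derive_seed(spec$seed, 1L) + i)
  }
  records <- generate_ema_records(cohort, schedules, params,
                                  seed = derive_seed(spec$seed, 2L))
  list(cohort = cohort, schedules = schedules, records = records)
}
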