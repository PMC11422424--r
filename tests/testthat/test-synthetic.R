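test_that("cohort generation respects class fractions and determinism", {
  # zero fractions force the low class everywhere
  co <- generate_cohort(cohort_spec(25, 20, 55, 0, 0, seed = 1))
  expect_equal(nrow(co), 100)
  expect_true(all(co$latent_class == "low"))
  expect_equal(as.vector(table(co$group)[c("HC", "RE", "PD")]), c(25, 20, 55))

  # fraction 1 forces the high class in PD
  co2 <- generate_cohort(cohort_spec(0, 0, 10, 1.0, 0, seed = 1))
  expect_equal(nrow(co2), 10)
  expect_true(all(co2$latent_class == "high"))

  # byte-identical under the same seed
  expect_identical(generate_cohort(cohort_spec(10, 5, 10, 0.3, 0.1, seed = 7)),
                   generate_cohort(cohort_spec(10, 5, 10, 0.3, 0.1, seed = 7)))

  expect_error(cohort_spec(0, 0, 0, seed = 1), "empty cohort")
  expect_error(cohort_spec(10, 0, 10, 0.5, 0.1), "seed")
})

test_that("high-class counts follow the binomial oracle over many seeds", {
  # expected count 0.25*55 + 0.02*45 = 14.65; check the mean over 1000
  # seeds against the binomial 99% bound on the mean
  counts <- vapply(1:1000, function(s)
    sum(generate_cohort(cohort_spec(25, 20, 55, 0.25, 0.02,
                                    seed = s))$latent_class == "high"), 0)
  expected <- 0.25 * 55 + 0.02 * 45
  se_mean <- sqrt(55 * 0.25 * 0.75 + 45 * 0.02 * 0.98) / sqrt(1000)
  expect_lt(abs(mean(counts) - expected), qnorm(0.995) * se_mean)
})

test_that("schedules respect design windows, caps and the 30-min gap", {
  sb <- generate_schedule("B", 7, 6, seed = 3)
  expect_equal(nrow(sb), 42)
  mins <- emadtw:::hhmm_to_min(sb$time)
  expect_true(all(mins >= 600 & mins <= 1320))
  sa <- generate_schedule("A", 7, 10, seed = 3)
  expect_equal(nrow(sa), 70)
  amins <- emadtw:::hhmm_to_min(sa$time)
  expect_true(all(amins >= 480 & amins <= 1350))
  for (d in 1:7) {
    dm <- amins[sa$day == d]
    expect_true(all(diff(dm) >= 30))
  }
  expect_identical(generate_schedule("A", 7, 10, seed = 3), sa)
  expect_error(generate_schedule("B", 7, 7, seed = 1), "at most")
})

test_that("noiseless low-class records sit on the rating floor and counts conserve", {
  co <- generate_cohort(cohort_spec(3, 0, 0, 0, 0, seed = 2))
  sch <- lapply(co$participant_id, function(id)
    generate_schedule("B", 7, 6, seed = 5))
  names(sch) <- co$participant_id
  pars <- trajectory_params(mean_low = 0, mean_high = 1, ar1 = 0,
                            loadings = rep(1, 5), noise_sd = 0,
                            missing_rate = 0)
  rec <- generate_ema_records(co, sch, pars, seed = 9)
  expect_true(all(rec$rating == 1L))
  # conservation: beeps x 5 items
  expect_equal(nrow(rec), 3 * 42 * 5)
  expect_error(generate_ema_records(co, sch[-1], pars, seed = 9),
               "missing schedule")
})

test_that("programmed class gap appears in the composite and missingness is calibrated", {
  spec <- cohort_spec(0, 0, 200, 0.5, 0, seed = 21)
  co <- generate_cohort(spec)
  sch <- lapply(co$participant_id, function(id) generate_schedule("B", 7, 6, seed = 4))
  names(sch) <- co$participant_id
  pars <- trajectory_params(mean_low = 0, mean_high = 3, ar1 = 0.5,
                            loadings = rep(1, 5), noise_sd = 0.2,
                            missing_rate = 0)
  rec <- generate_ema_records(co, sch, pars, seed = 22)
  comp <- tapply(rec$rating, rec$participant_id, mean)
  gap_obs <- mean(comp[co$participant_id[co$latent_class == "high"]]) -
             mean(comp[co$participant_id[co$latent_class == "low"]])
  # programmed gap on the rating scale: high ~ clamp(1 + z), z ~ 3 -> ~3 above
  # the floor at 1; allow Monte-Carlo and discretization slack
  expect_gt(gap_obs, 2.4)
  expect_lt(gap_obs, 3.6)

  # marginal calibration of MCAR missingness: within 3 binomial SE
  pars_m <- trajectory_params(missing_rate = 0.3, missing_mechanism = "MCAR")
  rec_m <- generate_ema_records(co[1:20, ], sch[co$participant_id[1:20]],
                                pars_m, seed = 23)
  n <- nrow(rec_m)
  expect_gt(n, 1000)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(is.na(rec_m$rating)) - 0.3), 3 * se)

  # compliance missingness drops whole beeps: per-beep item NA counts are 0 or 5
  pars_c <- trajectory_params(missing_rate = 0.3, missing_mechanism = "compliance")
  rec_c <- generate_ema_records(co[1:20, ], sch[co$participant_id[1:20]],
                                pars_c, seed = 24)
  per_beep <- tapply(is.na(rec_c$rating),
                     paste(rec_c$participant_id, rec_c$day, rec_c$time), sum)
  expect_true(all(per_beep %in% c(0L, 5L)))
})

test_that("simulated cohorts are reproducible end to end", {
  s1 <- simulate_ema_cohort(cohort_spec(5, 0, 5, 0.5, 0, seed = 31))
  s2 <- simulate_ema_cohort(cohort_spec(5, 0, 5, 0.5, 0, seed = 31))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$cohort, s2$cohort)
})
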