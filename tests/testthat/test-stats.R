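test_that("trajectory summaries give the mean and mean-corrected variance", {
  s <- summarize_trajectory(rep(4, 42))
  expect_equal(s$mean_rating, 4)
  expect_equal(s$corrected_variance, 0)
  # alternating 1, 3 over 42 slots: mean 2, s^2 = 42/41, corrected half that
  s2 <- summarize_trajectory(rep(c(1, 3), 21))
  expect_equal(s2$mean_rating, 2)
  expect_equal(s2$corrected_variance, (42 / 41) / 2)
  # arbitrary series matches a direct two-pass computation
  x <- rep(1:7, 6)
  s3 <- summarize_trajectory(x)
  expect_equal(s3$corrected_variance,
               sum((x - mean(x))^2) / (length(x) - 1) / mean(x))
})

test_that("Welch t matches the reference implementation to 1e-10", {
  set.seed(61)
  for (trial in 1:25) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    mine <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$ci, as.numeric(ref$conf.int), tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1
  z <- c(1, 2, 3, 4)
  expect_equal(welch_t(z, z)$statistic, 0)
  expect_equal(welch_t(z, z)$p, 1)
  expect_error(welch_t(1, z), "n >= 2")
})

test_that("Welch from summary statistics reproduces published group contrasts", {
  # group summaries n/mean/sd 12/20.3/4.3 vs 43/13.8/5.1
  res <- welch_t_summary(12, 20.3, 4.3, 43, 13.8, 5.1)
  expect_equal(round(res$statistic, 2), 4.44)
  # reduces to the pooled t when variances and sizes are equal
  set.seed(71)
  a <- rnorm(10)
  b <- rnorm(10)
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b)   # force sd(b) == sd(a)
  pooled <- t.test(a, b, var.equal = TRUE)
  m <- welch_t(a, b)
  expect_equal(m$statistic, unname(pooled$statistic), tolerance = 1e-10)
  expect_equal(m$df, 18)  # equal n and sd: Satterthwaite df = n1 + n2 - 2
})

test_that("one-way ANOVA matches aov and its algebraic identities", {
  set.seed(62)
  for (trial in 1:15) {
    g <- factor(sample(letters[1:3], 40, replace = TRUE))
    y <- rnorm(40) + as.integer(g) * 0.3
    mine <- oneway_anova(y, g)
    ref <- anova(aov(y ~ g))
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(c(mine$df1, mine$df2), ref$Df)
  }
  # two groups: F equals the square of the pooled t
  y2 <- rnorm(30); g2 <- rep(c("a", "b"), 15)
  tt <- t.test(y2 ~ g2, var.equal = TRUE)
  expect_equal(oneway_anova(y2, g2)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
  # equal group means with zero spread: F defined as 0
  expect_equal(oneway_anova(rep(2, 9), rep(letters[1:3], 3))$statistic, 0)
})

test_that("ANOVA from summary statistics reproduces the published age contrast", {
  res <- oneway_anova_summary(c(25, 55, 20), c(36.4, 39.9, 37.2),
                              c(8.2, 10.3, 14.7))
  expect_equal(round(res$statistic, 2), 1.07)
  expect_equal(c(res$df1, res$df2), c(2, 97))
})

test_that("Pearson chi-square has no continuity correction and matches the closed form", {
  tab <- matrix(c(12, 5, 9, 14), 2, 2)
  mine <- pearson_chi2(tab)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  # 2x2 closed form N(ad - bc)^2 / (row and column margin product)
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  closed <- sum(tab) * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(mine$statistic, closed, tolerance = 1e-10)
  expect_error(pearson_chi2(matrix(c(1, 2), 1)), "2x2")
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("BH adjustment equals p.adjust exactly and is monotone", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(63)
  for (trial in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_identical(q, p.adjust(p, method = "BH"))
    expect_true(all(q >= p - 1e-15 & q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cluster characterization dispatches tests and keeps families separate", {
  set.seed(64)
  n <- 60
  ids <- sprintf("S%02d", 1:n)
  assignment <- setNames(rep(1:2, each = n / 2), ids)
  dat <- data.frame(participant_id = ids,
                    age = rnorm(n, 40, 10),
                    sex = sample(c("f", "m"), n, replace = TRUE),
                    mean_rating = rnorm(n, 2, 0.5) + (assignment - 1) * 2,
                    panss = rnorm(n, 15, 5),
                    stringsAsFactors = FALSE)
  fams <- c(age = "demographics", sex = "demographics",
            mean_rating = "cluster_characterization", panss = "clinical")
  res <- characterize_clusters(assignment, dat, families = fams,
                               subset_by = list(panss = ids[31:60]))
  cmp <- res$comparisons
  expect_setequal(cmp$variable, c("age", "sex", "mean_rating"))
  # panss restricted to one cluster's participants -> single level, skipped
  expect_true("panss" %in% res$skipped)
  expect_equal(cmp$test[cmp$variable == "sex"], "chi2")
  expect_equal(cmp$test[cmp$variable == "age"], "welch_t")
  # FDR within family: singleton families keep p unchanged
  expect_equal(cmp$p_fdr[cmp$variable == "mean_rating"],
               cmp$p[cmp$variable == "mean_rating"])
  # the planted rating gap survives correction
  expect_lt(cmp$p_fdr[cmp$variable == "mean_rating"], 0.05)
  expect_true(all(cmp$p_fdr >= cmp$p - 1e-15))
})

test_that("null clusters produce uniform-looking corrected p-values", {
  set.seed(65)
  n <- 40
  ids <- sprintf("S%02d", 1:n)
  assignment <- setNames(rep(1:2, each = n / 2), ids)
  dat <- data.frame(participant_id = ids, v1 = rnorm(n), v2 = rnorm(n),
                    v3 = rnorm(n), stringsAsFactors = FALSE)
  res <- characterize_clusters(assignment, dat,
                               families = c(v1 = "a", v2 = "a", v3 = "a"))
  expect_true(all(res$comparisons$p_fdr >= res$comparisons$p))
})

test_that("clusters that are exact copies yield no survivals", {
  set.seed(66)
  n <- 40
  ids <- sprintf("S%02d", 1:n)
  assignment <- setNames(rep(1:2, each = n / 2), ids)
  half <- data.frame(v1 = rnorm(n / 2), v2 = rnorm(n / 2),
                     sex = sample(c("f", "m"), n / 2, replace = TRUE),
                     stringsAsFactors = FALSE)
  dat <- cbind(data.frame(participant_id = ids, stringsAsFactors = FALSE),
               rbind(half, half))
  res <- characterize_clusters(assignment, dat,
                               families = c(v1 = "a", v2 = "a", sex = "a"))
  # continuous copies: t = 0, p = 1; categorical copies: X^2 = 0, p = 1
  expect_true(all(res$comparisons$p == 1))
  expect_true(all(res$comparisons$p_fdr == 1))
})
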