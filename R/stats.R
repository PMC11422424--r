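#' Per-participant trajectory summaries
#'
#' The two characterization features of a composite trajectory: the mean
#' rating across the 42 slots and the corrected rating variance — the sample
#' variance (n - 1 denominator) divided by the mean rating, a
#' mean-standardized measure of within-person temporal variability. On the
#' 1-7 scale the mean is at least 1, so the ratio is always defined.
#'
#' @param traj Numeric vector (one trajectory) or participant x slot matrix.
#' @return Data frame with `participant_id`, `mean_rating`,
#'   `corrected_variance`.
#' @export
summarize_trajectory <- function(traj) {
  if (is.null(dim(traj))) traj <- matrix(traj, nrow = 1)
  m <- rowMeans(traj)
  v <- apply(traj, 1, var)
  data.frame(participant_id = rownames(traj) %||% as.character(seq_len(nrow(traj))),
             mean_rating = as.numeric(m),
             corrected_variance = as.numeric(v / m),
             stringsAsFactors = FALSE)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a 95% confidence interval for the mean difference. `welch_t()` takes
#' raw samples; `welch_t_summary()` takes the group sizes, means and standard
#' deviations, so comparisons printed in publication tables can be recomputed
#' without raw data.
#'
#' @param a,b Numeric samples, each of size at least 2.
#' @return List: `statistic`, `df`, `p`, `ci` (length 2), `estimate` (mean
#'   difference a - b).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  welch_t_summary(length(a), mean(a), sd(a), length(b), mean(b), sd(b))
}

#' @rdname welch_t
#' @param n1,m1,s1,n2,m2,s2 Sizes, means and standard deviations of the two
#'   groups.
#' @export
welch_t_summary <- function(n1, m1, s1, n2, m2, s2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  va <- s1^2 / n1
  vb <- s2^2 / n2
  if (va + vb == 0) stop("both groups have zero variance")
  se <- sqrt(va + vb)
  t <- (m1 - m2) / se
  df <- (va + vb)^2 / (va^2 / (n1 - 1) + vb^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  ci <- (m1 - m2) + c(-1, 1) * qt(0.975, df) * se
  list(statistic = t, df = df, p = p, ci = ci, estimate = m1 - m2)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition; `oneway_anova()` takes raw values
#' and group labels, `oneway_anova_summary()` group sizes, means and standard
#' deviations. When the group means are all equal and the within-group
#' variance is zero, F is defined as 0.
#'
#' @param values Numeric vector.
#' @param groups Group labels, at least two groups.
#' @return List: `statistic` (F), `df1`, `df2`, `p`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  ns <- tapply(values, groups, length)
  if (any(is.na(ns))) {
    groups <- droplevels(groups)
    ns <- tapply(values, groups, length)
  }
  oneway_anova_summary(as.integer(ns),
                       as.numeric(tapply(values, groups, mean)),
                       as.numeric(tapply(values, groups,
                                         function(x) if (length(x) > 1) sd(x) else 0)))
}

#' @rdname oneway_anova
#' @param ns,means,sds Per-group sizes, means and standard deviations.
#' @export
oneway_anova_summary <- function(ns, means, sds) {
  g <- length(ns)
  if (g < 2) stop("need at least 2 groups")
  n <- sum(ns)
  if (n <= g) stop("need total n > number of groups")
  gm <- sum(ns * means) / n
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- g - 1
  df2 <- n - g
  msb <- ssb / df1
  msw <- ssw / df2
  f <- if (msw == 0) {
    if (msb == 0) 0 else Inf
  } else msb / msw
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  list(statistic = f, df1 = df1, df2 = df2, p = p)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the margins,
#' `df = (r - 1)(c - 1)`, no continuity correction (the convention under
#' which the published 2x2 tables reproduce exactly).
#'
#' @param tab Count matrix, at least 2x2, no zero row/column margin.
#' @return List: `statistic`, `df`, `p`, `expected`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2x2 table")
  if (any(tab < 0)) stop("counts must be nonnegative")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  expected <- outer(rs, cs) / sum(tab)
  x2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = x2, df = df,
       p = pchisq(x2, df, lower.tail = FALSE), expected = expected)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  q <- m / seq_len(m) * p[o]
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Characterize clusters against participant-level variables
#'
#' Compares each variable between the clusters: continuous variables with a
#' Welch t-test (two clusters) or one-way ANOVA (more), categorical variables
#' with a Pearson chi-square on the variable x cluster table. P-values are
#' FDR-adjusted separately within each variable family (e.g. demographics,
#' cluster characterization, clinical instruments — families are never
#' pooled). For ANOVA main effects surviving the FDR threshold, post-hoc
#' pairwise Welch t-tests are run with their own FDR adjustment across the
#' cluster pairs of that variable.
#'
#' @param assignment Named integer cluster labels (names = participant ids).
#' @param data Data frame with a `participant_id` column and the variables to
#'   compare; numeric columns are treated as continuous, everything else as
#'   categorical.
#' @param families Named character vector mapping variable names to family
#'   labels; variables absent from it go to family "other".
#' @param subset_by Optional named logical vector (by participant id)
#'   restricting specific variables to a subset of participants, given as a
#'   list `variable -> participant ids` (e.g. instrument scores assessed only
#'   in patients).
#' @param alpha FDR threshold used to trigger post-hoc tests (default 0.05).
#' @return List: `comparisons` (data frame: variable, family, test,
#'   statistic, df, p, p_fdr), `posthoc` (pairwise tests, possibly empty) and
#'   `skipped` (variables with a single level).
#' @export
characterize_clusters <- function(assignment, data, families = NULL,
                                  subset_by = NULL, alpha = 0.05) {
  stopifnot(!is.null(names(assignment)), "participant_id" %in% names(data))
  data <- data[data$participant_id %in% names(assignment), , drop = FALSE]
  cl <- assignment[data$participant_id]
  vars <- setdiff(names(data), "participant_id")
  rows <- list()
  skipped <- character(0)
  for (v in vars) {
    x <- data[[v]]
    keep <- !is.na(x)
    if (!is.null(subset_by) && v %in% names(subset_by))
      keep <- keep & data$participant_id %in% subset_by[[v]]
    xv <- x[keep]
    cv <- cl[keep]
    fam <- if (!is.null(families) && v %in% names(families)) families[[v]] else "other"
    if (length(unique(xv)) < 2 || length(unique(cv)) < 2) {
      skipped <- c(skipped, v)
      next
    }
    if (is.numeric(x)) {
      if (length(unique(cv)) == 2) {
        ab <- split(xv, cv)
        res <- welch_t(ab[[1]], ab[[2]])
        rows[[v]] <- data.frame(variable = v, family = fam, test = "welch_t",
                                statistic = res$statistic, df = res$df,
                                p = res$p, stringsAsFactors = FALSE)
      } else {
        res <- oneway_anova(xv, cv)
        rows[[v]] <- data.frame(variable = v, family = fam, test = "anova",
                                statistic = res$statistic, df = res$df1,
                                p = res$p, stringsAsFactors = FALSE)
      }
    } else {
      tab <- table(xv, cv)
      res <- pearson_chi2(tab)
      rows[[v]] <- data.frame(variable = v, family = fam, test = "chi2",
                              statistic = res$statistic, df = res$df,
                              p = res$p, stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, rows)
  posthoc <- NULL
  if (!is.null(comparisons)) {
    rownames(comparisons) <- NULL
    comparisons$p_fdr <- NA_real_
    for (fam in unique(comparisons$family)) {
      idx <- comparisons$family == fam
      comparisons$p_fdr[idx] <- bh_fdr(comparisons$p[idx])
    }
    ph <- list()
    surv <- comparisons$variable[comparisons$test == "anova" &
                                 comparisons$p_fdr < alpha]
    for (v in surv) {
      x <- data[[v]]
      keep <- !is.na(x)
      if (!is.null(subset_by) && v %in% names(subset_by))
        keep <- keep & data$participant_id %in% subset_by[[v]]
      sp <- split(x[keep], cl[keep])
      prs <- utils::combn(names(sp), 2)
      pv <- apply(prs, 2, function(pr) {
        r <- welch_t(sp[[pr[1]]], sp[[pr[2]]])
        c(r$statistic, r$p)
      })
      ph[[v]] <- data.frame(variable = v,
                            cluster_a = prs[1, ], cluster_b = prs[2, ],
                            statistic = pv[1, ], p = pv[2, ],
                            p_fdr = bh_fdr(pv[2, ]), stringsAsFactors = FALSE)
    }
    if (length(ph)) posthoc <- do.call(rbind, ph)
  }
  list(comparisons = comparisons, posthoc = posthoc, skipped = skipped)
}
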