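#' Pearson chi-square test of independence
#'
#' Plain Pearson X^2 on an r x c contingency table, no continuity
#' correction, df = (r-1)(c-1).
#'
#' @param tab matrix of non-negative counts, at least 2 x 2.
#' @return list of class `TestResult`: `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop_invalid("table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_invalid("table must contain non-negative integer counts")
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop_degenerate("zero marginal in table")
  expected <- outer(rs, cs) / sum(tab)
  x2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  test_result("chi-square", x2, df, pchisq(x2, df, lower.tail = FALSE),
              expected = expected)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 df.
#'
#' @param groups list of numeric vectors, each non-empty.
#' @return `TestResult` with `statistic` (H), `df`, `p`, and `mean_ranks`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop_invalid("need >= 2 groups")
  if (any(vapply(groups, length, 1L) == 0L)) stop_invalid("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(x)
  if (length(unique(x)) == 1L) stop_degenerate("all values tied across groups")
  r <- rank(x)
  rsum <- tapply(r, g, sum)
  ni <- tabulate(g)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / ni) - 3 * (n + 1)
  ties <- table(x)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  df <- length(groups) - 1L
  res <- test_result("Kruskal-Wallis", h, df, pchisq(h, df, lower.tail = FALSE))
  res$mean_ranks <- as.numeric(rsum / ni)
  res
}

#' Dunn's post-hoc comparisons after Kruskal-Wallis
#'
#' z tests on pooled mean-rank differences with the tie-corrected variance,
#' Bonferroni-adjusted over the requested comparisons only.
#'
#' @param groups list of numeric vectors.
#' @param comparisons two-column matrix (or list of pairs) of group indices;
#'   default all pairs.
#' @return data.frame: `i`, `j`, `mean_rank_diff`, `z`, `p`, `p_adj`.
#' @export
dunns_posthoc <- function(groups, comparisons = NULL) {
  if (!is.list(groups) || length(groups) < 2L) stop_invalid("need >= 2 groups")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(x)
  r <- rank(x)
  mr <- tapply(r, g, mean)
  ni <- tabulate(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  if (is.null(comparisons)) {
    comparisons <- t(combn(length(groups), 2))
  } else if (is.list(comparisons)) {
    comparisons <- do.call(rbind, comparisons)
  }
  k <- nrow(comparisons)
  out <- data.frame(i = comparisons[, 1], j = comparisons[, 2])
  out$mean_rank_diff <- mr[out$i] - mr[out$j]
  se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[out$i] + 1 / ni[out$j]))
  out$z <- out$mean_rank_diff / se
  out$p <- 2 * pnorm(-abs(out$z))
  out$p_adj <- pmin(1, out$p * k)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Reports U on the `min(U1, U2)` convention. The p-value is exact (no-ties
#' null distribution) when both samples have at most 25 observations and
#' there are no ties; otherwise a normal approximation with tie correction
#' is used. Two-tailed.
#'
#' @param x,y numeric samples.
#' @return `TestResult` with `statistic` (U), `df = NA`, `p`, `exact` flag.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop_invalid("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && n1 <= 25 && n2 <= 25) {
    p <- min(1, 2 * pwilcox(u, n1, n2))
    exact <- TRUE
  } else {
    ties <- table(c(x, y))
    n <- n1 + n2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
    z <- (u - n1 * n2 / 2) / sigma
    p <- min(1, 2 * pnorm(z)) # u <= mean by construction
    exact <- FALSE
  }
  res <- test_result("Mann-Whitney U", u, NA, p)
  res$exact <- exact
  res
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' W is the smaller of the positive- and negative-rank sums over the nonzero
#' differences. Exact p (no ties in |d|) for at most 25 nonzero pairs,
#' normal approximation otherwise. All-zero differences give W = 0, p = 1,
#' flagged `degenerate`.
#'
#' @param d numeric vector of paired differences.
#' @return `TestResult` with `statistic` (W), `p`, `exact`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(d) {
  if (length(d) == 0L) stop_invalid("empty input")
  d <- d[d != 0]
  if (length(d) == 0L) {
    res <- test_result("Wilcoxon signed-rank", 0, NA, 1)
    res$degenerate <- TRUE
    return(res)
  }
  n <- length(d)
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  wneg <- sum(r[d < 0])
  w <- min(wpos, wneg)
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= 25) {
    p <- min(1, 2 * psignrank(w, n))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    p <- min(1, 2 * pnorm((w - mu) / sigma))
    exact <- FALSE
  }
  res <- test_result("Wilcoxon signed-rank", w, NA, p)
  res$exact <- exact
  res$degenerate <- FALSE
  res
}

#' Student t tests (two-sample pooled, paired, one-sample)
#'
#' @param x,y numeric samples (`y` omitted for the one-sample test).
#' @param paired paired test on `x - y`.
#' @param mu null value for the one-sample/paired mean.
#' @return `TestResult` with `statistic` (t), `df`, `p`, `estimate`.
#' @export
t_test <- function(x, y = NULL, paired = FALSE, mu = 0) {
  if (length(x) < 2L) stop_invalid("need >= 2 observations")
  if (paired) {
    if (is.null(y) || length(y) != length(x)) stop_invalid("paired test needs equal-length y")
    x <- x - y
    y <- NULL
  }
  if (is.null(y)) {
    n <- length(x)
    t <- (mean(x) - mu) / (sd(x) / sqrt(n))
    df <- n - 1
    est <- mean(x)
  } else {
    n1 <- length(x); n2 <- length(y)
    if (n2 < 2L) stop_invalid("need >= 2 observations per group")
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    est <- mean(x) - mean(y)
  }
  res <- test_result("t", t, df, 2 * pt(-abs(t), df))
  res$estimate <- est
  res
}

#' Two-way mixed (repeated-measures) ANOVA
#'
#' Classical pooled-error mixed ANOVA for a balanced design with one
#' between-subjects factor (`group`) and one within-subjects factor
#' (`epoch`), no sphericity correction: the between-group F uses the
#' subject-within-group mean square as error; the within factor and the
#' interaction use the residual (subject x epoch) mean square.
#'
#' @param data data.frame with columns `subject`, `group`, `epoch`, `value`;
#'   every subject must appear once per epoch and belong to one group, with
#'   equal group sizes.
#' @return list of `TestResult` for `group`, `epoch`, `interaction`.
#' @export
rm_anova_two_way <- function(data) {
  req <- c("subject", "group", "epoch", "value")
  if (!all(req %in% names(data))) {
    stop_invalid("data must have columns ", paste(req, collapse = ", "))
  }
  data$subject <- as.factor(data$subject)
  data$group <- as.factor(data$group)
  data$epoch <- as.factor(data$epoch)
  a <- nlevels(data$group); m <- nlevels(data$epoch)
  subj_group <- unique(data[, c("subject", "group")])
  if (anyDuplicated(subj_group$subject)) {
    stop_invalid("unsupported design: a subject appears in more than one group")
  }
  n_per <- table(subj_group$group)
  if (length(unique(as.integer(n_per))) != 1L) {
    stop_invalid("unsupported design: unequal group sizes")
  }
  cell <- table(data$subject, data$epoch)
  if (any(cell != 1L)) {
    stop_invalid("unsupported design: each subject needs exactly one value per epoch")
  }
  s <- as.integer(n_per[1]) # subjects per group
  N <- a * s
  grand <- mean(data$value)
  subj_means <- tapply(data$value, data$subject, mean)
  group_means <- tapply(data$value, data$group, mean)
  epoch_means <- tapply(data$value, data$epoch, mean)
  cellm <- tapply(data$value, list(data$group, data$epoch), mean)

  ss_group <- s * m * sum((group_means - grand)^2)
  ss_subj <- m * sum((subj_means - grand)^2) - ss_group
  ss_epoch <- N * sum((epoch_means - grand)^2)
  ss_cells <- s * sum((cellm - grand)^2)
  ss_int <- ss_cells - ss_group - ss_epoch
  ss_tot <- sum((data$value - grand)^2)
  ss_res <- ss_tot - ss_subj - ss_cells

  df_group <- a - 1; df_subj <- N - a
  df_epoch <- m - 1; df_int <- df_group * df_epoch
  df_res <- df_subj * df_epoch

  f_group <- (ss_group / df_group) / (ss_subj / df_subj)
  f_epoch <- (ss_epoch / df_epoch) / (ss_res / df_res)
  f_int <- (ss_int / df_int) / (ss_res / df_res)
  list(
    group = test_result("F (between: group)", f_group, c(df_group, df_subj),
                        pf(f_group, df_group, df_subj, lower.tail = FALSE)),
    epoch = test_result("F (within: epoch)", f_epoch, c(df_epoch, df_res),
                        pf(f_epoch, df_epoch, df_res, lower.tail = FALSE)),
    interaction = test_result("F (group x epoch)", f_int, c(df_int, df_res),
                              pf(f_int, df_int, df_res, lower.tail = FALSE))
  )
}

#' Sidak multiple-comparison adjustment
#'
#' @param p vector of raw p-values.
#' @param k number of comparisons in the family (default `length(p)`).
#' @return adjusted p-values `1 - (1 - p)^k`.
#' @export
sidak_posthoc <- function(p, k = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("p-values must lie in [0,1]")
  pmin(1, 1 - (1 - p)^k)
}

#' Confidence interval from mean, SEM and n
#'
#' `mean +/- t(1-(1-level)/2, n-1) * sem`.
#'
#' @param mean,sem,n summary statistics (`n >= 2`, `sem > 0`).
#' @param level confidence level.
#' @return c(lo, hi).
#' @export
ci_from_mean_sem <- function(mean, sem, n, level = 0.95) {
  check_number(n, "n", 2)
  check_number(sem, "sem", 1e-300)
  tcrit <- qt(1 - (1 - level) / 2, n - 1)
  c(mean - tcrit * sem, mean + tcrit * sem)
}

#' Unpaired pooled t statistic reconstructed from two confidence intervals
#'
#' Inverts [ci_from_mean_sem()]: each group's mean is the CI midpoint and
#' its SEM the CI half-width divided by the t quantile; the pooled-variance
#' two-sample t follows with df = n1 + n2 - 2.
#'
#' @param ci1,ci2 c(lo, hi) confidence intervals.
#' @param n1,n2 group sizes.
#' @param level confidence level of the intervals.
#' @return list: `t`, `df`, `p`, `mean1`, `mean2`, `sem1`, `sem2`.
#' @export
t_from_cis <- function(ci1, n1, ci2, n2, level = 0.95) {
  for (ci in list(ci1, ci2)) {
    if (length(ci) != 2L || diff(ci) <= 0) stop_invalid("CI must be c(lo, hi) with lo < hi")
  }
  check_number(n1, "n1", 2); check_number(n2, "n2", 2)
  m1 <- mean(ci1); m2 <- mean(ci2)
  sem1 <- diff(ci1) / 2 / qt(1 - (1 - level) / 2, n1 - 1)
  sem2 <- diff(ci2) / 2 / qt(1 - (1 - level) / 2, n2 - 1)
  s12 <- sem1^2 * n1; s22 <- sem2^2 * n2
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s12 + (n2 - 1) * s22) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       mean1 = m1, mean2 = m2, sem1 = sem1, sem2 = sem2)
}

#' A-priori sample size for the between-group effect of an RM-ANOVA
#'
#' G*Power-style computation for the between-subjects effect of a
#' groups x m repeated-measures design: noncentrality
#' `lambda = f^2 * N * m / (1 + (m - 1) * rho)`, numerator df
#' `groups - 1`, denominator df `N - groups`; power is the upper tail of
#' the noncentral F beyond the central critical value at `alpha`. Returns
#' the smallest total N (constrained to a multiple of `groups` when
#' `equal_groups`) reaching the target power.
#'
#' @param f Cohen's effect size f.
#' @param alpha significance level.
#' @param power target power.
#' @param groups number of groups.
#' @param m number of repeated measurements.
#' @param rho correlation between repeated measures.
#' @param equal_groups require equal group sizes.
#' @param n_max search bound on total N.
#' @return list: `N`, `F_crit`, `power` (achieved), `lambda`, `df`.
#' @export
rm_anova_power <- function(f, alpha = 0.05, power = 0.85, groups = 2, m = 4,
                           rho = 0.5, equal_groups = TRUE, n_max = 1e6) {
  check_number(f, "f", 1e-12)
  check_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  check_number(power, "power", 1e-12, 1 - 1e-12)
  check_number(m, "m", 2)
  if (rho <= -1 || rho >= 1) stop_invalid("rho must be in (-1, 1)")
  step <- if (equal_groups) groups else 1L
  n <- groups + step - (groups %% step) # smallest admissible N with df2 >= 1
  while (n <= n_max) {
    if (n - groups >= 1) {
      lambda <- f^2 * n * m / (1 + (m - 1) * rho)
      fc <- qf(1 - alpha, groups - 1, n - groups)
      pw <- pf(fc, groups - 1, n - groups, ncp = lambda, lower.tail = FALSE)
      if (pw >= power) {
        return(list(N = n, F_crit = fc, power = pw, lambda = lambda,
                    df = c(groups - 1, n - groups)))
      }
    }
    n <- n + step
  }
  stop_invalid("target power unreachable within N <= ", n_max)
}

test_result <- function(name, statistic, df, p, ...) {
  structure(list(name = name, statistic = as.numeric(statistic), df = df,
                 p = as.numeric(p), ...),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("<TestResult> %s = %.4g, df = %s, p = %.4g\n", x$name,
              x$statistic, paste(x$df, collapse = ","), x$p))
  invisible(x)
}

#' @importFrom utils combn
NULL
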