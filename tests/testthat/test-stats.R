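test_that("chi-square independence matches the hand formula", {
  expect_equal(chi_square_independence(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chi_square_independence(rbind(c(10, 10), c(10, 10)))$df, 1)
  # identical row proportions -> 0
  expect_equal(chi_square_independence(rbind(c(2, 4, 6), c(1, 2, 3)))$statistic,
               0, tolerance = 1e-12)
  tab <- rbind(c(5, 10, 15), c(15, 10, 5))
  res <- chi_square_independence(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected))
  expect_equal(res$df, 2)
  expect_equal(res$p, pchisq(res$statistic, 2, lower.tail = FALSE))
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))),
               class = "vtsfear_degenerate_input")
})

test_that("Kruskal-Wallis and Dunn agree with rank arithmetic", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))$statistic,
               0, tolerance = 1e-12)
  g <- list(c(2.1, 3.5, 4.2), c(1.0, 1.8), c(5.5, 6.1, 7.0, 8.2))
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, oracle_kw_h(g))
  expect_equal(res$df, 2)
  # two-group KW orders consistently with Mann-Whitney on random data
  set.seed(14)
  x <- rnorm(12); y <- rnorm(15, 1)
  kw <- kruskal_wallis(list(x, y))
  mw <- mann_whitney(x, y)
  expect_equal(kw$p < 0.05, mw$p < 0.05)
  expect_error(kruskal_wallis(list(rep(1, 3), rep(1, 4))),
               class = "vtsfear_degenerate_input")
  # Dunn: z from pooled mean ranks, Bonferroni over requested comparisons
  d <- dunns_posthoc(g)
  r <- rank(unlist(g))
  mr <- tapply(r, rep(1:3, lengths(g)), mean)
  expect_equal(d$mean_rank_diff[1], unname(mr[1] - mr[2]))
  n <- length(r)
  se12 <- sqrt(n * (n + 1) / 12 * (1 / 3 + 1 / 2))
  expect_equal(d$z[1], unname(mr[1] - mr[2]) / se12)
  expect_equal(d$p_adj, pmin(1, d$p * 3))
  d1 <- dunns_posthoc(g, comparisons = rbind(c(1, 3)))
  expect_equal(d1$p_adj, d1$p) # single comparison: no adjustment
})

test_that("Mann-Whitney follows the min(U1,U2) convention with exact small-n p", {
  # identical samples -> U = n1*n2/2, p = 1
  x <- c(1.5, 2.5, 3.5)
  expect_equal(mann_whitney(x, x)$statistic, 4.5)
  expect_equal(mann_whitney(x, x)$p, 1)
  # complete separation, n1 = n2 = 3 -> U = 0, exact two-tailed p = 0.1
  res <- mann_whitney(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  expect_true(res$exact)
  # exact p matches full enumeration on random no-ties samples
  set.seed(15)
  for (r in 1:5) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1), 0.8)
    got <- mann_whitney(x, y)
    ora <- oracle_mw(x, y)
    expect_equal(got$statistic, ora$u)
    expect_equal(got$p, ora$p, tolerance = 1e-12)
  }
  # swapping the groups preserves U and p
  set.seed(16)
  a <- rnorm(8); b <- rnorm(9, 0.5)
  expect_equal(mann_whitney(a, b)$statistic, mann_whitney(b, a)$statistic)
  expect_equal(mann_whitney(a, b)$p, mann_whitney(b, a)$p)
  expect_error(mann_whitney(numeric(0), 1), class = "vtsfear_invalid_argument")
})

test_that("Wilcoxon signed-rank handles the degenerate all-zero case", {
  res0 <- wilcoxon_signed_rank(rep(0, 5))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_true(res0$degenerate)
  # complete one-sided differences: W = 0
  res <- wilcoxon_signed_rank(c(1.2, 2.4, 0.6, 3.1, 1.8))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 2 * psignrank(0, 5))
})

test_that("two-way mixed RM-ANOVA reduces to t-tests in the 2x2 case", {
  set.seed(17)
  n <- 8
  dat <- expand.grid(subject = 1:(2 * n), epoch = c("e1", "e2"))
  dat$group <- ifelse(dat$subject <= n, "ctrl", "arch")
  dat$value <- rnorm(nrow(dat)) + ifelse(dat$group == "arch", 0.8, 0) +
    ifelse(dat$epoch == "e2", 0.5, 0)
  res <- rm_anova_two_way(dat)
  # between-group F = t^2 of the unpaired t on subject means
  sm <- aggregate(value ~ subject + group, dat, mean)
  tt <- t_test(sm$value[sm$group == "ctrl"], sm$value[sm$group == "arch"])
  expect_equal(res$group$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(res$group$df, c(1, 2 * n - 2))
  expect_equal(res$group$p, tt$p, tolerance = 1e-10)
  # unbalanced or incomplete designs are refused
  expect_error(rm_anova_two_way(dat[-1, ]), class = "vtsfear_invalid_argument")
  dat2 <- dat; dat2$group[1] <- "arch"
  expect_error(rm_anova_two_way(dat2), class = "vtsfear_invalid_argument")
})

test_that("between-group F is null-calibrated and grows with the effect", {
  set.seed(18)
  f_null <- replicate(200, {
    dat <- expand.grid(subject = 1:12, epoch = c("e1", "e2", "e3"))
    dat$group <- ifelse(dat$subject <= 6, "a", "b")
    dat$value <- rnorm(nrow(dat))
    rm_anova_two_way(dat)$group$statistic
  })
  expect_lt(abs(mean(f_null) - 1.25), 0.5) # E[F(1,10)] = 10/8 = 1.25
  f_of <- function(delta) {
    set.seed(19)
    dat <- expand.grid(subject = 1:12, epoch = c("e1", "e2", "e3"))
    dat$group <- ifelse(dat$subject <= 6, "a", "b")
    dat$value <- rnorm(nrow(dat)) + ifelse(dat$group == "b", delta, 0)
    rm_anova_two_way(dat)$group$statistic
  }
  expect_true(f_of(0.5) < f_of(1) && f_of(1) < f_of(2))
})

test_that("Sidak adjustment and CI reconstruction behave as published", {
  expect_equal(sidak_posthoc(c(0.01, 0.02), k = 4), 1 - (1 - c(0.01, 0.02))^4)
  ci <- ci_from_mean_sem(8.8, 1.6, 12)
  expect_equal(ci[1], 8.8 - qt(0.975, 11) * 1.6)
  # identical CIs, equal n -> t = 0
  expect_equal(t_from_cis(c(1, 2), 10, c(1, 2), 10)$t, 0)
  expect_error(ci_from_mean_sem(1, 0, 12), class = "vtsfear_invalid_argument")
  expect_error(t_from_cis(c(2, 1), 10, c(1, 2), 10),
               class = "vtsfear_invalid_argument")
})

test_that("RM-ANOVA power is monotone and returns the minimal N", {
  p16 <- rm_anova_power(0.667, 0.05, 0.85, 2, 4, 0.5)
  # minimality: the next smaller admissible N misses the target
  p14 <- with(list(n = 14), {
    lambda <- 0.667^2 * n * 4 / (1 + 3 * 0.5)
    pf(qf(0.95, 1, n - 2), 1, n - 2, ncp = lambda, lower.tail = FALSE)
  })
  expect_lt(p14, 0.85)
  expect_gte(p16$power, 0.85)
  # power monotone: decreasing in rho, increasing in f and N
  pw <- function(rho, f = 0.667, N = 16) {
    lambda <- f^2 * N * 4 / (1 + 3 * rho)
    pf(qf(0.95, 1, N - 2), 1, N - 2, ncp = lambda, lower.tail = FALSE)
  }
  expect_true(pw(0.2) > pw(0.5) && pw(0.5) > pw(0.8))
  expect_gt(rm_anova_power(0.4, 0.05, 0.85, 2, 4, 0.5)$N, 16)
  expect_error(rm_anova_power(1e-4, n_max = 100),
               class = "vtsfear_invalid_argument")
})
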