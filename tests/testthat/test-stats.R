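test_that("degenerate equal groups give null statistics", {
  tab <- data.frame(group = rep(c("a", "b"), each = 4),
                    value = rep(c(3, 3), each = 4))
  a <- one_way_anova_tukey(tab)
  expect_equal(a$statistic, 0)
  expect_equal(a$p_value, 1)
  tt <- two_sample_t(tab)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
})

test_that("ANOVA F matches a hand-computed sums-of-squares decomposition", {
  # 3 groups x 5 observations, fixed textbook-style values
  vals <- list(a = c(24, 26, 25, 23, 27),
               b = c(30, 32, 29, 31, 33),
               c = c(25, 27, 26, 28, 24))
  tab <- data.frame(group = rep(names(vals), each = 5),
                    value = unlist(vals))
  rep_ <- one_way_anova_tukey(tab)
  # oracle: direct SS decomposition
  gm <- mean(tab$value)
  ssb <- sum(vapply(vals, function(v) length(v) * (mean(v) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(rep_$statistic, f_oracle, tolerance = 1e-4)
  expect_equal(rep_$df, c(2, 12))
  expect_equal(rep_$p_value,
               stats::pf(f_oracle, 2, 12, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(nrow(rep_$pairwise), 3)
})

test_that("ANOVA on two groups reduces to the pooled t test (F = t^2)", {
  for (seed in 1:5) {
    tab <- simulate_group_table(c(10, 12), c(2, 2), 7, seed = seed)
    a <- one_way_anova_tukey(tab, tukey = FALSE)
    tt <- two_sample_t(tab)
    expect_equal(a$statistic, tt$statistic^2, tolerance = 1e-9)
    expect_equal(a$p_value, tt$p_value, tolerance = 1e-9)
  }
})

test_that("Tukey-adjusted p-values dominate raw pairwise t tests", {
  tab <- simulate_group_table(c(10, 11, 13), c(2, 2, 2), 7, seed = 3)
  rep_ <- one_way_anova_tukey(tab)
  for (i in seq_len(nrow(rep_$pairwise))) {
    gi <- rep_$pairwise$group_i[i]
    gj <- rep_$pairwise$group_j[i]
    raw <- stats::t.test(tab$value[tab$group == gi],
                         tab$value[tab$group == gj],
                         var.equal = TRUE)$p.value
    expect_gte(rep_$pairwise$adjusted_p[i] + 1e-12, raw)
  }
})

test_that("input validation guards group structure and missing data", {
  expect_error(one_way_anova_tukey(data.frame(group = "a", value = 1)),
               "at least 2")
  bad <- data.frame(group = rep(c("a", "b"), c(1, 5)), value = rnorm(6))
  expect_error(one_way_anova_tukey(bad), "n >= 2")
  three <- simulate_group_table(c(1, 2, 3), c(1, 1, 1), 5, seed = 1)
  expect_error(two_sample_t(three), "exactly 2")
  with_na <- simulate_group_table(c(1, 2), c(1, 1), 6, seed = 1)
  with_na$value[3] <- NA
  rep_ <- two_sample_t(with_na)
  expect_equal(rep_$n_dropped, 1L)
})

test_that("chi-squared on proportions matches direct expected-count arithmetic", {
  eq <- chi2_proportions(10, 100, 10, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  got <- chi2_proportions(30, 100, 10, 100)
  # oracle: Pearson formula via expected counts on the 2x2 table
  o <- c(30, 70, 10, 90)
  rowt <- c(100, 100); colt <- c(40, 160); N <- 200
  e <- c(rowt[1] * colt[1], rowt[1] * colt[2],
         rowt[2] * colt[1], rowt[2] * colt[2]) / N
  chi2_oracle <- sum((o - e)^2 / e)
  expect_equal(got$statistic, chi2_oracle, tolerance = 1e-9)
  expect_equal(got$df, 1)
  # symmetry under swapping groups
  swapped <- chi2_proportions(10, 100, 30, 100)
  expect_equal(swapped$statistic, got$statistic)
  # continuity correction shrinks the statistic
  corr <- chi2_proportions(30, 100, 10, 100, correct = TRUE)
  expect_lt(corr$statistic, got$statistic)
  expect_error(chi2_proportions(110, 100, 10, 100), "exceed")
  expect_error(chi2_proportions(10, 0, 10, 100), "> 0")
})

test_that("null p-values are approximately uniform at modest simulation size", {
  nrep <- 400
  p_anova <- vapply(seq_len(nrep), function(i) {
    tab <- simulate_group_table(c(5, 5, 5), c(1, 1, 1), 7, seed = 10000 + i)
    one_way_anova_tukey(tab, tukey = FALSE)$p_value
  }, numeric(1))
  rate <- mean(p_anova < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
  expect_gt(mean(p_anova), 0.45)
  expect_lt(mean(p_anova), 0.55)
})
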