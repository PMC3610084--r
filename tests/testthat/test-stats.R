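# Independent oracles are computed inline from the defining formulas.

test_that("Kruskal-Wallis matches the rank-formula oracle and handles ties", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  # H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 with no ties
  y <- unlist(g); N <- length(y)
  r <- rank(y)
  rbars <- tapply(r, rep(names(g), lengths(g)), mean)
  H_oracle <- 12 / (N * (N + 1)) *
    sum(lengths(g) * (rbars - (N + 1) / 2)^2)
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, H_oracle, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(H_oracle, 2, lower.tail = FALSE))

  tied <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)

  expect_error(kruskal_wallis(list(a = 1:3)), "two groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = 2)), "at least 2")
})

test_that("the null Kruskal-Wallis statistic follows chi-square(2)", {
  set.seed(500)
  H <- replicate(400, {
    y <- rnorm(30)
    kruskal_wallis(split(y, rep(1:3, each = 10)))$statistic
  })
  expect_equal(mean(H < qchisq(0.95, 2)), 0.95, tolerance = 0.04)
})

test_that("one-way ANOVA agrees with hand-computed sums of squares", {
  g <- list(x = c(2, 4, 6), y = c(5, 7, 9, 11), z = c(1, 2))
  y <- unlist(g); N <- length(y); k <- length(g)
  grand <- mean(y)
  ssb <- sum(lengths(g) * (vapply(g, mean, 0) - grand)^2)
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  F_oracle <- (ssb / (k - 1)) / (ssw / (N - k))
  res <- one_way_anova(g)
  expect_equal(res$statistic, F_oracle, tolerance = 1e-12)
  expect_equal(res$df, c(2, 6))

  # identical group means -> F = 0
  expect_equal(one_way_anova(list(a = c(1, 3), b = c(0, 4)))$statistic, 0)

  # two groups: F equals the squared pooled t statistic
  set.seed(9)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(one_way_anova(list(a = a, b = b))$statistic,
               unname(tt$statistic)^2, tolerance = 1e-10)

  # degenerate zero-variance case is flagged
  flat <- one_way_anova(list(a = c(1, 1), b = c(1, 1)))
  expect_false(is.finite(flat$statistic))
  expect_match(flat$note, "undefined")
})

test_that("summary-statistic ANOVA equals raw ANOVA on matching data", {
  means <- c(10, 12, 9); sds <- c(2, 2.5, 1.5); ns <- c(8, 6, 7)
  # construct raw groups with exactly these means and SDs
  raw <- lapply(seq_along(ns), function(i) {
    set.seed(i)
    z <- scale(rnorm(ns[i]))  # exact mean 0, sd 1
    means[i] + sds[i] * as.vector(z)
  })
  names(raw) <- letters[1:3]
  expect_equal(anova_from_summary(means, sds, ns)$statistic,
               one_way_anova(raw)$statistic, tolerance = 1e-10)
  expect_equal(anova_from_summary(c(5, 5), c(1, 2), c(4, 4))$statistic, 0)
  expect_error(anova_from_summary(c(1, 2), c(0, 1), c(4, 4)), "positive")
  expect_error(anova_from_summary(c(1, 2), c(1, 1), c(1, 4)), ">= 2")
})

test_that("chi-squared independence matches hand computations", {
  # perfectly diagonal 2x2 -> chi2 = N
  d <- chi_square_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(d$statistic, 20, tolerance = 1e-12)
  expect_equal(d$df, 1)

  # outer-product table -> chi2 = 0
  tab <- outer(c(10, 20), c(3, 6, 9)) / 3
  expect_equal(chi_square_independence(tab)$statistic, 0, tolerance = 1e-9)

  expect_error(chi_square_independence(rbind(c(1, -1), c(2, 2))),
               "non-negative")
  expect_error(chi_square_independence(rbind(c(0, 0), c(2, 2))), "margin")
})

test_that("Tukey comparisons behave canonically", {
  # identical groups: all adjusted p near 1
  same <- tukey_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3),
                             c = c(1, 2, 3)))
  expect_true(all(same$p > 0.99))
  expect_false(any(same$significant))

  # two groups: Tukey p equals the pooled t-test p (q = sqrt(2) |t|)
  set.seed(12)
  a <- rnorm(10); b <- rnorm(12, 1)
  tk <- tukey_posthoc(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(tk$p, tt$p.value, tolerance = 1e-6)

  # p-value ordering follows the mean-gap ordering
  set.seed(13)
  g <- list(lo = rnorm(20, 0), mid = rnorm(20, 1), hi = rnorm(20, 4))
  tk3 <- tukey_posthoc(g)
  gaps <- abs(tk3$diff)
  expect_equal(order(tk3$p), order(-gaps))
})

test_that("Fisher LSD uses the pooled MSW and the protection rule", {
  set.seed(21)
  g <- list(a = rnorm(10, 0), b = rnorm(10, 2), c = rnorm(10, 2.2))
  lsd <- fisher_lsd_posthoc(g)
  # oracle for the a-b pair
  msw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0)) / (30 - 3)
  t_ab <- (mean(g$a) - mean(g$b)) / sqrt(msw * (1 / 10 + 1 / 10))
  expect_equal(lsd$t[lsd$pair == "a-b"], t_ab, tolerance = 1e-12)
  expect_equal(lsd$p[lsd$pair == "a-b"], 2 * pt(-abs(t_ab), 27),
               tolerance = 1e-12)
  expect_true(attr(lsd, "protected"))

  # non-significant omnibus suppresses pairwise significance
  set.seed(22)
  null_g <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6))
  while (one_way_anova(null_g)$p_value < 0.2) {
    null_g <- lapply(null_g, function(v) rnorm(6))
  }
  lsd0 <- fisher_lsd_posthoc(null_g)
  expect_false(attr(lsd0, "protected"))
  expect_false(any(lsd0$significant))

  same <- fisher_lsd_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_false(any(same$significant))
})

test_that("correlation tables report r, p and stars per group", {
  df <- data.frame(group = rep("G", 10), x = 1:10, y = 1:10,
                   z = -(1:10), w = c(1:9, 9.5))
  ct <- pearson_correlations(df, "x", c("y", "z", "w"))$G
  expect_equal(ct$r[ct$score == "y"], 1)
  expect_equal(ct$r[ct$score == "z"], -1)
  expect_equal(ct$stars[ct$score == "w"], "**")

  # constant column flagged, not an error
  df$k <- 5
  ck <- pearson_correlations(df, "x", "k")$G
  expect_true(is.na(ck$r))
})

test_that("the VIQ split partitions at the cutoff with ties assigned low", {
  rec <- data.frame(id = 1:7, viq = c(30, 44, 44.0001, 50, 60, 20, 44))
  sp <- split_by_viq(rec, cutoff = 44)
  expect_equal(nrow(sp$hviq) + nrow(sp$lviq), 7)
  expect_true(all(sp$hviq$viq > 44))
  expect_true(all(sp$lviq$viq <= 44))
  expect_true(44 %in% sp$lviq$viq)

  # default cutoff is the sample mean; brute-force agreement
  set.seed(2)
  for (i in 1:10) {
    r <- data.frame(viq = runif(15, 20, 80))
    sp2 <- split_by_viq(r)
    expect_identical(sp2$hviq$viq, r$viq[r$viq > mean(r$viq)])
    expect_identical(sp2$lviq$viq, r$viq[r$viq <= mean(r$viq)])
  }

  expect_warning(split_by_viq(data.frame(viq = c(50, 60)), cutoff = 10),
                 "degenerate")
})

test_that("descriptive statistics match their defining formulas", {
  d <- descriptive_stats(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$range, 2)
  expect_equal(d$sem, 1 / sqrt(3))
  expect_equal(d$ci95_halfwidth, qt(0.975, 2) / sqrt(3))

  set.seed(4)
  v <- rexp(40)
  d2 <- descriptive_stats(v)
  expect_equal(d2$sem, sd(v) / sqrt(40))
  expect_equal(d2$shapiro_p, shapiro.test(v)$p.value)
  expect_false(d2$normal)  # exponential data are flagged non-normal
  expect_error(descriptive_stats(5), "at least two")
})

test_that("presence percentages are hand-countable", {
  rec <- data.frame(
    group = c("A", "A", "A", "B", "B"),
    presence_sr = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    presence_ft = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    presence_poa = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  pp <- presence_percentages(rec)
  expect_equal(pp$sr, c(100, 100))
  expect_equal(pp$ft[pp$group == "A"], 100 * 2 / 3)
  expect_equal(pp$poa, c(100 / 3, 0))
})
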