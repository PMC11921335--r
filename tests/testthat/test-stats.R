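test_that("Brunner-Munzel behaves symmetrically and detects nothing in identical samples", {
  x <- c(1.2, 3.4, 2.2, 5.0, 0.7)
  same <- brunner_munzel(x, x)
  expect_equal(same$effect, 0.5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)

  set.seed(14)
  a <- rlnorm(12); b <- rlnorm(15, 0.8)
  ab <- brunner_munzel(a, b)
  ba <- brunner_munzel(b, a)
  expect_equal(ba$effect, 1 - ab$effect)
  expect_equal(ba$p_raw, ab$p_raw, tolerance = 1e-12)
  expect_equal(ba$statistic, -ab$statistic, tolerance = 1e-12)
  expect_true(ab$effect >= 0 && ab$effect <= 1)

  expect_error(brunner_munzel(1, c(1, 2)), "two values")
  expect_error(brunner_munzel(rep(2, 5), rep(2, 4)), "degenerate")
})

test_that("Brunner-Munzel statistic and permutation p match a first-principles oracle", {
  set.seed(99)
  cases <- list(
    list(x = rnorm(6), y = rnorm(6)),
    list(x = rnorm(7), y = rnorm(8, 1)),
    list(x = round(rlnorm(8), 1), y = round(rlnorm(8, 0.5), 1)) # ties
  )
  for (cs in cases) {
    got <- brunner_munzel(cs$x, cs$y)
    expect_equal(got$statistic, oracle_bm_stat(cs$x, cs$y),
                 tolerance = 1e-12)
    perm <- brunner_munzel(cs$x, cs$y, method = "permutation")
    expect_equal(perm$p_raw, oracle_bm_perm_p(cs$x, cs$y),
                 tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis H matches the direct rank formula and handles degeneracy", {
  g <- list(a = c(2.1, 3.3, 1.8), b = c(4.0, 5.2, 3.9, 6.1), c = c(0.5, 1.1))
  got <- kruskal_wallis(g)
  # direct formula (no ties in this toy): H = 12/(N(N+1)) sum n_i Rbar_i^2 - 3(N+1)
  pooled <- unlist(g)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(g), lengths(g))
  H <- 12 / (N * (N + 1)) * sum(tapply(r, idx, sum)^2 / lengths(g)) -
    3 * (N + 1)
  expect_equal(got$statistic, H, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p_raw, 1 - pchisq(H, 2), tolerance = 1e-12)

  expect_error(kruskal_wallis(list(1:3)), "two groups")
  flat <- kruskal_wallis(list(rep(1, 4), rep(1, 5)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_raw, 1)
})

test_that("Dunn post hoc z statistics match a hand-computed oracle", {
  g <- list(w = c(12, 15, 11, 19, 14), s = c(22, 25, 21, 30, 24),
            a = c(16, 13, 20, 23, 17))
  res <- dunn_posthoc(g)
  expect_equal(nrow(res), 3L)  # k(k-1)/2

  # independent computation from pooled ranks
  pooled <- unlist(g); r <- rank(pooled); N <- length(pooled)
  rb <- tapply(r, rep(1:3, each = 5), mean)
  tie <- table(pooled); tie_c <- sum(tie^3 - tie) / (12 * (N - 1))
  vb <- N * (N + 1) / 12 - tie_c
  z12 <- (rb[1] - rb[2]) / sqrt(vb * (1 / 5 + 1 / 5))
  expect_equal(res$z[res$group1 == "w" & res$group2 == "s"],
               unname(z12), tolerance = 1e-12)
  expect_equal(res$p_adjusted,
               p.adjust(2 * pnorm(-abs(res$z)), "holm"), tolerance = 1e-12)

  ident <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$z, 0)
  expect_equal(ident$p_raw, 1)

  k4 <- dunn_posthoc(split(rnorm(40), rep(1:4, 10)))
  expect_equal(nrow(k4), 6L)
})

test_that("Holm adjustment matches the step-down oracle and its invariances", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    ord <- sample(seq_along(p))
    expect_equal(holm_adjust(p[ord])[order(ord)], adj)
  }
  expect_error(holm_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("bootstrap CIs are seeded, deterministic and leave the RNG alone", {
  x <- rnorm(40)
  a <- bootstrap_ci(x, mean, n_resamples = 500, seed = 9)
  b <- bootstrap_ci(x, mean, n_resamples = 500, seed = 9)
  expect_identical(a, b)
  expect_true(a$lower <= a$point && a$point <= a$upper)

  cst <- bootstrap_ci(rep(3.3, 10), mean, seed = 1)
  expect_equal(cst$lower, 3.3)
  expect_equal(cst$upper, 3.3)

  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(bootstrap_ci(x, mean, seed = 77)); after <- rnorm(1)
  expect_identical(before, after)

  md <- bootstrap_ci(x, median, n_resamples = 300, seed = 2)
  expect_true(md$lower <= md$point && md$point <= md$upper)
  expect_error(bootstrap_ci(numeric()), "empty")
})

test_that("boxplot summary uses linear-interpolation percentiles and 5-95 outliers", {
  s <- boxplot_summary(1:100)
  expect_equal(unname(s$percentiles),
               c(5.95, 25.75, 50.5, 75.25, 95.05))
  expect_equal(s$lower_outliers, 1:5)
  expect_equal(s$upper_outliers, 96:100)
  expect_true(all(diff(s$percentiles) >= 0))

  one <- boxplot_summary(7)
  expect_true(all(one$percentiles == 7))
  expect_equal(length(one$lower_outliers), 0L)
})

test_that("grouped comparison runner picks the right test by level count", {
  set.seed(6)
  d2 <- data.frame(v = rnorm(40), g = rep(c("u", "r"), 20))
  r2 <- compare_groups(d2, "v", "g")
  expect_equal(r2$omnibus$test_name, "Brunner-Munzel")
  expect_null(r2$pairwise)

  d4 <- data.frame(v = rnorm(80), g = rep(c("w", "sp", "su", "au"), 20))
  r4 <- compare_groups(d4, "v", "g")
  expect_equal(r4$omnibus$test_name, "Kruskal-Wallis")
  expect_equal(nrow(r4$pairwise), 6L)
  expect_true(all(r4$pairwise$p_adjusted >= r4$pairwise$p_raw))
})
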