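test_that("worked example: fully separated samples of three give exact p = 0.05", {
  r <- mwu_one_sided(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(r$p_one_sided, 1 / 20)
  expect_equal(r$method, "exact")
  expect_equal(r$U, 9)
  # same data through the opposite direction
  r2 <- mwu_one_sided(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(r2$p_one_sided, 1 / 20)
})

test_that("identical samples give p >= 0.5 and U is within bounds", {
  r <- mwu_one_sided(c(1, 2, 2, 3), c(1, 2, 2, 3), "greater")
  expect_gte(r$p_one_sided, 0.5)
  expect_true(r$U >= 0 && r$U <= 16)
  expect_error(mwu_one_sided(numeric(0), 1:3), "non-empty")
})

test_that("exact path agrees with brute-force enumeration on random small samples", {
  set.seed(99)
  for (i in 1:40) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    # mix of continuous and tied data
    x <- if (i %% 2) rnorm(n1) else sample(1:4, n1, TRUE)
    y <- if (i %% 2) rnorm(n2) else sample(1:4, n2, TRUE)
    alt <- sample(c("greater", "less"), 1)
    expect_equal(mwu_one_sided(x, y, alt)$p_one_sided,
                 mwu_brute_force(x, y, alt), tolerance = 1e-12)
  }
})

test_that("exact path agrees with the classical distribution on tie-free data", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(8)
    p_pkg <- mwu_one_sided(x, y, "greater")$p_one_sided
    p_ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
})

test_that("one-sided p-values of the two directions sum to 1 plus the point mass", {
  set.seed(31)
  for (i in 1:10) {
    x <- sample(1:5, 5, TRUE); y <- sample(1:5, 6, TRUE)
    pg <- mwu_one_sided(x, y, "greater")$p_one_sided
    pl <- mwu_one_sided(x, y, "less")$p_one_sided
    # P(U >= u) + P(U <= u) = 1 + P(U == u)
    expect_gte(pg + pl, 1 - 1e-12)
    expect_lte(pg + pl, 2)
  }
})

test_that("shifting one sample upward monotonically strengthens its evidence", {
  set.seed(17)
  x <- rnorm(6); y <- rnorm(6)
  ps <- vapply(c(0, 0.5, 1, 2, 4), function(d)
    mwu_one_sided(x + d, y, "greater")$p_one_sided, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(23)
  x <- rnorm(15, 1); y <- rnorm(15)
  r <- mwu_one_sided(x, y, "greater")
  expect_equal(r$method, "normal-approximation")
  p_ref <- wilcox.test(x, y, alternative = "greater", exact = FALSE,
                       correct = TRUE)$p.value
  expect_equal(r$p_one_sided, p_ref, tolerance = 1e-9)
})

test_that("IQR filter: trivial keep-all and the worked outlier case", {
  f <- iqr_outlier_filter(rep(3, 6))
  expect_length(f$outliers, 0L)
  f2 <- iqr_outlier_filter(c(1, 2, 3, 4, 100))
  # fences from type-7 quartiles of the full sample
  q <- quantile(c(1, 2, 3, 4, 100), c(0.25, 0.75), type = 7, names = FALSE)
  expect_true(100 > q[2] + 1.5 * diff(q))
  expect_equal(sort(f2$kept), c(1, 2, 3, 4))
  expect_equal(f2$outliers, 100)
})

test_that("outlier exclusion is single-pass: re-filtering can differ", {
  x <- c(0, 0, 0, 0, 10, 1000)
  f1 <- iqr_outlier_filter(x)
  expect_equal(f1$outliers, 1000)
  expect_true(10 %in% f1$kept)
  f2 <- iqr_outlier_filter(f1$kept)
  expect_equal(f2$outliers, 10)  # a second pass would have removed more
})

test_that("boxplot stats follow linear-interpolation quartiles and whiskers at kept extremes", {
  b <- boxplot_stats(c(1, 2, 3, 4, 5))
  expect_equal(b$q1, 2)
  expect_equal(b$median, 3)
  expect_equal(b$q3, 4)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 5)
  s <- boxplot_stats(7)
  expect_true(all(c(s$q1, s$median, s$q3, s$whisker_low, s$whisker_high) == 7))
  # outlier set matches the filter exactly
  v <- c(rnorm(20), 50)
  expect_equal(boxplot_stats(v)$outliers, iqr_outlier_filter(v)$outliers)
  b2 <- boxplot_stats(v)
  expect_true(b2$whisker_low <= b2$q1 && b2$q1 <= b2$median &&
                b2$median <= b2$q3 && b2$q3 <= b2$whisker_high)
})

test_that("mean_sem and significance stars match their definitions", {
  ms <- mean_sem(c(2, 4))
  expect_equal(ms$mean, 3)
  expect_equal(ms$sem, 1)
  expect_error(mean_sem(5), "at least two")
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.000004), "****")
  expect_equal(significance_stars(0.05), "")      # strict inequality
  expect_equal(significance_stars(0.005), "*")
  expect_equal(significance_stars(0.0004), "***")
  expect_error(significance_stars(0), "probability")
})

test_that("condition comparison reports one row per density with stars", {
  set.seed(55)
  d <- expand.grid(condition = c("coculture", "control"), density = c(1000, 10000),
                   biological = 1:2, technical = 1:5, stringsAsFactors = FALSE)
  d$viability <- ifelse(d$condition == "coculture", 0.9, 0.7) +
    rnorm(nrow(d), 0, 0.02)
  cmp <- compare_conditions(d, "viability")
  expect_equal(nrow(cmp), 2L)
  expect_true(all(cmp$p < 0.05))
  expect_true(all(cmp$stars != ""))
  cmp_b <- compare_conditions(d, "viability", within_biological = TRUE)
  expect_equal(nrow(cmp_b), 4L)
})
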