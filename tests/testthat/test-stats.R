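# brute-force two-way ANOVA decomposition by explicit loops, independent of
# the implementation's closed-form path
icc_oracle <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  grand <- sum(ratings) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(ratings[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(ratings[, j]) - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (ratings[i, j] - mean(ratings[i, ]) - mean(ratings[, j]) +
                    grand)^2
  }
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  list(absolute = (msr - mse) / (msr + (msc - mse) / n),
       consistency = (msr - mse) / msr,
       f = msr / mse)
}

test_that("ICC matches hand-computed mean squares on the worked example", {
  ratings <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  abs_icc <- icc_average(ratings, "absolute_agreement")
  con_icc <- icc_average(ratings, "consistency")
  expect_equal(abs_icc$icc, 20 / 23, tolerance = 1e-12)
  expect_equal(con_icc$icc, 1, tolerance = 1e-12)
  expect_identical(abs_icc$df1, 3L)
  expect_identical(abs_icc$df2, 3L)
})

test_that("identical raters give ICC 1 in both variants", {
  x <- c(3, 7, 11, 20, 14)
  for (variant in c("absolute_agreement", "consistency")) {
    res <- icc_average(cbind(x, x), variant)
    expect_equal(res$icc, 1)
    expect_true(res$defined)
  }
})

test_that("ICC agrees with the brute-force variance decomposition", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:30, 1); k <- sample(2:4, 1)
    ratings <- matrix(rnorm(n * k, 10, 3), n, k) +
      rnorm(n, 0, 2)  # subject effect
    oracle <- icc_oracle(ratings)
    abs_icc <- icc_average(ratings, "absolute_agreement")
    con_icc <- icc_average(ratings, "consistency")
    expect_equal(abs_icc$icc, oracle$absolute, tolerance = 1e-8)
    expect_equal(con_icc$icc, oracle$consistency, tolerance = 1e-8)
    expect_equal(abs_icc$f_value, oracle$f, tolerance = 1e-8)
    expect_identical(abs_icc$df1, n - 1L)
    expect_identical(abs_icc$df2, (n - 1L) * (k - 1L))
    expect_true(abs_icc$ci_low <= abs_icc$icc &&
                  abs_icc$icc <= abs_icc$ci_high)
    expect_true(con_icc$ci_low <= con_icc$icc)
  }
})

test_that("rater shift leaves consistency unchanged, lowers agreement", {
  set.seed(13)
  x <- rnorm(12, 15, 4)
  y <- x + rnorm(12, 0, 0.8)
  base_abs <- icc_average(cbind(x, y), "absolute_agreement")$icc
  base_con <- icc_average(cbind(x, y), "consistency")$icc
  shifted_abs <- icc_average(cbind(x, y + 3), "absolute_agreement")$icc
  shifted_con <- icc_average(cbind(x, y + 3), "consistency")$icc
  expect_equal(shifted_con, base_con, tolerance = 1e-12)
  expect_lt(shifted_abs, base_abs)
})

test_that("constant ratings are flagged undefined", {
  res <- icc_average(cbind(rep(2, 5), rep(2, 5)))
  expect_false(res$defined)
  expect_true(is.na(res$icc))
})

test_that("Pearson correlation matches closed-form small cases", {
  expect_equal(pearson_corr(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_corr(1:3, -(1:3))$r, -1)
  expect_equal(pearson_corr(1:3, c(1, 3, 2))$r, 0.5, tolerance = 1e-12)
  flat <- pearson_corr(1:5, rep(2, 5))
  expect_false(flat$defined)
  # invariance under positive affine maps of either argument
  set.seed(4)
  x <- rnorm(15); y <- rnorm(15)
  r0 <- pearson_corr(x, y)$r
  expect_equal(pearson_corr(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_corr(x, 0.2 * y - 5)$r, r0, tolerance = 1e-12)
})

test_that("ANCOVA reproduces the hand-computed nested-OLS example", {
  y <- c(0, 1, 2, 1, 2, 4)
  g <- rep(c("A", "B"), each = 3)
  x <- rep(0:2, 2)
  res <- ancova_group(y, g, x)
  expect_equal(res$f_value, 19.2, tolerance = 1e-10)
  expect_identical(res$df1, 1L)
  expect_identical(res$df2, 3L)
})

test_that("ANCOVA F has df (1, n - 3) and a null group effect gives F = 0", {
  set.seed(2)
  n <- 25
  x <- rnorm(n, 40, 3)
  g <- rep(c("preterm", "term"), length.out = n)
  y <- 2 * x + rnorm(n)
  res <- ancova_group(y, g, x)
  expect_identical(res$df2, 22L)
  # exactly covariate-determined response: no group effect
  exact <- ancova_group(2 * x + 1, g, x)
  expect_lte(exact$f_value, 1e-10)
  expect_error(ancova_group(y, rep("a", n), x), "two groups")
  expect_error(ancova_group(y, g, as.numeric(g == "term")), "singular")
})

test_that("ANCOVA agrees with a brute-force normal-equations solve", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    x <- rnorm(n, 10, 2)
    g <- sample(rep(c("g1", "g2"), length.out = n))
    y <- 1 + 0.5 * x + (g == "g2") * rnorm(1, 0, 2) + rnorm(n)
    res <- ancova_group(y, g, x)
    # explicit design matrices and normal equations
    Xf <- cbind(1, x, as.numeric(g == "g2"))
    Xr <- cbind(1, x)
    bf <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
    br <- solve(t(Xr) %*% Xr, t(Xr) %*% y)
    rssf <- sum((y - Xf %*% bf)^2)
    rssr <- sum((y - Xr %*% br)^2)
    f_oracle <- ((rssr - rssf) / 1) / (rssf / (n - 3))
    expect_equal(res$f_value, f_oracle, tolerance = 1e-8)
    # adjusted means at the grand covariate mean
    adj_oracle <- c(bf[[1]] + bf[[2]] * mean(x),
                    bf[[1]] + bf[[2]] * mean(x) + bf[[3]])
    expect_equal(unname(res$adjusted_means[c("g1", "g2")]), adj_oracle,
                 tolerance = 1e-8)
  }
})

test_that("stats config validates its significance level", {
  cfg <- stats_config()
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$icc_strong_threshold, 0.75)
  expect_error(stats_config(alpha = 0), "alpha")
})
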