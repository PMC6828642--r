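#' Average-measures intraclass correlation for a subjects-by-raters matrix
#'
#' Two-way ANOVA decomposition: `MSR` between subjects, `MSC` between
#' raters, `MSE` residual. The absolute-agreement average-measures ICC is
#' `(MSR - MSE) / (MSR + (MSC - MSE) / n)`; the consistency
#' average-measures ICC is `(MSR - MSE) / MSR`. Both variants share the
#' F test `F = MSR / MSE` on `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#' 95% confidence bounds follow McGraw & Wong: exact F bounds for the
#' consistency variant, the Satterthwaite single-measures interval mapped
#' through the Spearman-Brown step for absolute agreement.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns; no
#'   missing cells, at least 2 of each.
#' @param variant `"absolute_agreement"` (two-way random, average
#'   measures) or `"consistency"` (two-way mixed, average measures).
#' @param alpha Significance level for the confidence interval.
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `f_value`, `df1`, `df2`, `p`, `variant`, `defined` (FALSE when every
#'   subject is rated identically by all raters and the ICC is undefined).
#' @export
icc_average <- function(ratings,
                        variant = c("absolute_agreement", "consistency"),
                        alpha = 0.05) {
  variant <- match.arg(variant)
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings))) stopf("ratings must be complete and finite")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stopf("need at least 2 subjects and 2 raters")

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- max(sse / ((n - 1) * (k - 1)), 0)

  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  eps <- .Machine$double.eps * max(1, sst)
  if (msr <= eps && mse <= eps) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, f_value = NA_real_,
                          df1 = df1, df2 = df2, p = NA_real_,
                          variant = variant, defined = FALSE),
                     class = "icc_result"))
  }
  f_value <- msr / mse
  p <- stats::pf(f_value, df1, df2, lower.tail = FALSE)

  if (variant == "consistency") {
    icc <- (msr - mse) / msr
    fl <- f_value / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_value * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c(1 - 1 / fl, 1 - 1 / fu)
  } else {
    icc <- (msr - mse) / (msr + (msc - mse) / n)
    # single-measures agreement interval (Satterthwaite df), then
    # Spearman-Brown up to k raters
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (mse <= eps && msc <= eps) {
      ci <- c(1, 1)
    } else {
      a <- (k * icc1) / (n * (1 - icc1))
      b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f1 <- stats::qf(1 - alpha / 2, n - 1, v)
      f2 <- stats::qf(1 - alpha / 2, v, n - 1)
      low1 <- n * (msr - f1 * mse) /
        (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
      up1 <- n * (f2 * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f2 * msr)
      sb <- function(r) r * k / (1 + (k - 1) * r)
      ci <- c(sb(low1), sb(up1))
    }
  }
  structure(list(icc = icc, ci_low = min(ci, icc), ci_high = max(ci, icc),
                 f_value = f_value, df1 = df1, df2 = df2, p = p,
                 variant = variant, defined = TRUE),
            class = "icc_result")
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Numeric vectors of equal length (n >= 3, nonzero variance).
#' @return A list `r`, `n`, `p`, `t`, `df`; `defined = FALSE` with `NA`
#'   values when a variance is zero.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stopf("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3) stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = n, p = NA_real_, t = NA_real_,
                df = n - 2L, defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), n = n, p = ct$p.value,
       t = unname(ct$statistic), df = n - 2L, defined = TRUE)
}

#' ANCOVA: group comparison of scores adjusting for a covariate
#'
#' Nested ordinary-least-squares fits: full model
#' `y ~ 1 + covariate + group` against reduced `y ~ 1 + covariate`;
#' `F = ((RSS_red - RSS_full) / 1) / (RSS_full / (n - 3))` on
#' `(1, n - 3)` degrees of freedom for two groups and one covariate.
#' Adjusted group means are model predictions at the grand covariate mean;
#' `"term"` is the reference level.
#'
#' @param y Numeric response (e.g. MTS totals).
#' @param group Two-level grouping (character or factor).
#' @param covariate Numeric covariate (e.g. GAMRI in decimal weeks).
#' @param alpha Significance level recorded in the result.
#' @return A list of class `ancova_result`: `f_value`, `df1`, `df2`, `p`,
#'   `adjusted_means` (named by group), `slope`, `n`, `alpha`.
#' @export
ancova_group <- function(y, group, covariate, alpha = 0.05) {
  n <- length(y)
  if (length(group) != n || length(covariate) != n) {
    stopf("'y', 'group' and 'covariate' must have equal length")
  }
  levels_present <- unique(as.character(group))
  if (length(levels_present) != 2L) stopf("need exactly two groups")
  if (min(table(group)) < 2L) stopf("each group needs at least 2 subjects")
  lv <- if (all(c("term", "preterm") %in% levels_present)) {
    c("term", "preterm")  # term is the reference level
  } else {
    sort(levels_present)
  }
  g <- factor(as.character(group), levels = lv)
  dat <- data.frame(y = y, g = g, x = covariate)
  full <- stats::lm(y ~ x + g, data = dat)
  if (any(is.na(stats::coef(full)))) {
    stopf("singular design: covariate is collinear with the group indicator")
  }
  reduced <- stats::lm(y ~ x, data = dat)
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(reduced)^2)
  df2 <- n - 3L
  num <- rss_red - rss_full
  tol <- 1e-12 * max(rss_red, 1)
  f_value <- if (num <= tol && rss_full <= tol) 0 else num / (rss_full / df2)
  p <- stats::pf(f_value, 1, df2, lower.tail = FALSE)
  xbar <- mean(covariate)
  newdata <- data.frame(x = xbar, g = factor(levels(g), levels = levels(g)))
  adj <- stats::predict(full, newdata = newdata)
  names(adj) <- levels(g)
  structure(list(f_value = f_value, df1 = 1L, df2 = df2, p = p,
                 adjusted_means = adj,
                 slope = unname(stats::coef(full)[["x"]]),
                 n = n, alpha = alpha),
            class = "ancova_result")
}

#' Statistical-analysis configuration
#'
#' @param alpha Significance level (default 5%).
#' @param icc_strong_threshold ICC at or above which agreement is called
#'   strong (default 0.75).
#' @param icc_variant Default ICC variant reported first.
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, icc_strong_threshold = 0.75,
                         icc_variant = "absolute_agreement") {
  assert_prob(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stopf("'alpha' must be in (0, 1)")
  structure(list(alpha = alpha,
                 icc_strong_threshold = icc_strong_threshold,
                 icc_variant = icc_variant),
            class = "stats_config")
}
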