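# Replicate-aware nonparametric comparison of co-culture vs control.
#
# The workhorse is a one-sided Mann-Whitney U test with an exact small-sample
# path: when n1*n2 <= 100 the permutation distribution of the rank sum is
# computed in full (by a counting recursion when the pooled sample is
# tie-free, which is identical to enumerating all label assignments, and by
# explicit enumeration of assignments when ties are present). Larger samples
# use the normal approximation with tie-corrected variance and continuity
# correction. Summaries follow the boxplot convention with 1.5*IQR outlier
# exclusion and linear-interpolation quantiles.

# number of ways to choose n1 of the ranks 1..n with each possible rank sum
ranksum_counts <- function(n1, n) {
  maxs <- sum(seq(n - n1 + 1L, n))
  dp <- matrix(0, n1 + 1L, maxs + 1L)  # dp[j+1, s+1]: j chosen, sum s
  dp[1L, 1L] <- 1
  for (r in seq_len(n)) {
    for (j in seq(min(r, n1), 1L)) {
      dp[j + 1L, (r + 1L):(maxs + 1L)] <-
        dp[j + 1L, (r + 1L):(maxs + 1L)] + dp[j, 1L:(maxs + 1L - r)]
    }
  }
  dp[n1 + 1L, ]
}

#' One-sided Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. When
#' `n1 * n2 <= 100` the one-sided p-value is exact under the permutation
#' distribution of group labels over the pooled sample (ties included);
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction is used. `alternative = "greater"` tests whether
#' `x` tends to exceed `y`.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"greater"` (x shifted above y) or `"less"`.
#' @param exact_limit maximum `n1 * n2` for the exact path.
#' @return list of class `mwu_result` with `U` (number of (x, y) pairs with
#'   x > y, ties counting 1/2), `p_one_sided`, `method` (`"exact"` or
#'   `"normal-approximation"`), `stars` and the sample sizes.
#' @export
mwu_one_sided <- function(x, y, alternative = c("greater", "less"),
                          exact_limit = 100L) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  n <- n1 + n2
  has_ties <- anyDuplicated(pooled) > 0L
  eps <- 1e-9
  if (n1 * n2 <= exact_limit) {
    if (!has_ties) {
      cnt <- ranksum_counts(n1, n)
      s <- seq_along(cnt) - 1
      tot <- sum(cnt)
      p <- if (alternative == "greater") sum(cnt[s >= R1 - eps]) / tot
           else sum(cnt[s <= R1 + eps]) / tot
    } else {
      comb <- utils::combn(n, n1)
      sums <- colSums(matrix(r[comb], nrow = n1))
      p <- if (alternative == "greater") mean(sums >= R1 - eps)
           else mean(sums <= R1 + eps)
    }
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- if (alternative == "greater") (U - mu - 0.5) / sigma
         else (U - mu + 0.5) / sigma
    p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
    method <- "normal-approximation"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(U = U, p_one_sided = p, method = method,
                 stars = significance_stars(p), n1 = n1, n2 = n2),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), one-sided p = %.4g %s [%s]\n",
              x$U, x$n1, x$n2, x$p_one_sided, x$stars, x$method))
  invisible(x)
}

#' Single-pass 1.5 IQR outlier exclusion
#'
#' Quartiles use the linear-interpolation convention (R quantile type 7);
#' values below `q1 - 1.5*IQR` or above `q3 + 1.5*IQR` are excluded. The
#' fences are computed once on the input sample and not re-computed after
#' exclusion.
#'
#' @param values numeric sample (at least one value).
#' @return list with `kept`, `outliers` and the `fences` used.
#' @export
iqr_outlier_filter <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[2L] + 1.5 * iqr
  out <- values < lo | values > hi
  list(kept = values[!out], outliers = values[out], fences = c(lo, hi))
}

#' Boxplot summary following the 1.5 IQR whisker convention
#'
#' Quartiles by linear interpolation; outliers per [iqr_outlier_filter()];
#' whiskers at the minimum and maximum of the non-outlier values.
#'
#' @param values numeric sample (at least one value).
#' @return list of class `boxplot_stats` with `q1`, `median`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  f <- iqr_outlier_filter(values)
  structure(list(q1 = q[1L], median = q[2L], q3 = q[3L],
                 whisker_low = min(f$kept), whisker_high = max(f$kept),
                 outliers = f$outliers),
            class = "boxplot_stats")
}

#' Mean and standard error of the mean
#'
#' @param values numeric sample with at least two values.
#' @return list with `mean`, `sem` (sample sd over sqrt(n)) and `n`.
#' @export
mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("sem needs at least two values")
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Significance stars at the reporting thresholds
#'
#' Strict inequalities at p < 0.05 (*), < 0.005 (**), < 0.0005 (***) and
#' < 0.00005 (****); an empty string otherwise (so p = 0.05 exactly earns no
#' star).
#'
#' @param p probability in (0, 1].
#' @return string of 0-4 stars.
#' @export
significance_stars <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop("p must be a single probability in (0, 1]")
  if (p < 0.00005) "****"
  else if (p < 0.0005) "***"
  else if (p < 0.005) "**"
  else if (p < 0.05) "*"
  else ""
}

#' Compare treatment against control across densities
#'
#' For each density, tests one-sidedly whether the treatment condition
#' exceeds the control on the given measurement, after optional single-pass
#' IQR outlier exclusion per group. Technical replicates are pooled across
#' biological replicates by default; `within_biological = TRUE` instead
#' tests each biological replicate separately.
#'
#' @param data data frame with columns `condition`, `density`, `biological`
#'   and the value column.
#' @param value_col measurement column name.
#' @param treatment_label,control_label condition labels.
#' @param filter_outliers apply [iqr_outlier_filter()] per group first.
#' @param within_biological test within each biological replicate instead of
#'   pooling.
#' @return data frame with one row per comparison: group sizes, `U`, `p`,
#'   `stars`, `method`, and mean ± sem per group.
#' @export
compare_conditions <- function(data, value_col,
                               treatment_label = "coculture",
                               control_label = "control",
                               filter_outliers = TRUE,
                               within_biological = FALSE) {
  stopifnot(all(c("condition", "density", value_col) %in% names(data)))
  groups <- if (within_biological) {
    unique(data[, c("density", "biological")])
  } else {
    data.frame(density = unique(data$density))
  }
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, , drop = FALSE]
    sel <- data$density == g$density
    if (within_biological) sel <- sel & data$biological == g$biological
    xt <- data[[value_col]][sel & data$condition == treatment_label]
    xc <- data[[value_col]][sel & data$condition == control_label]
    xt <- xt[!is.na(xt)]; xc <- xc[!is.na(xc)]
    if (filter_outliers) {
      if (length(xt)) xt <- iqr_outlier_filter(xt)$kept
      if (length(xc)) xc <- iqr_outlier_filter(xc)$kept
    }
    if (!length(xt) || !length(xc)) next
    mw <- mwu_one_sided(xt, xc, "greater")
    mt <- if (length(xt) >= 2L) mean_sem(xt) else list(mean = mean(xt), sem = NA_real_)
    mc <- if (length(xc) >= 2L) mean_sem(xc) else list(mean = mean(xc), sem = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      density = g$density,
      biological = if (within_biological) g$biological else NA_integer_,
      n_treatment = length(xt), n_control = length(xc),
      mean_treatment = mt$mean, sem_treatment = mt$sem,
      mean_control = mc$mean, sem_control = mc$sem,
      U = mw$U, p = mw$p_one_sided, stars = mw$stars, method = mw$method)
  }
  do.call(rbind, rows)
}
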