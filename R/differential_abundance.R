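# Welch-Satterthwaite degrees of freedom for s2x/nx + rho^2 * s2y/ny.
welch_df <- function(s2x, nx, s2y, ny, rho = 1) {
  num <- (s2x / nx + rho^2 * s2y / ny)^2
  den <- (s2x / nx)^2 / (nx - 1) + (rho^2 * s2y / ny)^2 / (ny - 1)
  if (den == 0) return(nx + ny - 2)  # both variances zero
  num / den
}

#' Fieller confidence interval for a ratio of two means
#'
#' Confidence set for `rho = mean(x) / mean(y)` obtained by inverting the
#' t-test of `mean(x) - rho * mean(y) = 0` with unequal variances:
#' `(xbar - rho*ybar)^2 <= t^2 * (s2x/nx + rho^2 * s2y/ny)`, solved as the
#' quadratic
#' `(ybar^2 - t^2 s2y/ny) rho^2 - 2 xbar ybar rho + (xbar^2 - t^2 s2x/nx) <= 0`,
#' with the Welch-Satterthwaite degrees of freedom evaluated at the point
#' estimate. When the leading coefficient is non-positive (the denominator
#' mean is not significantly different from zero) the set is unbounded and
#' infinite bounds are reported.
#'
#' @param x_values,y_values numeric vectors (numerator and denominator
#'   groups), each with at least two values.
#' @param alpha two-sided error rate; the interval has level `1 - alpha`.
#' @return list with `ratio`, `ci_low`, `ci_high` (possibly `-Inf`/`Inf`),
#'   and `df`.
#' @examples
#' fieller_ci(c(9, 10, 11, 12, 13, 14), c(2, 3, 4, 5))
#' @export
fieller_ci <- function(x_values, y_values, alpha = 0.05) {
  x <- x_values[is.finite(x_values)]
  y <- y_values[is.finite(y_values)]
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need at least two finite values")
  }
  if (mean(y) == 0) stop("denominator mean is zero; handle as exclusivity")
  xbar <- mean(x); ybar <- mean(y)
  s2x <- stats::var(x); s2y <- stats::var(y)
  nx <- length(x); ny <- length(y)
  rho_hat <- xbar / ybar
  df <- welch_df(s2x, nx, s2y, ny, rho_hat)
  if (s2x == 0 && s2y == 0) {
    return(list(ratio = rho_hat, ci_low = rho_hat, ci_high = rho_hat, df = df))
  }
  tq <- stats::qt(1 - alpha / 2, df)
  a <- ybar^2 - tq^2 * s2y / ny
  b <- -2 * xbar * ybar
  cc <- xbar^2 - tq^2 * s2x / nx
  disc <- b^2 - 4 * a * cc
  if (a > 0 && disc >= 0) {
    lo <- (-b - sqrt(disc)) / (2 * a)
    hi <- (-b + sqrt(disc)) / (2 * a)
  } else {
    # denominator not bounded away from zero: unbounded ("exclusive" or
    # whole-line) Fieller set, reported with infinite bounds
    lo <- -Inf
    hi <- Inf
  }
  list(ratio = rho_hat, ci_low = lo, ci_high = hi, df = df)
}

#' Welch two-sample test of mean equality
#'
#' Two-sided Welch t-test (the Fieller statistic at ratio 1). Degenerate
#' inputs are handled without division errors: two identical constant
#' groups give p = 1, constant groups with different values give p = 0 (the
#' zero-variance limit).
#'
#' @param x_values,y_values numeric vectors with at least two values each.
#' @param log_scale test on log10 intensities instead of raw.
#' @return two-sided p-value, or `NA_real_` for degenerate input.
#' @export
ratio_test <- function(x_values, y_values, log_scale = FALSE) {
  x <- x_values[is.finite(x_values)]
  y <- y_values[is.finite(y_values)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (log_scale) {
    if (any(c(x, y) <= 0)) return(NA_real_)
    x <- log10(x); y <- log10(y)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Classify a metabolite by fold change and significance
#'
#' The study's threshold rule: increased when the ratio (condition B over
#' A) is at least `fold_threshold` with p below `alpha`; decreased when the
#' ratio is at most `1/fold_threshold` with p below `alpha`;
#' `exclusive_A`/`exclusive_B` when one condition is entirely undetected
#' and the other has at least `min_detected_exclusive` detected replicates
#' (the infinite fold-change convention); otherwise unchanged.
#' `unevaluable` covers everything the test cannot assess.
#'
#' @param ratio point estimate (B/A); may be `0` or `Inf` for exclusives.
#' @param p_value two-sided p-value (`NA` for exclusives/unevaluable).
#' @param n_A,n_B detected biological replicates per condition.
#' @param config a [default_config()].
#' @return one of `"increased"`, `"decreased"`, `"unchanged"`,
#'   `"exclusive_A"`, `"exclusive_B"`, `"unevaluable"`.
#' @export
classify_metabolite <- function(ratio, p_value, n_A, n_B,
                                config = default_config()) {
  if (n_A == 0 && n_B >= config$min_detected_exclusive) return("exclusive_B")
  if (n_B == 0 && n_A >= config$min_detected_exclusive) return("exclusive_A")
  if (n_A < 2 || n_B < 2 || is.na(p_value) || !is.finite(ratio)) {
    return("unevaluable")
  }
  if (ratio >= config$fold_threshold && p_value < config$alpha) return("increased")
  if (ratio <= 1 / config$fold_threshold && p_value < config$alpha) return("decreased")
  "unchanged"
}

#' Differential abundance over a collapsed feature table
#'
#' For every group of an injection-averaged biological-replicate matrix:
#' the B/A fold ratio, its Fieller confidence interval, the Welch test
#' p-value, and the threshold classification. Zeros are treated as not
#' detected (below detection), like missing cells.
#'
#' @param table a [feature_table()] with one column per biological
#'   replicate (see [average_injections()]).
#' @param config a [default_config()]. `multiple_testing_method = "BH"`
#'   adds a `padj` column and classifies on it instead of the raw p.
#' @return data.frame of class `diff_results`: `group_id`, `n_A`, `n_B`,
#'   `mean_A`, `mean_B`, `ratio`, `log_fold` (log10), `ci_low`, `ci_high`,
#'   `ci_level`, `df`, `p_value`, `label`. Summary counts are attached as
#'   attribute `summary`.
#' @export
diff_table <- function(table, config = default_config()) {
  stopifnot(inherits(table, "feature_table"))
  condA <- which(table$samples$condition == "A")
  condB <- which(table$samples$condition == "B")
  n <- nrow(table$matrix)
  res <- data.frame(
    group_id = table$features$feature_id,
    n_A = integer(n), n_B = integer(n),
    mean_A = rep(NA_real_, n), mean_B = rep(NA_real_, n),
    ratio = rep(NA_real_, n), log_fold = rep(NA_real_, n),
    ci_low = rep(NA_real_, n), ci_high = rep(NA_real_, n),
    ci_level = rep(1 - config$alpha, n),
    df = rep(NA_real_, n), p_value = rep(NA_real_, n),
    label = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (n == 0) {
    class(res) <- c("diff_results", "data.frame")
    attr(res, "summary") <- table(factor(character(),
      levels = c("increased", "decreased", "unchanged",
                 "exclusive_A", "exclusive_B", "unevaluable")))
    return(res)
  }
  log_scale <- identical(config$test_scale, "log")
  for (i in seq_len(n)) {
    a <- table$matrix[i, condA]
    b <- table$matrix[i, condB]
    a <- a[!is.na(a) & a > 0]  # zero intensity == below detection
    b <- b[!is.na(b) & b > 0]
    res$n_A[i] <- length(a)
    res$n_B[i] <- length(b)
    if (length(a)) res$mean_A[i] <- mean(a)
    if (length(b)) res$mean_B[i] <- mean(b)
    if (length(a) >= 2 && length(b) >= 2) {
      fc <- fieller_ci(b, a, config$alpha)
      res$ratio[i] <- fc$ratio
      res$ci_low[i] <- fc$ci_low
      res$ci_high[i] <- fc$ci_high
      res$df[i] <- fc$df
      res$p_value[i] <- ratio_test(b, a, log_scale = log_scale)
    } else if (length(a) == 0 && length(b) > 0) {
      res$ratio[i] <- Inf
    } else if (length(b) == 0 && length(a) > 0) {
      res$ratio[i] <- 0
    }
    res$log_fold[i] <- log10(res$ratio[i])
  }
  p_for_label <- res$p_value
  if (identical(config$multiple_testing_method, "BH")) {
    res$padj <- stats::p.adjust(res$p_value, method = "BH")
    p_for_label <- res$padj
  }
  res$label <- vapply(seq_len(n), function(i) {
    classify_metabolite(res$ratio[i], p_for_label[i], res$n_A[i], res$n_B[i],
                        config)
  }, character(1))
  class(res) <- c("diff_results", "data.frame")
  attr(res, "summary") <- table(factor(res$label,
    levels = c("increased", "decreased", "unchanged",
               "exclusive_A", "exclusive_B", "unevaluable")))
  res
}

#' @export
print.diff_results <- function(x, ...) {
  cat("diff_results:", nrow(x), "groups\n")
  print(attr(x, "summary"))
  invisible(x)
}
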