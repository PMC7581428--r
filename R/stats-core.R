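#' Two-sample unpaired t-test with degenerate-input convention
#'
#' Compares the means of two groups with a two-sided unpaired t-test and
#' returns the mean difference together with its 95% confidence interval.
#' This is the comparison used throughout the package for per-mouse
#' phenotypes (expansion indices, nuclear-intensity means) and for the
#' per-gene endpoint tests of the rescue classification.
#'
#' When both groups have zero variance the t statistic is undefined; rather
#' than aborting (which would kill genome-wide per-gene loops) the result is
#' flagged `degenerate` and the p-value follows a fixed convention: 1 if the
#' two means are equal, 0 otherwise.
#'
#' @param values_a,values_b Numeric vectors, at least 2 finite values each.
#' @param variance_mode `"pooled"` (classical Student t, the default) or
#'   `"welch"` (unequal-variance Welch t).
#' @return An object of class `group_comparison`: a list with elements
#'   `mean_a`, `mean_b`, `mean_diff` (a minus b), `ci95_low`, `ci95_high`,
#'   `t_stat`, `df`, `p_two_sided`, `n_a`, `n_b`, `degenerate`,
#'   `variance_mode`.
#' @examples
#' two_sample_ttest(c(15.1, 15.4, 15.0), c(12.6, 12.9, 12.5))
#' @export
two_sample_ttest <- function(values_a, values_b,
                             variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (anyNA(values_a) || anyNA(values_b)) {
    stop("two_sample_ttest: missing values are not allowed", call. = FALSE)
  }
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (n_a < 2L || n_b < 2L) {
    stop("two_sample_ttest: each group needs at least 2 values", call. = FALSE)
  }
  m_a <- mean(values_a)
  m_b <- mean(values_b)
  diff <- m_a - m_b
  v_a <- stats::var(values_a)
  v_b <- stats::var(values_b)

  if (v_a == 0 && v_b == 0) {
    # degenerate convention: identical-constant groups never abort a loop
    equal <- isTRUE(all.equal(m_a, m_b))
    res <- list(
      mean_a = m_a, mean_b = m_b, mean_diff = diff,
      ci95_low = diff, ci95_high = diff,
      t_stat = if (equal) 0 else sign(diff) * Inf,
      df = n_a + n_b - 2,
      p_two_sided = if (equal) 1 else 0,
      n_a = n_a, n_b = n_b,
      degenerate = TRUE, variance_mode = variance_mode
    )
    class(res) <- "group_comparison"
    return(res)
  }

  tt <- stats::t.test(values_a, values_b,
                      var.equal = (variance_mode == "pooled"),
                      conf.level = 0.95)
  res <- list(
    mean_a = m_a, mean_b = m_b, mean_diff = diff,
    ci95_low = unname(tt$conf.int[1]), ci95_high = unname(tt$conf.int[2]),
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p_two_sided = unname(tt$p.value),
    n_a = n_a, n_b = n_b,
    degenerate = FALSE, variance_mode = variance_mode
  )
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Two-sample t-test (%s)\n  mean A = %.4g (n=%d), mean B = %.4g (n=%d)\n  diff = %.4g, 95%% CI [%.4g, %.4g]\n  t = %.4g, df = %.4g, p = %.4g%s\n",
    x$variance_mode, x$mean_a, x$n_a, x$mean_b, x$n_b,
    x$mean_diff, x$ci95_low, x$ci95_high, x$t_stat, x$df, x$p_two_sided,
    if (x$degenerate) " [degenerate: zero variance in both groups]" else ""
  ))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation between two paired vectors; the two-sided
#' p-value comes from the t transform `r * sqrt((n-2) / (1-r^2))` with n-2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of the same length, n >= 3, each with nonzero
#'   variance.
#' @return An object of class `correlation_result`: list with `r`,
#'   `p_two_sided`, `n`.
#' @examples
#' pearson_correlation(1:10, 2 * (1:10) + rnorm(10))
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("pearson_correlation: x and y must have equal length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("pearson_correlation: missing values are not allowed", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) stop("pearson_correlation: need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_correlation: zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  res <- list(r = unname(ct$estimate), p_two_sided = unname(ct$p.value), n = n)
  class(res) <- "correlation_result"
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4g, p = %.4g, n = %d\n",
              x$r, x$p_two_sided, x$n))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Returns BH-adjusted p-values in the original order.  `NA` entries are
#' passed through and excluded from the number of tests m (used for genes
#' whose model fit did not converge).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Numeric vector of adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' One-sided Fisher exact test for set overlap (upper tail)
#'
#' Over-representation probability for observing at least `overlap_k`
#' elements in common between a query set of size `query_K` and a draw of
#' size `draw_n` from a universe of `universe_N` elements:
#' `Pr(X >= k)` for hypergeometric X.
#'
#' @param overlap_k Observed overlap count.
#' @param query_K Size of the query set.
#' @param draw_n Size of the second set.
#' @param universe_N Size of the shared universe.
#' @return An object of class `fisher_result`: list with `overlap_k`,
#'   `query_size_K`, `draw_size_n`, `universe_N`, `odds_ratio` (sample odds
#'   ratio of the 2x2 table, `Inf` when a margin is saturated) and
#'   `p_one_sided`.
#' @examples
#' fisher_one_sided(2, 3, 3, 10)  # p = 22/120
#' @export
fisher_one_sided <- function(overlap_k, query_K, draw_n, universe_N) {
  k <- as.integer(overlap_k); K <- as.integer(query_K)
  n <- as.integer(draw_n); N <- as.integer(universe_N)
  if (anyNA(c(k, K, n, N)) || any(c(k, K, n, N) < 0L)) {
    stop("fisher_one_sided: counts must be nonnegative integers", call. = FALSE)
  }
  if (K > N || n > N || k > min(K, n) || k < max(0L, K + n - N)) {
    stop("fisher_one_sided: inconsistent 2x2 counts", call. = FALSE)
  }
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  # sample odds ratio of the induced 2x2 table
  a <- k; b <- K - k; c_ <- n - k; d <- N - K - n + k
  odds <- if (b == 0L || c_ == 0L) {
    if (a == 0L || d == 0L) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  res <- list(overlap_k = k, query_size_K = K, draw_size_n = n,
              universe_N = N, odds_ratio = odds, p_one_sided = p)
  class(res) <- "fisher_result"
  res
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf(
    "One-sided Fisher exact: k = %d of K = %d vs n = %d in N = %d; OR = %.4g, p = %.4g\n",
    x$overlap_k, x$query_size_K, x$draw_size_n, x$universe_N,
    x$odds_ratio, x$p_one_sided))
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
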