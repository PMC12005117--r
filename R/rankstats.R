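# Statistical kernels shared by all analysis stages: rank-sum tests,
# auROC marker scores, multiple-testing correction, contingency tests,
# ANOVA/Tukey, standardized major axis fits and permutation z-tests.

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum test with an exact enumeration path for small samples and a
#' tie- and continuity-corrected normal approximation otherwise. The exact
#' two-sided p-value is defined as `2 * min(P(W <= w), P(W >= w))`, capped
#' at 1, where `W` is the rank sum of `x`; enumeration is over all
#' relabelings of the pooled data, so ties are handled exactly.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param mode `"auto"` (exact when the smaller sample has at most 8
#'   observations and the total at most 30), `"exact"`, or `"normal"`.
#' @return A `test_result` list with fields `statistic` (rank sum of `x`),
#'   `p`, `method` and `sided`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  use_exact <- switch(mode,
    exact  = TRUE,
    normal = FALSE,
    auto   = min(n1, n2) <= 8L && n <= 30L
  )
  if (use_exact) {
    combs <- utils::combn(n, n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    p_le <- mean(ws <= w + 1e-9)
    p_ge <- mean(ws >= w - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "rank_sum_exact"
  } else {
    mu <- n1 * (n + 1) / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "rank_sum_normal"
  }
  test_result(statistic = w, p = p, method = method, sided = "two")
}

#' Area under the ROC curve for two samples
#'
#' Mann-Whitney AUC: the probability that a value drawn from `x` exceeds a
#' value drawn from `y`, counting ties as one half.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return AUC in `[0, 1]`.
#' @export
auroc <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty")
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  # rank-sum identity: U = W - n1(n1+1)/2 already accounts for half-ties
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (with an optional explicit family size `m`) or
#' Benjamini-Hochberg step-up adjustment.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @param m Family size for Bonferroni; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh"), m = NULL) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(m)) m <- length(p)
  switch(method,
    bonferroni = pmin(1, p * m),
    bh = stats::p.adjust(p, method = "BH", n = m)
  )
}

#' Chi-square test on a 2x2 contingency table
#'
#' Closed-form chi-square statistic with Yates continuity correction
#' (default), one degree of freedom.
#'
#' @param tab 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return A `test_result` with the chi-square statistic and p-value.
#' @examples
#' chi_square_2x2(matrix(c(23, 79, 1, 1078), 2, 2))
#' @export
chi_square_2x2 <- function(tab, yates = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  storage.mode(tab) <- "double"  # avoid integer overflow in margins
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) stop("all margins must be positive")
  delta <- abs(a * d - b * c_)
  if (yates) delta <- max(0, delta - n / 2)
  chi <- n * delta^2 / (r1 * r2 * c1 * c2)
  test_result(statistic = chi,
              p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
              method = if (yates) "chi_square_yates" else "chi_square",
              sided = "two")
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param groups Named list of numeric vectors, each with at least two
#'   observations; at least two groups.
#' @return A list: `test_result` with the F statistic and p-value, and
#'   `tukey`, a data frame of pairwise comparisons (`group_a`, `group_b`,
#'   `diff`, `p_adj`).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs at least two observations")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), ns), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  res <- test_result(statistic = an[["F value"]][1],
                     p = an[["Pr(>F)"]][1],
                     method = "anova_oneway", sided = "two")
  tk <- stats::TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(
    group_a = vapply(pairs, `[`, "", 1L),
    group_b = vapply(pairs, `[`, "", 2L),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    row.names = NULL
  )
  list(test = res, tukey = tukey)
}

#' Standardized major axis (SMA) regression
#'
#' The SMA slope is `sign(r) * sd(y)/sd(x)` and the line passes through
#' the means. Symmetric in the roles of `x` and `y` (up to inversion).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both non-constant.
#' @return List with `slope` and `intercept`.
#' @export
sma_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need paired vectors with n >= 3")
  }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  s <- if (r < 0) -1 else 1
  slope <- s * sy / sx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Permutation z-test
#'
#' Compares an observed statistic against a sample of values obtained
#' under permutation, using a normal approximation to the permutation
#' distribution: `z = (observed - mean(perm)) / sd(perm)`, two-sided.
#' A degenerate permutation distribution (zero spread) yields `p = 1`
#' with `degenerate = TRUE`.
#'
#' @param observed Observed statistic (scalar).
#' @param permuted Numeric vector of at least two permuted statistics.
#' @return A `test_result` with extra field `degenerate`.
#' @export
perm_z_test <- function(observed, permuted) {
  if (length(permuted) < 2L) stop("need at least two permuted values")
  s <- stats::sd(permuted)
  if (!is.finite(s) || s == 0) {
    res <- test_result(statistic = NA_real_, p = 1,
                       method = "perm_z", sided = "two")
    res$degenerate <- TRUE
    return(res)
  }
  z <- (observed - mean(permuted)) / s
  res <- test_result(statistic = z, p = min(1, 2 * stats::pnorm(-abs(z))),
                     method = "perm_z", sided = "two")
  res$degenerate <- FALSE
  res
}

# Light-weight result container shared by the test functions.
test_result <- function(statistic, p, method, sided) {
  structure(list(statistic = statistic, p = p, method = method,
                 sided = sided),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s-sided): statistic = %.6g, p = %.4g\n",
              x$method, x$sided, x$statistic, x$p))
  invisible(x)
}
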