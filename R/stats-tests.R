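# Rank-based and paired-proportion test primitives.
#
# All primitives return a `serosig_test` object: statistic, two-sided
# p-value, method tag and whether the p-value is exact. Two-sided p-values
# are used throughout.

new_test_result <- function(statistic, p_value, method, exact, note = NULL) {
  abort_if(!is.na(p_value) && (p_value < 0 || p_value > 1),
           "internal error: p-value outside [0,1]")
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         exact = exact, note = note),
    class = "serosig_test"
  )
}

#' @export
print.serosig_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g (%s)\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) "exact" else "asymptotic"))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test for a location difference between two independent samples.
#' Ties are handled with mid-ranks. The exact mode enumerates the full
#' permutation distribution of U over all \eqn{\binom{n+m}{n}} group
#' assignments of the observed (mid-)ranks; because complementary subsets map
#' U to nm - U, this distribution is symmetric about nm/2 even under ties,
#' and the two-sided p-value is \eqn{P(|U - nm/2| \ge |u - nm/2|)}.
#' The asymptotic mode uses the normal approximation with the tie-corrected
#' variance and a 0.5 continuity correction (so U exactly at its null mean
#' gives p = 1).
#'
#' @param x,y numeric vectors, each nonempty.
#' @param mode `"exact"`, `"asymptotic"`, or `"auto"` (exact when
#'   `length(x) + length(y) <= 20` and there are no ties).
#' @return A `serosig_test` with the U statistic for `x` and a two-sided p.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4), mode = "exact")  # p = 1/3
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  abort_if(length(x) == 0 || length(y) == 0, "both samples must be nonempty")
  abort_if(!is.numeric(x) || !is.numeric(y), "samples must be numeric")
  abort_if(anyNA(x) || anyNA(y), "samples must not contain NA")
  n <- length(x); m <- length(y)
  r <- midrank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (mode == "auto") {
    mode <- if (n + m <= 20 && !has_ties) "exact" else "asymptotic"
  }
  if (mode == "exact") {
    p <- mw_exact_p(r, n, u)
    return(new_test_result(u, p, "Mann-Whitney U", exact = TRUE))
  }
  mu <- n * m / 2
  nt <- n + m
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n * m / 12 * ((nt + 1) - tie_term / (nt * (nt - 1)))
  if (sigma2 <= 0) {  # all values identical
    return(new_test_result(u, 1, "Mann-Whitney U", exact = FALSE,
                           note = "all observations tied"))
  }
  z <- max(abs(u - mu) - 0.5, 0) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-z))
  new_test_result(u, p, "Mann-Whitney U", exact = FALSE)
}

# Exact two-sided p for U by enumeration of all group assignments of the
# observed mid-ranks. Symmetric about nm/2, so tail both sides.
mw_exact_p <- function(ranks, n, u_obs) {
  nt <- length(ranks)
  m <- nt - n
  idx <- utils::combn(nt, n)
  offset <- n * (n + 1) / 2
  us <- colSums(matrix(ranks[idx], nrow = n)) - offset
  centre <- n * m / 2
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' Pearson chi-square without continuity correction, as used for categorical
#' cohort comparisons (comorbidity prevalences, sex).
#'
#' @param table a matrix of nonnegative integer counts, at least 2 x 2.
#' @return A `serosig_test` with the chi-square statistic, df attribute in
#'   `note`, and asymptotic p.
#' @examples
#' chi_square_2xk(matrix(c(20, 0, 0, 20), 2))
#' @export
chi_square_2xk <- function(table) {
  abort_if(!is.matrix(table) || nrow(table) < 2 || ncol(table) < 2,
           "need a matrix of counts, at least 2x2")
  abort_if(any(table < 0) || any(table != floor(table)),
           "counts must be nonnegative integers")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  abort_if(any(rs == 0) || any(cs == 0),
           "zero marginal row or column: test undefined")
  expected <- outer(rs, cs) / n
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  new_test_result(stat, p, "Pearson chi-square", exact = FALSE,
                  note = sprintf("df = %d", df))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. A constant input vector makes the
#' coefficient undefined; `NA` is returned with a warning rather than an
#' error so correlation matrices over many proteins degrade gracefully.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A single correlation in [-1, 1], or `NA` if either input is
#'   constant.
#' @examples
#' spearman(1:4, c(2, 1, 4, 3))  # 0.6
#' @export
spearman <- function(x, y) {
  abort_if(length(x) != length(y), "x and y must have equal length")
  abort_if(length(x) < 3, "need at least 3 paired observations")
  abort_if(anyNA(x) || anyNA(y), "inputs must not contain NA")
  rx <- midrank(x); ry <- midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input: Spearman correlation undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

# Spearman correlation matrix over columns of a numeric matrix; constant
# columns give NA rows/columns (diagonal kept at 1 where defined).
spearman_matrix <- function(mat) {
  ranks <- apply(mat, 2, midrank)
  sds <- apply(ranks, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(ranks))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  cc
}

#' McNemar test for paired proportions
#'
#' Compares two paired diagnostic classifications through their discordant
#' counts `b` (first positive, second negative) and `c` (reverse). The exact
#' mode is the two-sided binomial test of b against Bin(b + c, 1/2); the
#' asymptotic mode is the continuity-corrected chi-square statistic
#' \eqn{(|b-c|-1)^2/(b+c)} on 1 df (the correction is required for the
#' chi-square p to track the exact binomial p at moderate counts).
#'
#' @param b,c nonnegative integer discordant counts.
#' @param mode `"exact"` (default) or `"asymptotic"`.
#' @return A `serosig_test`. When `b + c == 0` the p-value is 1 by
#'   convention and the result is flagged in `note`.
#' @examples
#' mcnemar(9, 1)  # p = 0.021484375
#' @export
mcnemar <- function(b, c, mode = c("exact", "asymptotic")) {
  mode <- match.arg(mode)
  abort_if(!is_count(b) || !is_count(c),
           "discordant counts must be nonnegative integers")
  n <- b + c
  if (n == 0) {
    return(new_test_result(0, 1, "McNemar", exact = mode == "exact",
                           note = "no discordant pairs; p = 1 by convention"))
  }
  if (mode == "exact") {
    k <- min(b, c)
    p <- min(1, 2 * stats::pbinom(k, n, 0.5))
    return(new_test_result(b - c, p, "McNemar", exact = TRUE))
  }
  stat <- (max(abs(b - c) - 1, 0))^2 / n
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  new_test_result(stat, p, "McNemar", exact = FALSE)
}
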