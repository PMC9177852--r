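# Exact and asymptotic 2x2 / rank statistics written from first principles.
# stats::fisher.test, chisq.test and wilcox.test are used in the test suite
# as independent oracles, never here.

as_table2x2 <- function(x) {
  if (is.matrix(x) && all(dim(x) == c(2, 2))) m <- x
  else if (is.numeric(x) && length(x) == 4) m <- matrix(x, 2, 2, byrow = TRUE)
  else abort("Expected a 2x2 matrix or a length-4 vector (a, b, c, d).")
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
    abort("Cell counts must be non-negative integers.")
  }
  m
}

#' Build a 2x2 contingency table from two positive counts
#'
#' Rows are the two groups, columns feature-positive / feature-negative.
#'
#' @param pos1,n1 Positives and total in group 1.
#' @param pos2,n2 Positives and total in group 2.
#' @return A 2x2 integer matrix.
#' @export
counts_to_table <- function(pos1, n1, pos2, n2) {
  as_table2x2(c(pos1, n1 - pos1, pos2, n2 - pos2))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on the hypergeometric distribution of the
#' top-left cell given fixed margins. The two-sided p-value uses the
#' probability-mass method: it sums the probabilities of all tables with
#' the same margins whose point probability does not exceed that of the
#' observed table (within a relative tolerance of 1e-7 for floating-point
#' ties). Point probabilities are computed in log-gamma arithmetic, stable
#' well beyond n = 1000. The statistic is the sample odds ratio `ad/bc`
#' (`Inf` when `bc = 0`).
#'
#' @param x A 2x2 matrix or length-4 vector `(a, b, c, d)` read row-wise.
#' @return A one-row tibble: `method`, `statistic` (odds ratio),
#'   `p_value`, `df` (`NA`).
#' @export
#' @examples
#' fisher_exact_two_sided(c(9, 8, 18, 1))
fisher_exact_two_sided <- function(x) {
  m <- as_table2x2(x)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  res <- function(p) tibble::tibble(
    method = "fisher_exact", statistic = if (b * c_ == 0 && a * d > 0) Inf
    else if (b * c_ == 0) NaN else (a * d) / (b * c_),
    p_value = p, df = NA_integer_
  )
  m1 <- a + b; m2 <- c_ + d; n1 <- a + c_; N <- m1 + m2
  if (m1 == 0 || m2 == 0 || n1 == 0 || n1 == N) {
    warn("Degenerate margin; p = 1 by convention.")
    return(res(1))
  }
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  support <- lo:hi
  lp <- lchoose(m1, support) + lchoose(m2, n1 - support) - lchoose(N, n1)
  lp_obs <- lp[support == a]
  p <- sum(exp(lp[lp <= lp_obs + log(1 + 1e-7)]))
  res(min(1, p))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's X-squared with 1 degree of freedom, without continuity
#' correction by default; the p-value comes from the chi-square survival
#' function.
#'
#' @param x A 2x2 matrix or length-4 vector `(a, b, c, d)`.
#' @param correct Apply the Yates continuity correction?
#' @return A one-row tibble: `method`, `statistic` (X-squared), `p_value`,
#'   `df`.
#' @export
chi_square <- function(x, correct = FALSE) {
  m <- as_table2x2(x)
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  if (any(rs == 0) || any(cs == 0)) abort("Zero margin: chi-square undefined.")
  E <- outer(rs, cs) / N
  dev <- abs(m - E)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / E)
  tibble::tibble(method = if (correct) "chi_square_yates" else "chi_square",
                 statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1L)
}

#' Choose between Fisher's exact test and chi-square
#'
#' The classical small-count rule: Fisher when any expected cell count
#' under independence is below 5 or any observed cell is zero, chi-square
#' otherwise.
#'
#' @param x A 2x2 matrix or length-4 vector.
#' @return `"fisher"` or `"chi2"`.
#' @export
select_test <- function(x) {
  m <- as_table2x2(x)
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  if (N == 0 || any(rs == 0) || any(cs == 0) || any(m == 0)) return("fisher")
  E <- outer(rs, cs) / N
  if (any(E < 5)) "fisher" else "chi2"
}

#' Run the selected 2x2 test
#'
#' Applies [select_test()] and dispatches to [fisher_exact_two_sided()] or
#' [chi_square()]; `force_fisher` overrides the selection.
#'
#' @inheritParams chi_square
#' @param force_fisher Always use Fisher's exact test?
#' @return A one-row result tibble.
#' @export
test_2x2 <- function(x, force_fisher = FALSE, correct = FALSE) {
  if (force_fisher || select_test(x) == "fisher") fisher_exact_two_sided(x)
  else chi_square(x, correct = correct)
}

# cached combn index matrices for the exact rank-sum path
.split_cache <- new.env(parent = emptyenv())

rank_sum_splits <- function(n, m) {
  key <- paste(n, m, sep = "_")
  if (is.null(.split_cache[[key]])) {
    .split_cache[[key]] <- utils::combn(n + m, n)
  }
  .split_cache[[key]]
}

#' One-sided two-sample rank-sum (Mann-Whitney) test
#'
#' Computes the Mann-Whitney U statistic for `x` versus `y` with midranks
#' for ties. When `n + m <= 12` (the default `exact = NULL` policy) the
#' p-value is exact: all `choose(n+m, n)` assignments of the pooled
#' observations to the two groups are enumerated and the p-value is the
#' fraction of assignments with U at least as large as observed (for
#' `alternative = "greater"`). This permutation enumeration is exact under
#' ties as well. For larger samples, a normal approximation with the tie
#' correction and a 0.5 continuity correction is used.
#'
#' Two constant, identical samples give p = 1 (every permutation ties the
#' observed U).
#'
#' @param x,y Numeric vectors (non-empty).
#' @param alternative `"greater"` (x stochastically greater), `"less"`, or
#'   `"two.sided"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the enumeration path;
#'   `NULL` chooses it when `n + m <= 12`.
#' @return A one-row tibble: `method`, `statistic` (U), `p_value`, `n_x`,
#'   `n_y`.
#' @export
#' @examples
#' rank_sum_test(c(0.3, 0.2, 0.1), c(0, 0, 0))  # exact p = 1/20
rank_sum_test <- function(x, y, alternative = c("greater", "less", "two.sided"),
                          exact = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(x) || anyNA(y)) {
    abort("`x` and `y` must be non-empty and free of NA.")
  }
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  use_exact <- if (is.null(exact)) N <= 12 else exact

  if (use_exact) {
    idx <- rank_sum_splits(n, m)
    u_all <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    tol <- 1e-9
    p <- switch(alternative,
      greater = mean(u_all >= u_obs - tol),
      less = mean(u_all <= u_obs + tol),
      two.sided = min(1, 2 * min(mean(u_all >= u_obs - tol),
                                 mean(u_all <= u_obs + tol)))
    )
    method <- "rank_sum_exact_enumeration"
  } else {
    mu <- n * m / 2
    ties <- table(pooled)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z_g <- (u_obs - mu - 0.5) / sqrt(sigma2)
      z_l <- (u_obs - mu + 0.5) / sqrt(sigma2)
      p <- switch(alternative,
        greater = stats::pnorm(z_g, lower.tail = FALSE),
        less = stats::pnorm(z_l),
        two.sided = min(1, 2 * min(stats::pnorm(z_g, lower.tail = FALSE),
                                   stats::pnorm(z_l)))
      )
    }
    method <- "rank_sum_normal_approximation"
  }
  tibble::tibble(method = method, statistic = u_obs, p_value = p,
                 n_x = n, n_y = m)
}

#' Shapiro-Wilk normality gate
#'
#' Records whether a frequency vector passes the Shapiro-Wilk normality
#' test (Royston's algorithm, 3 <= n <= 5000) at the given alpha. The
#' repertoire pipeline records the verdict but always proceeds with
#' nonparametric rank tests, which is the analysis branch a non-normal
#' verdict selects.
#'
#' @param values Non-constant numeric vector, 3 <= n <= 5000.
#' @param alpha Significance level.
#' @return A one-row tibble: `statistic` (W), `p_value`, `normal`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3 || length(values) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000.")
  }
  if (stats::sd(values) == 0) abort("Constant vector: normality undefined.")
  sw <- stats::shapiro.test(values)
  tibble::tibble(statistic = unname(sw$statistic), p_value = sw$p.value,
                 normal = sw$p.value >= alpha)
}
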