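## Rank and correlation statistics used throughout the pipeline.

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Computes U from midrank sums (ties counted half) and reports both
#' tails. For n1 + n2 <= 25 the p-values are exact: the permutation
#' distribution of the group-A rank sum over all choose(n1+n2, n1)
#' labelings is obtained by a subset-sum count over the (doubled,
#' hence integer) midranks, which conditions on the observed tie
#' pattern. Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param group_a,group_b Numeric vectors (nonempty).
#' @return List of class `rank_test`: `U`, `n1`, `n2`, `p_one_tailed`,
#'   `p_two_tailed`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be nonempty")
  n1 <- length(group_a); n2 <- length(group_b); n <- n1 + n2
  r <- rank(c(group_a, group_b))           # midranks
  ra <- sum(r[seq_len(n1)])
  ua <- ra - n1 * (n1 + 1) / 2
  ub <- n1 * n2 - ua
  U <- min(ua, ub)
  if (n <= 25L) {
    d2 <- as.integer(round(2 * r))         # doubled midranks, integers
    tot <- sum(d2)
    ## dp[k+1, s+1] = number of k-subsets of d2 with doubled-rank sum s
    dp <- matrix(0, nrow = n1 + 1L, ncol = tot + 1L)
    dp[1L, 1L] <- 1
    for (v in d2) {
      kmax <- n1
      for (k in kmax:1) {
        idx <- seq_len(tot + 1L - v)
        dp[k + 1L, idx + v] <- dp[k + 1L, idx + v] + dp[k, idx]
      }
    }
    cnt <- dp[n1 + 1L, ]                   # distribution of doubled R_a
    total <- sum(cnt)                      # = choose(n, n1)
    ## doubled U_a for each achievable doubled rank sum
    s <- seq_along(cnt) - 1L
    ua2 <- s - n1 * (n1 + 1)               # 2 * U_a
    obs2 <- as.integer(round(2 * ua))
    p_low <- sum(cnt[ua2 <= obs2]) / total
    p_high <- sum(cnt[ua2 >= obs2]) / total
    p_one <- if (ua <= ub) p_low else p_high
    lim2 <- as.integer(round(2 * (n1 * n2 - U)))
    u_obs2 <- as.integer(round(2 * U))
    p_two <- min(1, sum(cnt[ua2 <= u_obs2]) / total +
                    sum(cnt[ua2 >= lim2]) / total)
    if (ua == ub) p_two <- 1
    method <- "exact"
  } else {
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    z <- (U + 0.5 - n1 * n2 / 2) / sqrt(sigma2)
    p_one <- stats::pnorm(z)
    p_two <- min(1, 2 * p_one)
    method <- "normal_approx"
  }
  structure(list(U = U, U_a = ua, U_b = ub, n1 = n1, n2 = n2,
                 p_one_tailed = p_one, p_two_tailed = p_two,
                 method = method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.3f (n1 = %d, n2 = %d, %s)\n",
              x$U, x$n1, x$n2, x$method),
      sprintf("  one-tailed p = %.4f, two-tailed p = %.4f\n",
              x$p_one_tailed, x$p_two_tailed), sep = "")
  invisible(x)
}

.cor_result <- function(method, r, n, df, tail) {
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- switch(tail,
              negative = stats::pt(t, df),
              positive = stats::pt(t, df, lower.tail = FALSE))
  structure(list(method = method, r = r, n = n, df = df, t = t,
                 tail = tail, p_one_tailed = p),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("%s correlation r = %.4f (n = %d, d.f. = %d)\n",
              x$method, x$r, x$n, x$df),
      sprintf("  t = %.4f, one-tailed (%s) p = %.4f\n",
              x$t, x$tail, x$p_one_tailed), sep = "")
  invisible(x)
}

#' One-tailed Pearson correlation
#'
#' Product-moment correlation with the t test on n - 2 degrees of
#' freedom, evaluated in a single prespecified tail.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite, with
#'   nonzero variance.
#' @param tail `"negative"` or `"positive"`: the direction predicted a
#'   priori.
#' @return A `cor_result` list: `method`, `r`, `n`, `df`, `t`, `tail`,
#'   `p_one_tailed`.
#' @export
pearson_one_tailed <- function(x, y, tail = c("negative", "positive")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  r <- stats::cor(x, y)
  .cor_result("pearson", r, length(x), length(x) - 2L, tail)
}

#' One-tailed Spearman rank correlation
#'
#' Pearson correlation of midranked data; the p-value uses the same t
#' approximation on n - 2 degrees of freedom as the parametric test
#' (the convention of classical comparative analyses), not an exact
#' permutation of ranks.
#'
#' @inheritParams pearson_one_tailed
#' @return A `cor_result` with `method = "spearman"`.
#' @export
spearman_one_tailed <- function(x, y, tail = c("negative", "positive")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined: zero variance in ranks")
  r <- stats::cor(rx, ry)
  res <- .cor_result("spearman", r, length(x), length(x) - 2L, tail)
  res
}

#' Through-origin correlation (for standardized contrasts)
#'
#' Correlation constrained through the origin,
#' r = sum(xy) / sqrt(sum(x^2) sum(y^2)), with n - 1 degrees of
#' freedom. Appropriate for independent contrasts, whose expectation is
#' zero and whose signs are arbitrary (the statistic is invariant to
#' flipping both members of any pair).
#'
#' @inheritParams pearson_one_tailed
#' @return A `cor_result` with `method = "pearson_through_origin"` and
#'   `df = n - 1`.
#' @export
origin_correlation <- function(x, y, tail = c("negative", "positive")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 contrast pairs")
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0)
    stop("correlation undefined: zero sum of squares")
  r <- sum(x * y) / sqrt(sx * sy)
  .cor_result("pearson_through_origin", r, length(x), length(x) - 1L, tail)
}

#' Combine per-tRNA correlations across families
#'
#' Meta-combination of k independent correlation results: the pooled
#' effect is the inverse Fisher transform of the (n_i - 3)-weighted mean
#' of atanh(r_i); the combined evidence is Stouffer's unweighted sum of
#' probit-transformed one-tailed p-values, Z = sum(qnorm(1 - p_i)) /
#' sqrt(k), with p_combined = 1 - pnorm(Z).
#'
#' @param studies Data frame (or list of lists) with columns/fields
#'   `r`, `n`, `p_one_tailed`, and optionally `label`.
#' @return List of class `meta_result`: `studies`, `r_weighted`,
#'   `Z_stouffer`, `p_combined`, `k`.
#' @export
combine_correlations <- function(studies) {
  if (!is.data.frame(studies))
    studies <- do.call(rbind, lapply(studies, function(s)
      data.frame(label = if (is.null(s$label)) NA_character_ else s$label,
                 r = s$r, n = s$n, p_one_tailed = s$p_one_tailed)))
  small <- studies$n < 4L
  if (any(small)) {
    warning(sum(small), " study(ies) with n < 4 dropped from meta-analysis")
    studies <- studies[!small, , drop = FALSE]
  }
  if (!nrow(studies)) stop("no studies with n >= 4")
  if (any(abs(studies$r) >= 1))
    stop("|r| = 1 gives an infinite Fisher z; cannot combine")
  w <- studies$n - 3
  r_weighted <- tanh(sum(w * atanh(studies$r)) / sum(w))
  k <- nrow(studies)
  Z <- sum(stats::qnorm(1 - studies$p_one_tailed)) / sqrt(k)
  structure(list(studies = studies, r_weighted = r_weighted,
                 Z_stouffer = Z, p_combined = 1 - stats::pnorm(Z), k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Meta-analysis of %d correlation(s)\n", x$k),
      sprintf("  weighted Fisher r = %.4f\n", x$r_weighted),
      sprintf("  Stouffer Z = %.4f, combined p = %.4f\n",
              x$Z_stouffer, x$p_combined), sep = "")
  invisible(x)
}
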