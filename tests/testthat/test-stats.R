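test_that("U statistic: separation, ties, and basic identities", {
  u <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_identical(u$U, 0)
  expect_identical(u$U_a + u$U_b, 4)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
  # U is invariant under common monotone transforms
  set.seed(5)
  a <- rnorm(7); b <- rnorm(9)
  expect_identical(mann_whitney_u(a, b)$U,
                   mann_whitney_u(exp(a), exp(b))$U)
  expect_identical(mann_whitney_u(a, b)$U,
                   mann_whitney_u(rank(c(a, b))[1:7],
                                  rank(c(a, b))[8:16])$U)
})

test_that("exact p equals brute-force enumeration, with and without ties", {
  enum_p <- function(a, b) {
    n1 <- length(a); n <- n1 + length(b)
    r <- rank(c(a, b))
    cmb <- utils::combn(n, n1)
    ra <- colSums(matrix(r[cmb], nrow = n1))
    ua <- ra - n1 * (n1 + 1) / 2
    umin <- pmin(ua, n1 * length(b) - ua)
    obs <- mann_whitney_u(a, b)
    list(p1 = if (obs$U_a <= obs$U_b) mean(ua <= obs$U_a)
              else mean(ua >= obs$U_a),
         p2 = mean(umin <= obs$U))
  }
  set.seed(11)
  for (i in 1:5) {
    a <- sample(1:20, 8, replace = TRUE)  # replacement forces ties
    b <- sample(1:20, 8, replace = TRUE)
    got <- mann_whitney_u(a, b)
    expect_identical(got$method, "exact")
    ora <- enum_p(a, b)
    expect_equal(got$p_one_tailed, ora$p1, tolerance = 1e-12, info = i)
    expect_equal(got$p_two_tailed, min(1, ora$p2), tolerance = 1e-12,
                 info = i)
  }
  # large samples switch to the tie-corrected normal approximation
  big <- mann_whitney_u(rnorm(15), rnorm(15))
  expect_identical(big$method, "normal_approx")
})

test_that("exact U distribution is a proper probability distribution", {
  # all labelings enumerated: lower + strict-upper tails of U_a sum to 1
  a <- c(3.2, 1.1, 7.4, 5.5); b <- c(2.0, 9.9, 4.4, 6.1, 0.5)
  u <- mann_whitney_u(a, b)
  # P(U_a <= k) + P(U_a > k) = 1 via complementary calls on flipped data
  r <- rank(c(a, b))
  cmb <- utils::combn(9, 4)
  ua <- colSums(matrix(r[cmb], nrow = 4)) - 10
  expect_equal(mean(ua <= u$U_a) + mean(ua > u$U_a), 1)
})

test_that("pearson matches the definitional formula; tails behave", {
  set.seed(21)
  x <- rnorm(20); y <- rnorm(20)
  got <- pearson_one_tailed(x, y, "negative")
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_def, tolerance = 1e-12)
  expect_identical(got$df, 18L)
  up <- pearson_one_tailed(x, 2 * x + 1, "positive")
  expect_equal(up$r, 1)
  expect_lt(up$p_one_tailed, 1e-6)
  dn <- pearson_one_tailed(x, -x, "negative")
  expect_equal(dn$r, -1)
  expect_error(pearson_one_tailed(x, rep(1, 20)), "zero variance")
  expect_error(pearson_one_tailed(1:2, 1:2), "at least 3")
  # symmetric in its arguments
  expect_equal(pearson_one_tailed(x, y, "negative")$r,
               pearson_one_tailed(y, x, "negative")$r)
  # affine maps: positive slope preserves, negative slope negates
  expect_equal(pearson_one_tailed(2 * x + 3, y, "negative")$r, got$r)
  expect_equal(pearson_one_tailed(-x, y, "negative")$r, -got$r)
})

test_that("spearman uses midranks and the t approximation", {
  x <- c(1, 1, 2); y <- c(1, 2, 3)
  got <- spearman_one_tailed(x, y, "positive")
  # hand ranks: x -> (1.5, 1.5, 3), y -> (1, 2, 3)
  expect_equal(got$r, stats::cor(c(1.5, 1.5, 3), c(1, 2, 3)),
               tolerance = 1e-12)
  mono <- spearman_one_tailed(1:10, (1:10)^3, "positive")
  expect_equal(mono$r, 1)
  # t approximation is close to the exhaustive permutation p at n = 8
  set.seed(33)
  x8 <- rnorm(8); y8 <- rnorm(8)
  obs <- spearman_one_tailed(x8, y8, "positive")
  # enumerate all 8! permutations of the y ranks
  permute <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  ry <- rank(y8); rx <- rank(x8)
  rs <- vapply(permute(ry), function(p) stats::cor(rx, p), numeric(1))
  p_perm <- mean(rs >= obs$r)
  expect_lt(abs(p_perm - obs$p_one_tailed), 0.03)
})

test_that("through-origin correlation: definition and invariances", {
  set.seed(41)
  x <- rnorm(12); y <- 0.6 * x + rnorm(12, sd = 0.3)
  got <- origin_correlation(x, y, "positive")
  expect_equal(got$r, sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
               tolerance = 1e-14)
  expect_identical(got$df, 11L)
  # perfect proportionality through zero
  expect_equal(origin_correlation(x, 3 * x, "positive")$r, 1)
  # flipping both members of any pair leaves r unchanged
  flip <- sample(c(-1, 1), 12, replace = TRUE)
  expect_equal(origin_correlation(flip * x, flip * y, "positive")$r,
               got$r, tolerance = 1e-14)
})

test_that("meta-combination identities", {
  studies <- data.frame(r = rep(0.3, 5), n = rep(10L, 5),
                        p_one_tailed = rep(0.2, 5))
  m <- combine_correlations(studies)
  expect_equal(m$r_weighted, 0.3, tolerance = 1e-12)
  expect_identical(m$k, 5L)
  half <- data.frame(r = c(0.1, -0.2), n = c(10L, 12L),
                     p_one_tailed = c(0.5, 0.5))
  expect_equal(combine_correlations(half)$Z_stouffer, 0)
  expect_equal(combine_correlations(half)$p_combined, 0.5)
  anti <- data.frame(r = c(0.5, -0.5), n = c(10L, 10L),
                     p_one_tailed = c(0.1, 0.9))
  expect_equal(combine_correlations(anti)$r_weighted, 0,
               tolerance = 1e-12)
  single <- data.frame(r = 0.4, n = 20L, p_one_tailed = 0.05)
  s <- combine_correlations(single)
  expect_equal(s$r_weighted, 0.4, tolerance = 1e-12)
  expect_equal(s$p_combined, 0.05, tolerance = 1e-12)
  expect_warning(
    dropped <- combine_correlations(
      data.frame(r = c(0.4, 0.9), n = c(20L, 3L),
                 p_one_tailed = c(0.05, 0.01))),
    "dropped")
  expect_identical(dropped$k, 1L)
  expect_error(combine_correlations(
    data.frame(r = 1, n = 10L, p_one_tailed = 0.01)), "infinite")
})
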