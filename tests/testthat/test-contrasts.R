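test_that("log transform, pseudocount, and round trip", {
  v <- c(A = 1, B = 10, C = 100)
  expect_equal(unclass(log_transform(v)), c(A = 0, B = 1, C = 2),
               ignore_attr = TRUE)
  expect_error(log_transform(c(A = 0)), "pseudocount")
  z <- log_transform(c(A = 0, B = 1), pseudocount = 0.5 / 1000)
  expect_true(all(is.finite(z)))
  expect_identical(attr(z, "n_pseudocount"), 1L)
  expect_error(log_transform(c(A = -1)), "negative")
  x <- c(A = 0.3, B = 7, C = 19)
  expect_equal(10^log_transform(x), x, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("two- and three-tip trees match the closed forms", {
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  ic2 <- independent_contrasts(tr2, c(A = 0, B = 2), c(A = 5, B = 1))
  expect_identical(nrow(ic2), 1L)
  expect_equal(ic2$contrast_x, 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(ic2$contrast_y, -4 / sqrt(2), tolerance = 1e-12)
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  x <- c(A = 1.3, B = 0.2, C = 2.9); y <- c(A = 0.5, B = 2.2, C = 1.1)
  ic3 <- independent_contrasts(tr3, x, y)
  expect_identical(nrow(ic3), 2L)
  # cherry contrast (xA - xB)/sqrt(2); basal contrast uses the
  # extended branch: mean(cherry) vs C over sqrt(1.5 + 1)
  got <- ic3[order(ic3$sd), ]
  sign1 <- sign(x[["A"]] - x[["B"]])
  expect_equal(got$contrast_x[1], sign1 * (x[["A"]] - x[["B"]]) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(got$contrast_y[1], sign1 * (y[["A"]] - y[["B"]]) / sqrt(2),
               tolerance = 1e-12)
  mx <- mean(x[c("A", "B")]); my <- mean(y[c("A", "B")])
  sign2 <- sign(mx - x[["C"]])
  expect_equal(got$contrast_x[2], sign2 * (mx - x[["C"]]) / sqrt(2.5),
               tolerance = 1e-12)
  expect_equal(got$contrast_y[2], sign2 * (my - y[["C"]]) / sqrt(2.5),
               tolerance = 1e-12)
})

test_that("contrasts agree with the reference implementation", {
  set.seed(91)
  for (n in c(5L, 9L, 17L)) {
    tr <- ape::rtree(n)
    x <- stats::setNames(rnorm(n), tr$tip.label)
    y <- stats::setNames(rnorm(n), tr$tip.label)
    ic <- independent_contrasts(tr, x, y)
    expect_identical(nrow(ic), n - 1L)
    ref <- ape::pic(x, tr)
    expect_equal(sort(abs(ic$contrast_x)), sort(abs(unname(ref))),
                 tolerance = 1e-10)
    refy <- ape::pic(y, tr)
    expect_equal(sort(abs(ic$contrast_y)), sort(abs(unname(refy))),
                 tolerance = 1e-10)
  }
})

test_that("through-origin contrast correlation equals the GLS oracle", {
  set.seed(92)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    x <- stats::setNames(rnorm(n), tr$tip.label)
    y <- stats::setNames(rnorm(n), tr$tip.label)
    ic <- independent_contrasts(tr, x, y)
    r_ic <- contrast_correlation(ic, tail = "negative")$r
    expect_equal(r_ic, gls_correlation(tr, x, y), tolerance = 1e-10,
                 info = rep)
  }
})

test_that("contrasts are shift-invariant and sign-oriented", {
  set.seed(93)
  tr <- ape::rtree(10)
  x <- stats::setNames(rnorm(10), tr$tip.label)
  y <- stats::setNames(rnorm(10), tr$tip.label)
  ic1 <- independent_contrasts(tr, x, y)
  ic2 <- independent_contrasts(tr, x + 100, y - 42)
  expect_equal(ic1$contrast_x, ic2$contrast_x, tolerance = 1e-10)
  expect_equal(ic1$contrast_y, ic2$contrast_y, tolerance = 1e-10)
  expect_true(all(ic1$contrast_x >= 0))
  # orientation does not affect the through-origin correlation
  expect_equal(contrast_correlation(ic1, tail = "negative")$r,
               {
                 flipped <- ic1
                 flipped$contrast_x <- -flipped$contrast_x
                 flipped$contrast_y <- -flipped$contrast_y
                 contrast_correlation(flipped, tail = "negative")$r
               }, tolerance = 1e-14)
})

test_that("polytomies and label mismatches are rejected", {
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  vals <- c(A = 1, B = 2, C = 3)
  expect_error(independent_contrasts(poly, vals, vals), "polytom")
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  expect_error(independent_contrasts(tr, vals[-1], vals), "differ")
  expect_error(independent_contrasts(tr, c(vals, D = 4), vals), "differ")
  # unit branch lengths are substituted when absent
  nb <- ape::read.tree(text = "((A,B),C);")
  ic <- independent_contrasts(nb, vals, vals)
  expect_equal(ic$sd[order(ic$sd)][1], sqrt(2), tolerance = 1e-12)
})

test_that("parameter recovery: correlated Brownian data on a tree", {
  # moderate-size check; the full calibration lives in the acceptance
  # suite
  rs <- vapply(1:40, function(i) {
    tr <- simulate_tree(33L, seed = 400L + i)
    tv <- simulate_bm_tips(tr, rho = -0.4, seed = 900L + i)
    ic <- independent_contrasts(tr, tv[, "x"], tv[, "y"])
    contrast_correlation(ic, tail = "negative")$r
  }, numeric(1))
  expect_lt(abs(mean(rs) + 0.4), 0.08)
})
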