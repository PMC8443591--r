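test_that("plug-in Shannon index matches closed forms", {
  x <- matrix(rep(1, 8), 2, 4)          # uniform over 4 taxa
  expect_equal(unname(shannon(x)), rep(log(4), 2))
  expect_equal(unname(shannon(matrix(c(7, 0, 0), 1, 3))), 0)
  expect_equal(unname(shannon(matrix(c(0.5, 0.25, 0.25), 1, 3))),
               1.0397, tolerance = 1e-4)
  expect_error(shannon(matrix(c(1, -1), 1, 2)), "nonnegative")
  expect_error(shannon(matrix(c(0, 0), 1, 2)), "all-zero")
})

test_that("diversity correlations rank by significance with BH control", {
  set.seed(20)
  n <- 30
  div <- runif(n, 1, 3)
  blk <- cbind(same = div, noise1 = rnorm(n), noise2 = rnorm(n),
               flat = rep(1, n))
  expect_warning(out <- metabolite_diversity_correlations(blk, div), NA)
  expect_equal(out$feature[1], "same")
  expect_equal(out$r[1], 1, tolerance = 1e-12)
  expect_equal(attr(out, "excluded"), "flat")
  expect_true(!is.unsorted(out$p_value))
  # closed-form oracle on a 5-point fixture
  x5 <- c(1, 3, 2, 5, 4); d5 <- c(2, 1, 4, 3, 5)
  out5 <- metabolite_diversity_correlations(matrix(x5, 5, 1), d5)
  r_oracle <- sum((x5 - mean(x5)) * (d5 - mean(d5))) /
    sqrt(sum((x5 - mean(x5))^2) * sum((d5 - mean(d5))^2))
  expect_equal(out5$r, r_oracle, tolerance = 1e-12)
  t_o <- r_oracle * sqrt(3) / sqrt(1 - r_oracle^2)
  expect_equal(out5$p_value, 2 * pt(-abs(t_o), 3), tolerance = 1e-12)
})

test_that("independent metabolites stay below the null correlation bound", {
  exceed <- vapply(1:20, function(s) {
    set.seed(600 + s)
    div <- rnorm(134)
    abs(cor(rnorm(134), div)) >= 0.25
  }, logical(1))
  expect_lte(sum(exceed), 1)   # |r| < 0.25 in at least 19/20 seeds
})

test_that("PLS1 recovers exact fits and the analytic first direction", {
  set.seed(21)
  # response an exact linear function of the single predictor
  x1 <- matrix(rnorm(40), 40, 1)
  fit <- pls_variance_explained(x1, 2 * x1[, 1] + 1, n_components = 1,
                                seed = 1)
  expect_equal(fit$r2y[1], 1, tolerance = 1e-10)
  x <- matrix(rnorm(40 * 6), 40, 6)
  # first PLS1 weight vector is proportional to t(X) %*% y
  y2 <- rnorm(40)
  f2 <- pls_variance_explained(x, y2, n_components = 1, seed = 1)
  w <- f2$weights[, 1]
  a <- drop(crossprod(scale(x), y2 - mean(y2)))
  expect_gt(abs(sum(w * a) / sqrt(sum(w^2) * sum(a^2))), 1 - 1e-8)
})

test_that("R2Y is invariant to response rescaling and Q2 punishes noise", {
  set.seed(22)
  x <- matrix(rnorm(50 * 10), 50, 10)
  y <- x[, 1] + rnorm(50, sd = 0.5)
  f1 <- pls_variance_explained(x, y, n_components = 2, seed = 3)
  f2 <- pls_variance_explained(x, 100 * y - 7, n_components = 2, seed = 3)
  expect_equal(f1$r2y, f2$r2y, tolerance = 1e-10)
  expect_true(all(diff(f1$r2y) >= -1e-10) && all(f1$r2y <= 1 + 1e-10))
  # pure-noise response: cross-validated Q2 at or below zero in median
  q2 <- vapply(1:20, function(s) {
    set.seed(700 + s)
    pls_variance_explained(matrix(rnorm(40 * 15), 40, 15), rnorm(40),
                           n_components = 1, seed = s)$q2[1]
  }, numeric(1))
  expect_lte(median(q2), 0)
})

test_that("planted explained variance is recovered at cohort size", {
  fits <- vapply(1:10, function(s) {
    set.seed(800 + s)
    x <- matrix(rnorm(134 * 40), 134, 40)
    signal <- drop(x[, 1:5] %*% rep(1, 5)) / sqrt(5)
    y <- signal + rnorm(134)            # true R2 = 0.5
    f <- pls_variance_explained(x, y, n_components = 2, seed = s)
    c(f$r2y[1], f$q2[2])
  }, numeric(2))
  expect_lt(abs(median(fits[1, ]) - 0.5), 0.1)
  # cross-validated Q2 is the conservative counterpart: below R2Y, above 0
  expect_true(all(fits[2, ] < fits[1, ]))
  expect_gt(median(fits[2, ]), 0)
})

test_that("component count is truncated at the block rank with a warning", {
  x <- matrix(rnorm(20), 10, 2)
  y <- x[, 1] + x[, 2]
  expect_warning(fit <- pls_variance_explained(x, y, n_components = 5),
                 "truncat")
  expect_lte(fit$n_components, 2)
})
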