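test_that("confounder residualization is a least-squares projection", {
  g <- factor(rep(c("a", "b"), each = 3))
  x <- cbind(v1 = c(1, 1, 1, 3, 3, 3), v2 = c(0, 1, 2, 4, 5, 6))
  r <- residualize_on_confounder(x, g)
  expect_equal(unname(colMeans(r[1:3, ])), c(0, 0))
  expect_equal(unname(colMeans(r[4:6, ])), c(0, 0))
  # orthogonal to the group indicator
  ind <- as.numeric(g == "b") - mean(g == "b")
  expect_lt(max(abs(crossprod(r, ind))), 1e-10)
  # explicit lm oracle
  oracle <- apply(x, 2, function(col) stats::resid(stats::lm(col ~ g)))
  expect_equal(unname(r), unname(oracle), tolerance = 1e-12)
  expect_warning(residualize_on_confounder(x, factor(c(1, 2, 2, 2, 2, 2))),
                 "size 1")
})

test_that("L1 projection kernel matches a bisection oracle and is monotone", {
  oracle <- function(a, c) {
    soft <- function(a, d) sign(a) * pmax(abs(a) - d, 0)
    unit <- function(v) { n <- sqrt(sum(v^2)); if (n == 0) v else v / n }
    u <- unit(a)
    if (sum(abs(u)) <= c) return(u)
    lo <- 0; hi <- max(abs(a))
    for (i in 1:300) {
      mid <- (lo + hi) / 2
      s <- sum(abs(unit(soft(a, mid))))
      if (s > c || s == 0) lo <- mid else hi <- mid
    }
    unit(soft(a, hi))
  }
  set.seed(12)
  for (i in 1:50) {
    p <- sample(2:30, 1)
    a <- rnorm(p) * 10^runif(1, -2, 2)
    cc <- runif(1, 1, sqrt(p))
    u <- skinomics:::l1_project(a, cc)
    expect_equal(u, oracle(a, cc), tolerance = 1e-7)
    expect_lte(sum(abs(u)), cc + 1e-6)
    expect_equal(sum(u^2), 1, tolerance = 1e-9)
  }
  # support monotonicity: shrinking c never grows the support
  a <- rnorm(40)
  supp <- vapply(seq(sqrt(40), 1, length.out = 15), function(cc)
    sum(skinomics:::l1_project(a, cc) != 0), numeric(1))
  expect_true(all(diff(supp) <= 0))
})

test_that("rank-1 PMD solves trivial, toy and unconstrained cases", {
  # single shared feature
  x <- scale(matrix(rnorm(30), 30, 1))
  f <- pmd_rank1(x, x, c1 = 1, c2 = 1)
  expect_equal(abs(unname(f$u)), 1)
  expect_equal(f$rho, 1, tolerance = 1e-12)

  # 2-feature toy with strongly unbalanced cross-covariance and tight L1:
  # support concentrates on the dominant feature; objective matches an
  # exhaustive grid search over the L1-feasible unit circle
  set.seed(13)
  X <- scale(matrix(rnorm(100), 50, 2))
  Y <- scale(cbind(X[, 1] * 5 + rnorm(50, sd = 0.1),
                   X[, 2] + rnorm(50, sd = 2)))
  f <- pmd_rank1(X, Y, c1 = 1, c2 = 1)
  expect_equal(f$support_x, 1L, ignore_attr = TRUE)
  expect_equal(f$support_y, 1L, ignore_attr = TRUE)
  Z <- crossprod(X, Y)
  best <- -Inf
  for (th in seq(0, 2 * pi, length.out = 361)) {
    u <- c(cos(th), sin(th))
    if (sum(abs(u)) > 1 + 1e-9) next
    for (ph in seq(0, 2 * pi, length.out = 361)) {
      v <- c(cos(ph), sin(ph))
      if (sum(abs(v)) > 1 + 1e-9) next
      best <- max(best, drop(t(u) %*% Z %*% v))
    }
  }
  expect_equal(tail(f$objective, 1), best, tolerance = 1e-3)

  # inactive L1 bounds: matches the leading singular pair of t(X) %*% Y
  set.seed(14)
  for (i in 1:20) {
    X <- scale(matrix(rnorm(100), 20, 5))
    Y <- scale(matrix(rnorm(100), 20, 5))
    f <- pmd_rank1(X, Y)
    sv <- svd(crossprod(X, Y))
    expect_gt(abs(sum(f$u * sv$u[, 1])), 0.999)
    expect_gt(abs(sum(f$v * sv$v[, 1])), 0.999)
  }
})

test_that("PMD objective is nondecreasing and norms respect constraints", {
  set.seed(15)
  for (i in 1:10) {
    X <- scale(matrix(rnorm(40 * 12), 40, 12))
    Y <- scale(matrix(rnorm(40 * 9), 40, 9))
    f <- pmd_rank1(X, Y, c1 = 1.8, c2 = 1.5)
    expect_true(all(diff(f$objective) >= -1e-9))
    expect_lte(sum(abs(f$u)), 1.8 + 1e-6)
    expect_lte(sum(abs(f$v)), 1.5 + 1e-6)
    expect_lte(sum(f$u^2), 1 + 1e-9)
    expect_lte(sum(f$v^2), 1 + 1e-9)
    expect_true(f$rho >= -1 && f$rho <= 1)
  }
})

test_that("permutation tuning detects a planted pair at floor p-value", {
  co <- generate_cohort(cohort_spec(
    n_per_group = 100, n_metabolites = 60, n_pah = 40, n_otu = 20,
    n_latent_factors = 1, sparse_support_size = 8,
    canonical_correlation = 0.8, city_effect_size = 0,
    cluster_separation = 0, seed = 21))
  pt <- permute_tune(log(co$blocks$pah$x), log(co$blocks$metabolites$x),
                     nperms = 100, seed = 21)
  expect_equal(pt$p_value, 1 / 101)   # minimum resolvable
  expect_gt(jaccard(pt$pair$support_y,
                    co$truth$active_feature_sets$metabolites$pair_pah), 0.4)
  expect_true(pt$p_value >= 1 / (pt$nperms + 1) && pt$p_value <= 1)
})

test_that("permuting both blocks identically leaves the correlation fixed", {
  set.seed(16)
  X <- scale(matrix(rnorm(60 * 6), 60, 6))
  Y <- scale(matrix(rnorm(60 * 7), 60, 7))
  f0 <- pmd_rank1(X, Y, c1 = 1.5, c2 = 1.5)
  idx <- sample.int(60)
  f1 <- pmd_rank1(X[idx, ], Y[idx, ], c1 = 1.5, c2 = 1.5)
  expect_equal(f1$rho, f0$rho, tolerance = 1e-8)
})

test_that("cross-correlation matches the textbook formula", {
  set.seed(17)
  x <- matrix(rnorm(10), 5, 2)
  y <- cbind(x[, 1], -x[, 1], rnorm(5))
  cc <- cross_correlation(x, y)
  expect_equal(cc[1, 1], 1)
  expect_equal(cc[1, 2], -1)
  oracle <- function(a, b)
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  for (i in 1:2) for (j in 1:3)
    expect_equal(cc[i, j], oracle(x[, i], y[, j]), tolerance = 1e-12)
  # zero-variance feature propagates as missing
  y0 <- cbind(y, rep(2, 5))
  expect_true(all(is.na(suppressWarnings(cross_correlation(x, y0))[, 4])))
})
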