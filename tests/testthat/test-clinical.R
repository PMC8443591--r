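test_that("PAH score is the first PC of log concentrations, sign-fixed", {
  # single-PAH block: score equals the standardized log concentrations
  x <- matrix(exp(c(1, 2, 3, 4, 5)), ncol = 1,
              dimnames = list(paste0("S", 1:5), "pah1"))
  ps <- pah_score(x)
  expect_equal(unname(ps$scores), as.numeric(scale(log(x))),
               tolerance = 1e-10)
  expect_equal(ps$variance_explained_pc1, 1)

  # eigendecomposition oracle on a 5 x 3 hand matrix
  set.seed(1)
  m <- matrix(exp(rnorm(15)), 5, 3)
  ps <- pah_score(m)
  z <- scale(log(m))
  ev <- eigen(crossprod(z) / 4)
  sc <- drop(z %*% ev$vectors[, 1])
  if (cor(sc, rowMeans(log(m))) < 0) sc <- -sc
  expect_equal(unname(ps$scores), sc, tolerance = 1e-10)
  expect_equal(ps$variance_explained_pc1, ev$values[1] / sum(ev$values),
               tolerance = 1e-10)

  # planted common factor dominates the score
  set.seed(2)
  f <- rnorm(80)
  blk <- exp(outer(f, rep(1, 10)) + matrix(rnorm(800, sd = 0.4), 80, 10))
  expect_gt(abs(cor(pah_score(blk)$scores, f)), 0.9)

  expect_error(pah_score(matrix(c(-1, 1, 2, 3), 2, 2)), "lod_impute")
})

test_that("median split sends ties below and balances even cohorts", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("below", "below", "above", "above"))
  co <- generate_cohort(cohort_spec(seed = 6))
  grp <- median_split(pah_score(co$blocks$pah)$scores)
  expect_equal(unname(table(grp)), c(67L, 67L), ignore_attr = TRUE)
  expect_warning(grp0 <- median_split(rep(1, 5)), "median")
  expect_true(all(grp0 == "below"))
})

test_that("ordinal Wilcoxon reproduces the published two-city p-values", {
  expect_equal(
    round(wilcoxon_ordinal(rbind(c(63, 2, 2, 0), c(50, 12, 2, 3)))$p_value,
          4), 0.0029)
  expect_equal(
    round(wilcoxon_ordinal(rbind(c(41, 23, 2, 1), c(31, 21, 13, 2)))$p_value,
          4), 0.0212)
  # identical group distributions: z = 0, p = 1
  r <- wilcoxon_ordinal(rbind(c(5, 3, 2), c(5, 3, 2)))
  expect_equal(r$z_or_chi2, 0)
  expect_equal(r$p_value, 1)
  expect_error(wilcoxon_ordinal(rbind(c(0, 0), c(1, 2))), "at least one")
})

test_that("Wilcoxon agrees with enumeration and permutation oracles", {
  tabs <- list(rbind(c(3, 2, 1), c(2, 1, 3)),
               rbind(c(4, 1, 1), c(1, 3, 2)),
               rbind(c(5, 0, 1), c(1, 4, 1)))
  for (tab in tabs) {
    # small-sample approximation bound against exhaustive enumeration
    expect_lt(abs(wilcoxon_ordinal(tab)$p_value - wilcoxon_exact_p(tab)),
              0.2)
  }
  # at realistic group sizes the t-approximation is close to the
  # permutation distribution
  tab <- rbind(c(20, 7, 3), c(12, 11, 7))
  expect_lt(abs(wilcoxon_ordinal(tab)$p_value -
                  wilcoxon_mc_p(tab, nsim = 40000, seed = 2)), 0.02)
})

test_that("Wilcoxon rank statistic ignores category spacing and its tie
           correction vanishes without ties", {
  # the statistic depends only on the ordered table, so any strictly
  # increasing relabeling of the category scores leaves it unchanged;
  # splitting an empty category in or out must not matter either
  tab <- rbind(c(6, 2, 4, 1), c(2, 5, 3, 4))
  tab_pad <- cbind(tab[, 1:2], c(0, 0), tab[, 3:4])
  expect_equal(wilcoxon_ordinal(tab)$p_value,
               wilcoxon_ordinal(tab_pad)$p_value, tolerance = 1e-12)
  # untied data: one subject per category; compare with the classical
  # untied normal-approximation formula
  n1 <- 5; n2 <- 5; N <- 10
  tab1 <- matrix(0, 2, N)
  tab1[1, 1:5] <- 1; tab1[2, 6:10] <- 1
  r <- wilcoxon_ordinal(tab1, method = "wilcoxon_normal")
  S <- sum(1:5); E <- n1 * (N + 1) / 2
  V <- n1 * n2 * (N + 1) / 12
  z <- (S - E + 0.5) / sqrt(V)
  expect_equal(r$z_or_chi2, z, tolerance = 1e-12)
})

test_that("binary chi-squared reproduces the published p-values", {
  expect_equal(round(chi2_binary(rbind(c(17, 50), c(9, 58)))$p_value, 4),
               0.0805)
  expect_equal(round(chi2_binary(rbind(c(65, 2), c(61, 6)))$p_value, 4),
               0.1447)
  r <- chi2_binary(rbind(c(10, 20), c(10, 20)))
  expect_equal(r$z_or_chi2, 0)
  expect_equal(r$p_value, 1)
  expect_error(chi2_binary(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("chi-squared equals the squared two-proportion z-statistic", {
  tab <- rbind(c(14, 53), c(28, 39))
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  p1 <- tab[1, 2] / n1; p2 <- tab[2, 2] / n2
  pp <- sum(tab[, 2]) / sum(tab)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(chi2_binary(tab)$z_or_chi2, z^2, tolerance = 1e-12)
})

test_that("prevalence arithmetic matches the published percentages", {
  expect_equal(prevalence(c(No = 29, Weak = 22, Moderate = 13, Severe = 3)),
               56.7)
  expect_equal(prevalence(c(No = 63, Weak = 2, Moderate = 2, Severe = 0)),
               6.0)
  expect_equal(prevalence(c(No = 10, Yes = 0)), 0)
  expect_error(prevalence(c(Yes = 5)), "No")
})
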