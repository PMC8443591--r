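test_that("outlier fence drops extreme values and degenerates safely", {
  # hand oracle: Q1 = 2, Q3 = 4, IQR = 2, upper fence = 10
  expect_equal(remove_outliers(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  expect_equal(remove_outliers(c(1, 2, 3, 4, -100)), c(1, 2, 3, 4))
  # values inside the fences untouched
  expect_equal(remove_outliers(c(1, 2, 3, 4, 9)), c(1, 2, 3, 4, 9))
  # degenerate: IQR = 0 or too few values pass through with a warning
  expect_warning(out <- remove_outliers(rep(5, 6)), "IQR")
  expect_equal(out, rep(5, 6))
  expect_warning(out <- remove_outliers(c(1, 2, 3)), "fewer")
  expect_equal(out, c(1, 2, 3))
  # idempotence
  set.seed(1)
  x <- c(rnorm(50), 40)
  expect_equal(remove_outliers(remove_outliers(x)), remove_outliers(x))
})

test_that("volcano handles identical groups and enforces strict thresholds", {
  g <- factor(rep(c("less", "more"), each = 10),
              levels = c("less", "more"))
  x <- cbind(flat = rep(exp(1:10), 2),
             # mean ratio exactly 2^0.6: at the fold-change boundary
             edge = c(rep(1, 10), rep(2^0.6, 10)))
  v <- suppressWarnings(volcano(x, g))
  expect_equal(v$log2_fc[v$feature == "flat"], 0)
  expect_false(v$significant[v$feature == "flat"])
  expect_equal(v$log2_fc[v$feature == "edge"], 0.6)
  # |log2FC| > 0.6 is strict: exactly 0.6 is never significant
  expect_false(v$significant[v$feature == "edge"])
})

test_that("swapping group labels negates fold changes, p and q unchanged", {
  set.seed(3)
  x <- exp(matrix(rnorm(40 * 25), 40, 25))
  g <- factor(rep(c("a", "b"), each = 20), levels = c("a", "b"))
  g_rev <- factor(g, levels = c("b", "a"))
  v1 <- volcano(x, g)
  v2 <- volcano(x, g_rev)
  expect_equal(v2$log2_fc, -v1$log2_fc, tolerance = 1e-12)
  expect_equal(v2$p_value, v1$p_value, tolerance = 1e-12)
  expect_equal(v2$q_value, v1$q_value, tolerance = 1e-12)
})

test_that("q-values equal the Benjamini-Hochberg step-up oracle", {
  set.seed(4)
  x <- exp(matrix(rnorm(30 * 40), 30, 40))
  g <- factor(rep(c("a", "b"), each = 15))
  v <- volcano(x, g)
  p <- v$p_value
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q_oracle <- pmin(1, cummin(m / rev(seq_len(m)) * p[o]))[order(o)]
  expect_equal(v$q_value, q_oracle, tolerance = 1e-12)
})

test_that("planted two-fold changes are recovered with FDR control", {
  hits <- 0; false_rates <- numeric(20)
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 67; p <- 120
    base <- matrix(rnorm(2 * n * p, sd = 0.294), 2 * n, p)  # ~30% CV
    x <- exp(base)
    x[(n + 1):(2 * n), 1:20] <- x[(n + 1):(2 * n), 1:20] * 2
    g <- factor(rep(c("less", "more"), each = n),
                levels = c("less", "more"))
    v <- volcano(x, g)
    sel <- which(v$significant)
    hits <- hits + (length(intersect(sel, 1:20)) >= 18)
    false_rates[s] <- if (length(sel))
      length(setdiff(sel, 1:20)) / length(sel) else 0
  }
  expect_gte(hits, 18)          # >= 18/20 planted features found, most runs
  expect_lte(mean(false_rates), 0.05)
})

test_that("cumulative fold-change distribution matches a sort oracle", {
  f1 <- cumulative_fc(data.frame(log2_fc = 2))
  expect_equal(f1(1.999), 0)
  expect_equal(f1(2), 1)
  f2 <- cumulative_fc(c(-0.5, 0.5))
  expect_equal(f2(0), 0.5)
  set.seed(5)
  lfc <- rnorm(100)
  f3 <- cumulative_fc(lfc)
  at <- seq(-3, 3, by = 0.25)
  oracle <- vapply(at, function(t) mean(sort(lfc) <= t), numeric(1))
  expect_equal(f3(at), oracle)
})

test_that("pathway aggregation averages fold changes per label", {
  rec <- data.frame(feature = paste0("m", 1:6),
                    log2_fc = c(1, -1, 0.5, 0.7, 0.9, 2),
                    p_value = rep(0.01, 6),
                    q_value = c(0.2, 0.2, 0.01, 0.01, 0.2, 0.001),
                    significant = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE))
  ps <- pathway_summary(rec, c("A", "A", "B", "B", "B", ""))
  expect_equal(ps$mean_log2_fc[ps$pathway == "A"], 0)
  expect_equal(ps$mean_log2_fc[ps$pathway == "B"], mean(c(0.5, 0.7, 0.9)))
  expect_equal(ps$pathway, c("A", "B", "unassigned"))
  expect_equal(ps$n_features, c(2L, 3L, 1L))
  # single pathway: one row equal to the global mean
  ps1 <- pathway_summary(rec, rep("all", 6))
  expect_equal(nrow(ps1), 1L)
  expect_equal(ps1$mean_log2_fc, mean(rec$log2_fc))
  # per-feature star annotation tracks q < 0.05
  pf <- attr(ps, "per_feature")
  expect_equal(pf$star, rec$q_value < 0.05)
})
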