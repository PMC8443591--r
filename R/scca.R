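#' Residualize a block on a categorical confounder
#'
#' Replaces every feature by its residuals from a group-means model on the
#' confounder (equivalently, group-mean centering). Used to adjust
#' cross-block correlation analyses for the city effect.
#'
#' @param block [omics_block] or matrix.
#' @param confounder Factor of length `nrow(block)`.
#' @return Matrix of residuals, same dimnames as the input.
#' @export
residualize_on_confounder <- function(block, confounder) {
  x <- block_matrix(block)
  confounder <- as.factor(confounder)
  if (length(confounder) != nrow(x))
    stop("'confounder' length must match the number of subjects")
  if (any(table(confounder) == 1))
    warning("confounder group(s) of size 1: their residuals are exactly 0")
  out <- x
  for (g in levels(confounder)) {
    i <- confounder == g
    out[i, ] <- sweep(x[i, , drop = FALSE], 2,
                      colMeans(x[i, , drop = FALSE]), "-")
  }
  out
}

# Soft-thresholding kernel of the penalized matrix decomposition: returns the
# unit-L2 vector u = S(a, delta) / ||S(a, delta)|| with the smallest
# delta >= 0 such that ||u||_1 <= c (delta = 0 when the unconstrained
# optimum is already feasible). The L1 norm of the normalized
# soft-thresholded vector decreases continuously and monotonically in delta,
# piecewise-smooth between consecutive sorted |a| values, so the threshold
# is solved exactly: locate the support segment whose L1 range brackets c,
# then solve (S1 - m*delta)^2 = c^2 * (S2 - 2*delta*S1 + m*delta^2) there.
l1_project <- function(a, c) {
  soft <- function(a, d) sign(a) * pmax(abs(a) - d, 0)
  unit <- function(v) {
    n2 <- sqrt(sum(v^2))
    if (n2 == 0) v else v / n2
  }
  u <- unit(a)
  if (sum(abs(u)) <= c) return(u)
  basis <- function() {
    u <- numeric(length(a))
    j <- which.max(abs(a))
    u[j] <- sign(a[j])
    u
  }
  if (c <= 1) return(basis())
  b <- sort(abs(a), decreasing = TRUE)
  p <- length(b)
  m <- seq_len(p)
  S1 <- cumsum(b)
  S2 <- cumsum(b^2)
  lo <- c(b[-1], 0)                       # lower delta bound per segment
  l2lo <- S2 - 2 * lo * S1 + m * lo^2
  Rlo <- ifelse(l2lo > 0, (S1 - m * lo) / sqrt(pmax(l2lo, 0)), Inf)
  seg <- which(Rlo >= c)[1]               # smallest support reaching c
  if (is.na(seg)) return(unit(a))
  dlo <- lo[seg]; dhi <- b[seg]
  A <- seg^2 - c^2 * seg
  B <- 2 * S1[seg] * (c^2 - seg)
  C <- S1[seg]^2 - c^2 * S2[seg]
  delta <- if (abs(A) < 1e-300) {
    if (abs(B) > 0) -C / B else dlo
  } else {
    disc <- max(B^2 - 4 * A * C, 0)
    roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
    inseg <- roots[roots >= dlo - 1e-12 & roots <= dhi + 1e-12]
    if (length(inseg)) min(max(inseg[1], dlo), dhi) else dlo
  }
  u <- unit(soft(a, delta))
  if (all(u == 0) || sum(abs(u)) > c + 1e-6) u <- basis()
  u
}

#' Rank-1 sparse CCA by penalized matrix decomposition
#'
#' Finds sparse weight vectors `u`, `v` maximizing `t(u) %*% t(X) %*% Y %*% v`
#' subject to `||u||_2 <= 1`, `||v||_2 <= 1`, `||u||_1 <= c1`,
#' `||v||_1 <= c2`, by alternating soft-thresholded power iterations:
#' `u <- normalize(soft_threshold(t(X) %*% Y %*% v, delta))` with the
#' threshold `delta` solved exactly to meet the L1 bound (and 0 when the
#' bound is inactive), then symmetrically for `v`, until the relative change
#' of the objective falls below `tol`. The canonical correlation `rho` is the
#' Pearson correlation of the component scores `X %*% u` and `Y %*% v`.
#'
#' @param X,Y Column-standardized matrices with the same subject order (use
#'   [standardize_blocks()] / `scale()` upstream; [permute_tune()] does this
#'   for you).
#' @param c1,c2 L1 bounds on `u` and `v`; must lie in `[1, sqrt(p)]` to be
#'   meaningful. See [permute_tune()] for the fraction parameterization.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum alternation sweeps.
#' @param seed Optional seed for the random start (the default start is the
#'   deterministic leading right singular vector direction; the seed only
#'   matters for `init = "random"`).
#' @param init `"svd"` (default) or `"random"` start for `v`.
#' @return List of class `canonical_pair`: `u`, `v` (named), `rho`,
#'   `support_x`, `support_y` (integer indices of nonzero weights), `c1`,
#'   `c2`, `objective` (trace of objective values across iterations),
#'   `converged`, `iterations`.
#' @export
pmd_rank1 <- function(X, Y, c1 = sqrt(ncol(X)), c2 = sqrt(ncol(Y)),
                      tol = 1e-8, max_iter = 200, seed = NULL,
                      init = c("svd", "random")) {
  init <- match.arg(init)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same subjects")
  Z <- crossprod(X, Y)
  v <- if (init == "random") {
    with_seed(seed, stats::rnorm(ncol(Y)))
  } else {
    # power start on t(Z) Z: deterministic, independent of feature order signs
    v0 <- rep(1 / sqrt(ncol(Y)), ncol(Y))
    for (i in 1:5) {
      v0 <- crossprod(Z, Z %*% v0)
      v0 <- v0 / sqrt(sum(v0^2))
    }
    drop(v0)
  }
  v <- v / sqrt(sum(v^2))
  obj_trace <- numeric(0)
  obj_old <- -Inf
  converged <- FALSE
  u <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    u <- l1_project(drop(Z %*% v), c1)
    v <- l1_project(drop(crossprod(Z, u)), c2)
    obj <- drop(crossprod(u, Z %*% v))
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_old) &&
        abs(obj - obj_old) <= tol * max(1, abs(obj_old))) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  xs <- drop(X %*% u); ys <- drop(Y %*% v)
  rho <- if (stats::sd(xs) > 0 && stats::sd(ys) > 0) stats::cor(xs, ys) else 0
  names(u) <- colnames(X); names(v) <- colnames(Y)
  structure(list(u = u, v = v, rho = rho,
                 support_x = which(u != 0), support_y = which(v != 0),
                 c1 = c1, c2 = c2, objective = obj_trace,
                 converged = converged, iterations = length(obj_trace)),
            class = "canonical_pair")
}

#' @export
print.canonical_pair <- function(x, ...) {
  cat(sprintf(
    "<canonical_pair: rho = %.3f, support %d x %d%s>\n", x$rho,
    length(x$support_x), length(x$support_y),
    if (!is.null(x$perm_p)) sprintf(", perm p = %.4g", x$perm_p) else ""))
  invisible(x)
}

#' Permutation-based sparsity selection and significance for sparse CCA
#'
#' Tunes the L1 sparsity of [pmd_rank1()] over a grid of fractions `f`, with
#' bounds `c1 = f * sqrt(ncol(X))`, `c2 = f * sqrt(ncol(Y))`. For each grid
#' point the observed canonical correlation is Fisher-z transformed
#' (`z = atanh(rho)`) and compared with `nperms` refits on row-permuted `X`
#' (single-block permutation; `Y` fixed): the grid point maximizing the
#' standardized score `(z_obs - mean(z_perm)) / (sd(z_perm) + 0.05)` is
#' selected, ties broken toward the smallest fraction (the 0.05 stabilizes
#' grid points whose permutation distribution is extreme-value compressed).
#'
#' Because the grid point is *selected* by maximizing that score, the naive
#' tail fraction of permuted z at the chosen point understates the true
#' p-value. The reported `p_value` therefore corrects for selection: it
#' compares the observed maximal score with the permutation distribution of
#' the grid-maximal score (a maxT correction over the grid, using the same
#' permutations), which is calibrated under the null. The uncorrected
#' at-chosen-point tail fraction is also returned as `p_value_chosen` (the
#' reporting convention of the classical two-block permutation tuner). Both
#' use the +1 add-one convention, so p is never 0.
#'
#' Columns are standardized (mean 0, sd 1) internally; zero-variance columns
#' are dropped with a warning. If `confounder` is given, both blocks are
#' group-mean centered first.
#'
#' @param X,Y Subjects x features matrices (raw scale).
#' @param grid Candidate sparsity fractions in (0, 1].
#' @param nperms Number of permutations (study default 500).
#' @param seed Integer seed driving the permutations.
#' @param confounder Optional factor for [residualize_on_confounder()].
#' @param ... Passed to [pmd_rank1()].
#' @return List of class `scca_tuning`: `grid`, `z_obs`, `z_perm_mean`,
#'   `z_perm_sd`, `score` per grid point, `chosen` (fraction), `p_value`
#'   (selection-corrected), `p_value_chosen` (at-chosen-point tail
#'   fraction), and `pair` (the [pmd_rank1()] fit at the chosen sparsity,
#'   augmented with `perm_p`, `z_obs`, `z_perm_mean`).
#' @export
permute_tune <- function(X, Y, grid = seq(0.1, 0.7, by = 0.1), nperms = 500,
                         seed = 1, confounder = NULL, ...) {
  if (length(grid) < 2) stop("need at least 2 grid points")
  X <- block_matrix(X); Y <- block_matrix(Y)
  if (!is.null(confounder)) {
    X <- residualize_on_confounder(X, confounder)
    Y <- residualize_on_confounder(Y, confounder)
  }
  X <- standardize_columns(X)
  Y <- standardize_columns(Y)
  n <- nrow(X)
  fits <- lapply(grid, function(f)
    pmd_rank1(X, Y, c1 = max(1, f * sqrt(ncol(X))),
              c2 = max(1, f * sqrt(ncol(Y))), ...))
  z_obs <- vapply(fits, function(f) atanh(min(max(f$rho, -1 + 1e-12),
                                              1 - 1e-12)), numeric(1))
  z_perm <- with_seed(seed, {
    vapply(seq_len(nperms), function(b) {
      idx <- sample.int(n)
      vapply(seq_along(grid), function(i) {
        f <- grid[i]
        fit <- pmd_rank1(X[idx, , drop = FALSE], Y,
                         c1 = max(1, f * sqrt(ncol(X))),
                         c2 = max(1, f * sqrt(ncol(Y))), ...)
        atanh(min(max(fit$rho, -1 + 1e-12), 1 - 1e-12))
      }, numeric(1))
    }, numeric(length(grid)))
  })
  z_perm <- matrix(z_perm, nrow = length(grid))
  pm <- rowMeans(z_perm)
  psd <- apply(z_perm, 1, stats::sd)
  if (any(psd == 0))
    warning("zero permutation spread at ", sum(psd == 0), " grid point(s)")
  # the 0.05 added to the permutation sd stabilizes the score at grid points
  # with a degenerate (extreme-value-compressed) permutation distribution,
  # following the reference permutation tuner for two-block sparse CCA
  score <- (z_obs - pm) / (psd + 0.05)
  best <- which.max(score)  # which.max takes the first (smallest f) on ties
  p_chosen <- (sum(z_perm[best, ] >= z_obs[best]) + 1) / (nperms + 1)
  score_perm <- (z_perm - pm) / (psd + 0.05)
  max_perm <- apply(score_perm, 2, max)
  p_value <- (sum(max_perm >= score[best]) + 1) / (nperms + 1)
  pair <- fits[[best]]
  pair$perm_p <- p_value
  pair$z_obs <- z_obs[best]
  pair$z_perm_mean <- pm[best]
  structure(list(grid = grid, z_obs = z_obs, z_perm_mean = pm,
                 z_perm_sd = psd, score = score, chosen = grid[best],
                 nperms = nperms, p_value = p_value,
                 p_value_chosen = p_chosen, pair = pair),
            class = "scca_tuning")
}

#' @export
print.scca_tuning <- function(x, ...) {
  cat(sprintf(
    "<scca_tuning: chosen f = %.2f, rho = %.3f, perm p = %.4g (%d perms)>\n",
    x$chosen, x$pair$rho, x$p_value, x$nperms))
  invisible(x)
}

#' Cross-correlation matrix between selected features of two blocks
#'
#' Pearson correlations between the features selected by a sparse CCA fit,
#' the matrix behind the cross-block heatmaps.
#'
#' @param X_selected,Y_selected Matrices restricted to the selected features
#'   (confounder-adjusted upstream if desired).
#' @return `ncol(X_selected)` x `ncol(Y_selected)` matrix of Pearson r;
#'   zero-variance features give `NA` entries.
#' @export
cross_correlation <- function(X_selected, Y_selected) {
  X_selected <- as.matrix(X_selected); Y_selected <- as.matrix(Y_selected)
  if (!ncol(X_selected) || !ncol(Y_selected)) stop("empty support")
  suppressWarnings(stats::cor(X_selected, Y_selected))
}
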