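#' Plug-in Shannon diversity per subject
#'
#' Within-sample (alpha) diversity `H = -sum(p_i * log(p_i))` over the
#' nonzero taxon proportions of each subject, in nats. This is the plug-in
#' estimator on observed proportions; estimators that model unobserved
#' richness can be supplied externally wherever a diversity vector is
#' accepted downstream.
#'
#' @param otu [omics_block] or matrix of nonnegative counts or relative
#'   abundances, subjects in rows.
#' @param kingdom Optional label (`"bacterial"`/`"fungal"`) stored as an
#'   attribute.
#' @return Named numeric vector of Shannon indices.
#' @export
shannon <- function(otu, kingdom = NULL) {
  x <- block_matrix(otu)
  if (any(x < 0, na.rm = TRUE)) stop("abundances must be nonnegative")
  rs <- rowSums(x, na.rm = TRUE)
  if (any(rs == 0)) stop("subject(s) with all-zero abundances")
  p <- x / rs
  h <- apply(p, 1, function(pi) {
    pi <- pi[!is.na(pi) & pi > 0]
    -sum(pi * log(pi))
  })
  if (!is.null(kingdom)) attr(h, "kingdom") <- kingdom
  h
}

#' Pearson screen of features against a diversity index
#'
#' Per-feature Pearson correlation with a per-subject diversity vector,
#' two-sided p-values from the t-distribution, Benjamini-Hochberg q-values,
#' ranked by significance.
#'
#' @param block [omics_block] or matrix (e.g. log metabolite abundances).
#' @param diversity Named numeric vector aligned to the block's subjects.
#' @return data.frame sorted by p-value: `feature`, `r`, `p_value`,
#'   `q_value`. Constant features are excluded and listed in the
#'   `"excluded"` attribute.
#' @export
metabolite_diversity_correlations <- function(block, diversity) {
  x <- ensure_colnames(block_matrix(block))
  if (!is.null(names(diversity)) && !is.null(rownames(x))) {
    if (!all(rownames(x) %in% names(diversity)))
      stop("diversity vector does not cover all subjects")
    diversity <- diversity[rownames(x)]
  }
  if (length(diversity) != nrow(x))
    stop("'diversity' length must match the number of subjects")
  sds <- apply(x, 2, stats::sd)
  excluded <- colnames(x)[sds == 0]
  x <- x[, sds > 0, drop = FALSE]
  res <- t(apply(x, 2, function(col) {
    ct <- stats::cor.test(col, diversity)
    c(r = unname(ct$estimate), p = ct$p.value)
  }))
  out <- data.frame(feature = rownames(res), r = res[, "r"],
                    p_value = res[, "p"],
                    q_value = stats::p.adjust(res[, "p"], "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# One NIPALS PLS1 fit on centered/scaled training data. Returns weights,
# loadings and regression coefficients for 1..ncomp components.
pls1_nipals <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  Xd <- X; yd <- y
  actual <- 0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pv <- drop(crossprod(Xd, tt)) / tt2
    qv <- sum(yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pv)
    yd <- yd - qv * tt
    W[, a] <- w; P[, a] <- pv; Q[a] <- qv; Tm[, a] <- tt
    actual <- a
  }
  list(W = W[, seq_len(actual), drop = FALSE],
       P = P[, seq_len(actual), drop = FALSE],
       Q = Q[seq_len(actual)], scores = Tm[, seq_len(actual), drop = FALSE],
       ncomp = actual)
}

# Regression coefficients (on the scaled X, centered y) for the first a
# components: B = W (P'W)^{-1} q.
pls1_coef <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  q <- fit$Q[seq_len(a)]
  drop(W %*% solve(crossprod(P, W), q))
}

#' PLS1 variance of a diversity index explained by a feature block
#'
#' NIPALS partial least squares regression of a single response (e.g.
#' bacterial or fungal Shannon diversity) on a feature block (e.g. log
#' metabolite abundances). Predictors are autoscaled (mean 0, sd 1), the
#' response centered. Reports, per cumulative number of components, the
#' in-sample explained variance `R2Y = 1 - RSS/TSS` and the k-fold
#' cross-validated `Q2 = 1 - PRESS/TSS` (the "variance of the response
#' accounted for by the predictors" convention of standard chemometrics
#' software; both are exposed because reporting practice varies).
#'
#' @param block [omics_block] or matrix of predictors.
#' @param diversity Numeric response vector.
#' @param n_components Number of PLS components (default 2; truncated with a
#'   warning if the block rank is lower).
#' @param cv_folds Folds for Q2 (default 7).
#' @param seed Seed for the fold assignment.
#' @return List of class `pls_fit`: `r2y` and `q2` (cumulative, one entry
#'   per component), `weights`, `loadings`, `scores`, `n_components`,
#'   `cv_folds`.
#' @export
pls_variance_explained <- function(block, diversity, n_components = 2,
                                   cv_folds = 7, seed = 1) {
  X0 <- ensure_colnames(block_matrix(block))
  y0 <- as.numeric(diversity)
  if (length(y0) != nrow(X0))
    stop("'diversity' length must match the number of subjects")
  if (n_components < 1) stop("n_components must be >= 1")
  keep <- apply(X0, 2, stats::sd) > 0
  X0 <- X0[, keep, drop = FALSE]
  Xs <- scale(X0)
  yc <- y0 - mean(y0)
  fit <- pls1_nipals(Xs, yc, n_components)
  if (fit$ncomp < n_components) {
    warning("block rank supports only ", fit$ncomp, " component(s); ",
            "truncated")
    n_components <- fit$ncomp
  }
  tss <- sum(yc^2)
  r2y <- vapply(seq_len(n_components), function(a) {
    pred <- drop(Xs %*% pls1_coef(fit, a))
    1 - sum((yc - pred)^2) / tss
  }, numeric(1))
  n <- nrow(Xs)
  folds <- with_seed(seed, sample(rep(seq_len(cv_folds), length.out = n)))
  press <- matrix(NA_real_, n, n_components)
  for (k in seq_len(cv_folds)) {
    te <- folds == k
    ctr <- colMeans(X0[!te, , drop = FALSE])
    sdv <- apply(X0[!te, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X0[!te, , drop = FALSE], 2, ctr), 2, sdv, "/")
    Xte <- sweep(sweep(X0[te, , drop = FALSE], 2, ctr), 2, sdv, "/")
    my <- mean(y0[!te])
    f <- pls1_nipals(Xtr, y0[!te] - my, n_components)
    for (a in seq_len(min(n_components, f$ncomp))) {
      press[te, a] <- (y0[te] - (my + drop(Xte %*% pls1_coef(f, a))))^2
    }
  }
  q2 <- 1 - colSums(press) / sum((y0 - mean(y0))^2)
  structure(list(r2y = r2y, q2 = q2, weights = fit$W, loadings = fit$P,
                 scores = fit$scores, n_components = n_components,
                 cv_folds = cv_folds),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit: %d component(s), R2Y = %s, Q2 = %s>\n",
              x$n_components,
              paste(sprintf("%.3f", x$r2y), collapse = "/"),
              paste(sprintf("%.3f", x$q2), collapse = "/")))
  invisible(x)
}
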