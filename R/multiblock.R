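#' MAXVAR-A consensus space over several omics blocks
#'
#' Builds a common ("consensus") representation of subjects described by
#' several feature blocks, as a special case of regularized generalized
#' canonical correlation analysis: every block is connected to a superblock
#' (the column concatenation of all standardized blocks), block shrinkage
#' `tau = 1` (covariance/weight-norm constraint), superblock `tau = 0`
#' (correlation/unit-variance constraint), squared-covariance (factorial)
#' scheme. The block-coordinate update is monotone in the RGCCA criterion
#' `sum_j cov^2(X_j a_j, X_s a_s)`; the consensus components are the
#' superblock components. Further components are obtained by deflating every
#' block (and the superblock) against its own previous component, so
#' within-block score vectors are mutually orthogonal.
#'
#' The singular superblock covariance under `tau = 0` (features usually
#' outnumber subjects) is stabilized by a small ridge.
#'
#' @param blocks Named list of [omics_block]s or matrices sharing subject
#'   order. Each is column-standardized internally.
#' @param n_components Number of consensus components (default 2).
#' @param tol Relative criterion-change convergence tolerance.
#' @param max_iter Maximum update sweeps per component.
#' @param ridge Ridge fraction added to the superblock covariance diagonal.
#' @return List of class `consensus_model`: `block_weights` (list of
#'   features x components matrices per block), `block_scores` (list of
#'   subjects x components), `consensus_scores` (subjects x components,
#'   unit variance), `variance_explained` (per component: mean squared
#'   correlation of the original superblock columns with the component),
#'   `criterion` (list of per-iteration criterion values per component),
#'   `converged` (logical per component), `block_names`.
#' @export
maxvar_a <- function(blocks, n_components = 2, tol = 1e-10,
                     max_iter = 1000, ridge = 1e-8) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  Xs <- lapply(blocks, function(b) standardize_columns(block_matrix(b)))
  n <- nrow(Xs[[1]])
  if (!all(vapply(Xs, nrow, 1L) == n))
    stop("all blocks must share the same subjects")
  J <- length(Xs)
  super0 <- do.call(cbind, Xs)
  p_s <- ncol(super0)

  weights <- lapply(Xs, function(x)
    matrix(0, ncol(x), n_components,
           dimnames = list(colnames(x), NULL)))
  bscores <- lapply(Xs, function(x) matrix(0, n, n_components))
  cscores <- matrix(0, n, n_components,
                    dimnames = list(rownames(super0), NULL))
  crit_trace <- vector("list", n_components)
  converged <- logical(n_components)
  var_expl <- numeric(n_components)

  Xd <- Xs
  Sd <- super0
  for (comp in seq_len(n_components)) {
    # superblock covariance (tau = 0) with ridge stabilization
    Ssig <- crossprod(Sd) / n
    diag(Ssig) <- diag(Ssig) + ridge * max(1, mean(diag(Ssig)))
    R <- chol(Ssig)

    # normalizations return the zero vector for degenerate inputs (e.g. a
    # block exhausted by deflation), which then contributes nothing
    norm_tau1 <- function(a) {
      n2 <- sqrt(sum(a^2))
      if (!is.finite(n2) || n2 < 1e-300) rep(0, length(a)) else a / n2
    }
    norm_tau0 <- function(a) {
      # solve Ssig w = a, then scale to unit component variance
      w <- backsolve(R, forwardsolve(t(R), a))
      v <- drop(crossprod(w, Ssig %*% w))
      if (!is.finite(v) || v < 1e-300) rep(0, length(a)) else w / sqrt(v)
    }

    a <- lapply(Xd, function(x) norm_tau1(drop(crossprod(x, x[, 1]))))
    a_s <- norm_tau0(drop(crossprod(Sd, Sd[, 1])))
    y <- mapply(function(x, aj) drop(x %*% aj), Xd, a, SIMPLIFY = FALSE)
    y_s <- drop(Sd %*% a_s)

    crit <- function() sum(vapply(y, function(yj)
      (sum(yj * y_s) / n)^2, numeric(1)))
    trace <- crit()
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      # update each individual block against the superblock component
      for (j in seq_len(J)) {
        cjs <- sum(y[[j]] * y_s) / n
        z <- 2 * cjs * y_s
        aj <- drop(crossprod(Xd[[j]], z)) / n
        nj <- sqrt(sum(aj^2))
        if (!is.finite(nj) || nj < 1e-300) next
        a[[j]] <- norm_tau1(aj)
        y[[j]] <- drop(Xd[[j]] %*% a[[j]])
      }
      # update the superblock component against all blocks
      z <- Reduce(`+`, lapply(seq_len(J), function(j)
        2 * (sum(y[[j]] * y_s) / n) * y[[j]]))
      as_new <- drop(crossprod(Sd, z)) / n
      if (sqrt(sum(as_new^2)) >= 1e-300) {
        a_s <- norm_tau0(as_new)
        y_s <- drop(Sd %*% a_s)
      }
      trace <- c(trace, crit())
      m <- length(trace)
      if (abs(trace[m] - trace[m - 1]) <= tol * max(1, abs(trace[m - 1]))) {
        ok <- TRUE
        break
      }
    }
    converged[comp] <- ok
    crit_trace[[comp]] <- trace
    for (j in seq_len(J)) {
      weights[[j]][, comp] <- a[[j]]
      bscores[[j]][, comp] <- y[[j]]
    }
    cscores[, comp] <- y_s
    var_expl[comp] <- mean(suppressWarnings(
      stats::cor(super0, y_s))^2, na.rm = TRUE)

    # deflate every block and the superblock against their own component
    if (comp < n_components) {
      Xd <- lapply(seq_len(J), function(j) {
        t1 <- bscores[[j]][, comp]
        if (sum(t1^2) == 0) return(Xd[[j]])
        Xd[[j]] - tcrossprod(t1 / sum(t1^2), drop(crossprod(Xd[[j]], t1)))
      })
      names(Xd) <- names(Xs)
      t1 <- cscores[, comp]
      Sd <- Sd - tcrossprod(t1 / sum(t1^2), drop(crossprod(Sd, t1)))
    }
  }
  structure(list(block_weights = weights, block_scores = bscores,
                 consensus_scores = cscores,
                 variance_explained = var_expl,
                 criterion = crit_trace, converged = converged,
                 block_names = names(Xs)),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf(
    "<consensus_model: %d blocks, %d components, %.1f%% variance on 1-%d>\n",
    length(x$block_names), ncol(x$consensus_scores),
    100 * sum(x$variance_explained), ncol(x$consensus_scores)))
  invisible(x)
}

#' Ward clustering of subjects in the consensus space
#'
#' Hierarchical clustering (Ward linkage, Euclidean distance) of the
#' subjects on the consensus components. If `k` is not given, the number of
#' clusters is chosen by the dendrogram gap rule: the cut `k` in
#' `k_range` maximizing the drop between consecutive merge heights.
#'
#' @param model A [maxvar_a()] result (or a plain subjects x components
#'   score matrix).
#' @param k Number of clusters; `NULL` (default) applies the gap rule.
#' @param k_range Candidate cluster numbers for the gap rule.
#' @return List of class `cluster_assignment`: `cluster` (named integer),
#'   `k`, `gap_used` (height drop at the chosen cut), `heights` (merge
#'   heights), `hclust` (the tree).
#' @export
consensus_clustering <- function(model, k = NULL, k_range = 2:10) {
  scores <- if (inherits(model, "consensus_model"))
    model$consensus_scores else as.matrix(model)
  n <- nrow(scores)
  if (n < 3) {
    if (n == 2) {
      cl <- stats::setNames(1:2, rownames(scores))
      return(structure(list(cluster = cl, k = 2L, gap_used = NA_real_,
                            heights = numeric(0), hclust = NULL),
                       class = "cluster_assignment"))
    }
    stop("need at least 2 subjects")
  }
  if (all(apply(scores, 2, stats::sd) == 0))
    stop("zero-variance consensus space")
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  heights <- hc$height
  gap_used <- NA_real_
  if (is.null(k)) {
    k_range <- k_range[k_range >= 2 & k_range <= n - 1]
    # cutting into k clusters removes the top k-1 merges; the gap for k is
    # the height drop between the (k-1)-th and k-th highest merges
    hs <- sort(heights, decreasing = TRUE)
    gaps <- vapply(k_range, function(kk) hs[kk - 1] - hs[kk], numeric(1))
    k <- k_range[which.max(gaps)]
    gap_used <- max(gaps)
  }
  cl <- stats::cutree(hc, k = k)
  structure(list(cluster = cl, k = as.integer(k), gap_used = gap_used,
                 heights = heights, hclust = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: k = %d, sizes %s>\n", x$k,
              paste(table(x$cluster), collapse = "/")))
  invisible(x)
}

#' Cluster-by-group composition table
#'
#' Cross-tabulates a cluster assignment against a per-subject grouping
#' (e.g. city), the inset-table view of a clustered consensus plot.
#'
#' @param assignment A [consensus_clustering()] result (or integer vector).
#' @param groups Factor of per-subject group labels.
#' @return A `groups x cluster` contingency table.
#' @export
cluster_composition <- function(assignment, groups) {
  cl <- if (inherits(assignment, "cluster_assignment"))
    assignment$cluster else assignment
  table(group = groups, cluster = cl)
}
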