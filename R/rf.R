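#' Random-forest classification with owned out-of-bag bookkeeping
#'
#' Fits a bootstrap-per-tree randomized tree ensemble for class labels (e.g.
#' city membership from the metabolite block). The tree learner is the
#' standard `randomForest` implementation; the out-of-bag (OOB) aggregation
#' is done here from the per-tree in-bag counts so that the same bookkeeping
#' can be replayed with permuted features ([permutation_vimp()]): a
#' subject's OOB prediction is the majority vote over the trees whose
#' bootstrap sample excluded it, and the OOB error is the misclassification
#' rate of those votes.
#'
#' @param block [omics_block] or matrix of predictors.
#' @param labels Factor of class labels (>= 2 classes).
#' @param n_trees Number of trees (default 1000).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param seed Integer seed.
#' @return List of class `forest_fit`: `forest` (the randomForest object),
#'   `inbag` (subjects x trees bootstrap counts), `oob_pred` (factor of OOB
#'   majority votes, `NA` if a subject was never OOB), `oob_error`,
#'   `labels`, `n_trees`, `seed`.
#' @export
fit_forest <- function(block, labels, n_trees = 1000, mtry = NULL,
                       seed = 1) {
  x <- ensure_colnames(block_matrix(block))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("labels must have >= 2 classes")
  if (n_trees < 50) stop("n_trees must be >= 50")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  forest <- with_seed(seed,
    randomForest::randomForest(x = x, y = labels, ntree = n_trees,
                               mtry = mtry, keep.inbag = TRUE,
                               keep.forest = TRUE))
  inbag <- forest$inbag
  per_tree <- predict(forest, newdata = x, predict.all = TRUE)$individual
  oob_pred <- oob_majority(per_tree, inbag, levels(labels))
  fit <- list(forest = forest, inbag = inbag, oob_pred = oob_pred,
              oob_error = mean(oob_pred != labels, na.rm = TRUE),
              labels = labels, n_trees = n_trees, seed = seed)
  class(fit) <- "forest_fit"
  fit
}

# Majority vote over OOB trees per subject; deterministic tie-break toward
# the earlier class level. Subjects with no OOB tree get NA.
oob_majority <- function(per_tree, inbag, class_levels) {
  n <- nrow(per_tree)
  out <- rep(NA_character_, n)
  oob <- inbag == 0
  for (i in seq_len(n)) {
    votes <- per_tree[i, oob[i, ]]
    if (length(votes)) {
      tab <- table(factor(votes, levels = class_levels))
      out[i] <- names(tab)[which.max(tab)]
    }
  }
  factor(out, levels = class_levels)
}

#' @export
print.forest_fit <- function(x, ...) {
  cat(sprintf("<forest_fit: %d trees, OOB error = %.3f>\n",
              x$n_trees, x$oob_error))
  invisible(x)
}

#' Permutation variable importance on the OOB error scale
#'
#' For each feature in turn, "noises up" the variable by randomly permuting
#' its values across subjects, replays the forest's OOB prediction with the
#' permuted column, and reports the importance
#' `vimp = oob_error_permuted - oob_error_observed`. A variable the forest
#' never uses gets exactly 0; a pure-noise variable hovers near 0; a
#' variable the model relies on gets a positive error-rate increase.
#'
#' @param fit A [fit_forest()] result.
#' @param block The predictor block the forest was fitted on.
#' @param seed Integer seed for the permutations (one global permutation per
#'   feature).
#' @param top_k Number of top-ranked features flagged in the returned table
#'   (display convention; all features are reported).
#' @return data.frame of class `vimp_table` sorted by decreasing `vimp`:
#'   `feature`, `vimp`, `rank`, `top` (logical, rank <= top_k); attributes
#'   `oob_error`, `n_trees`, `seed`.
#' @export
permutation_vimp <- function(fit, block, seed = 1, top_k = 20) {
  stopifnot(inherits(fit, "forest_fit"))
  x <- ensure_colnames(block_matrix(block))
  labels <- fit$labels
  n <- nrow(x)
  vimp <- with_seed(seed, {
    vapply(seq_len(ncol(x)), function(j) {
      xp <- x
      xp[, j] <- xp[sample.int(n), j]
      per_tree <- predict(fit$forest, newdata = xp,
                          predict.all = TRUE)$individual
      pred <- oob_majority(per_tree, fit$inbag, levels(labels))
      mean(pred != labels, na.rm = TRUE) - fit$oob_error
    }, numeric(1))
  })
  ord <- order(vimp, decreasing = TRUE)
  out <- data.frame(feature = colnames(x)[ord], vimp = vimp[ord],
                    rank = seq_along(ord),
                    top = seq_along(ord) <= top_k,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("vimp_table", "data.frame")
  attr(out, "oob_error") <- fit$oob_error
  attr(out, "n_trees") <- fit$n_trees
  attr(out, "seed") <- seed
  out
}
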