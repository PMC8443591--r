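#' v-test for a continuous variable in a subject cluster
#'
#' Signed standardized comparison of a cluster's mean with the global mean:
#' `v = (mean_k - mean) / sqrt((s2 / n_k) * (N - n_k) / (N - 1))`, where
#' `s2` is the *global* variance with the divide-by-N convention. Under the
#' null of the cluster being a simple random subsample, v is approximately
#' standard normal; `|v| >= 2` flags the variable as characterizing the
#' cluster (over-represented if positive, under-represented if negative).
#'
#' @param values Numeric vector over all subjects.
#' @param cluster_mask Logical vector: TRUE for subjects in the cluster.
#'   Cluster size must satisfy `1 <= n_k < N`.
#' @return List of class `vtest`: `v`, `significant` (`|v| >= 2`),
#'   `cluster_mean`, `global_mean`, `n_cluster`, `n_total`, `type`.
#'   Zero global variance gives `v = NA`.
#' @export
vtest_continuous <- function(values, cluster_mask) {
  cluster_mask <- as.logical(cluster_mask)
  N <- length(values)
  if (length(cluster_mask) != N) stop("mask length mismatch")
  nk <- sum(cluster_mask)
  if (nk < 1 || nk >= N)
    stop("cluster must be a proper nonempty subset of the subjects")
  gm <- mean(values)
  cm <- mean(values[cluster_mask])
  s2 <- mean((values - gm)^2)  # divide-by-N global variance
  v <- if (s2 > 0)
    (cm - gm) / sqrt((s2 / nk) * (N - nk) / (N - 1)) else NA_real_
  structure(list(v = v, significant = !is.na(v) && abs(v) >= 2,
                 cluster_mean = cm, global_mean = gm,
                 n_cluster = nk, n_total = N, type = "continuous"),
            class = "vtest")
}

#' v-test for a categorical modality in a subject cluster
#'
#' Tests whether a modality (one level of a categorical variable) is over-
#' or under-represented in a cluster, using the hypergeometric model for the
#' count of modality carriers drawn into the cluster: `n_k` subjects drawn
#' from `N` of which `n_j` carry the modality. The two-sided p-value is
#' twice the smaller tail (capped at 1) and is converted to a signed normal
#' quantile: `v = sign(prop_cluster - prop_global) * qnorm(1 - p/2)`.
#' `p = 1` (no enrichment signal) gives `v = 0`.
#'
#' @param modality_mask Logical vector: TRUE for subjects carrying the
#'   modality.
#' @param cluster_mask Logical vector: TRUE for subjects in the cluster.
#' @return List of class `vtest`: `v`, `significant`, `p_value`,
#'   `modality_proportion` (in cluster), `global_proportion`, `n_cluster`,
#'   `n_total`, `type`. A modality absent from the whole population gives
#'   `v = NA`.
#' @export
vtest_modality <- function(modality_mask, cluster_mask) {
  modality_mask <- as.logical(modality_mask)
  cluster_mask <- as.logical(cluster_mask)
  N <- length(modality_mask)
  if (length(cluster_mask) != N) stop("mask length mismatch")
  nk <- sum(cluster_mask)
  if (nk < 1 || nk >= N)
    stop("cluster must be a proper nonempty subset of the subjects")
  nj <- sum(modality_mask)
  if (nj == 0)
    return(structure(list(v = NA_real_, significant = FALSE,
                          p_value = NA_real_, modality_proportion = 0,
                          global_proportion = 0, n_cluster = nk,
                          n_total = N, type = "modality"),
                     class = "vtest"))
  nkj <- sum(modality_mask & cluster_mask)
  lo <- stats::phyper(nkj, nj, N - nj, nk)
  hi <- stats::phyper(nkj - 1, nj, N - nj, nk, lower.tail = FALSE)
  p <- min(1, 2 * min(lo, hi))
  dirn <- sign(nkj / nk - nj / N)
  v <- if (p >= 1 || dirn == 0) 0 else dirn * stats::qnorm(1 - p / 2)
  structure(list(v = v, significant = abs(v) >= 2, p_value = p,
                 modality_proportion = nkj / nk,
                 global_proportion = nj / N,
                 n_cluster = nk, n_total = N, type = "modality"),
            class = "vtest")
}

#' @export
print.vtest <- function(x, ...) {
  cat(sprintf("<vtest (%s): v = %.3f%s>\n", x$type, x$v,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Characterize clusters by continuous blocks and categorical clinical signs
#'
#' Runs [vtest_continuous()] on every feature of the supplied blocks
#' (log-transformed by default, the scale on which abundances are roughly
#' symmetric) and [vtest_modality()] on every modality of the supplied
#' categorical clinical columns, for every cluster. Results are sorted by
#' `|v|` descending within cluster.
#'
#' @param assignment A [consensus_clustering()] result or named integer
#'   vector of cluster labels.
#' @param blocks Named list of [omics_block]s / matrices of continuous
#'   variables (may be empty).
#' @param clinical Optional data.frame of categorical columns (factors,
#'   integers or characters), subjects in rows, aligned with the blocks.
#' @param log_continuous Log-transform continuous blocks before testing
#'   (default TRUE; requires positive values, otherwise that block is used
#'   as is with a warning).
#' @param significant_only Keep only `|v| >= 2` rows (default TRUE).
#' @return data.frame: `cluster`, `variable`, `block`, `type`
#'   (`continuous`/`modality`), `modality` (NA for continuous), `v`,
#'   `significant`.
#' @export
characterize_clusters <- function(assignment, blocks = list(),
                                  clinical = NULL, log_continuous = TRUE,
                                  significant_only = TRUE) {
  cl <- if (inherits(assignment, "cluster_assignment"))
    assignment$cluster else assignment
  ks <- sort(unique(cl))
  if (length(ks) < 2) stop("need at least 2 clusters")
  rows <- list()
  for (bn in names(blocks)) {
    x <- ensure_colnames(block_matrix(blocks[[bn]]))
    if (nrow(x) != length(cl)) stop("block '", bn, "' subject mismatch")
    if (log_continuous) {
      if (any(x <= 0)) {
        warning("block '", bn, "' has non-positive values; tested untransformed")
      } else x <- log(x)
    }
    for (k in ks) {
      mask <- cl == k
      vs <- vapply(seq_len(ncol(x)), function(j) {
        vt <- vtest_continuous(x[, j], mask)
        vt$v
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        cluster = k, variable = colnames(x), block = bn,
        type = "continuous", modality = NA_character_, v = vs,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(clinical)) {
    if (nrow(clinical) != length(cl)) stop("clinical subject mismatch")
    for (cn in names(clinical)) {
      col <- as.factor(clinical[[cn]])
      for (lev in levels(col)) {
        for (k in ks) {
          vt <- vtest_modality(col == lev, cl == k)
          rows[[length(rows) + 1]] <- data.frame(
            cluster = k, variable = cn, block = "clinical",
            type = "modality", modality = lev, v = vt$v,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$v) & abs(out$v) >= 2
  if (significant_only) out <- out[out$significant, , drop = FALSE]
  out <- out[order(out$cluster, -abs(out$v)), ]
  rownames(out) <- NULL
  out
}
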