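#' Remove extreme outliers from a vector of abundances
#'
#' Drops values at or beyond three interquartile ranges from the quartiles:
#' `x >= Q3 + 3 * IQR` or `x <= Q1 - 3 * IQR` (a two-sided extreme-outlier
#' fence). Degenerate inputs pass through unchanged with a warning: fewer
#' than 4 values (quartiles unstable) or `IQR == 0` (the fence would collapse
#' onto the data).
#'
#' @param x Numeric vector (one feature, one group).
#' @return `x` with outliers removed.
#' @export
remove_outliers <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4) {
    warning("fewer than 4 values; outlier removal skipped")
    return(x)
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) {
    warning("IQR is zero; outlier removal skipped")
    return(x)
  }
  x[x < q[2] + 3 * iqr & x > q[1] - 3 * iqr]
}

#' Fold-change / Welch-t / Benjamini-Hochberg volcano screen
#'
#' For every feature of a block, compares two subject groups: the fold
#' change is computed on the original abundance scale after per-group
#' extreme-outlier removal ([remove_outliers()]), as
#' `log2(mean(group2) / mean(group1))` with `group1` the reference (first
#' factor level; for the two-city design the less polluted city, so positive
#' values mean higher abundance in the more polluted group). Significance is
#' a Welch two-sample t-test on the log-transformed values of *all*
#' subjects (outlier trimming is a robustness device for the ratio of means
#' only; trimming before the t-test would shrink its variance estimate and
#' inflate significance), corrected across all features by the
#' Benjamini-Hochberg step-up procedure. A feature is called significant
#' when `|log2_fc| > lfc_threshold` AND `q_value < q_threshold`, both
#' strict inequalities.
#'
#' @param block [omics_block] (or matrix) of positive abundances.
#' @param groups Factor of length `nrow(block)` with exactly 2 levels; the
#'   first level is the reference (denominator of the fold change).
#' @param lfc_threshold,q_threshold Significance thresholds (defaults 0.6
#'   and 0.05).
#' @param log_values Whether t-tests run on `log(x)` (default TRUE).
#' @return data.frame of class `volcano_table`: `feature`, `log2_fc`,
#'   `p_value`, `q_value`, `significant`, `n_used_1`, `n_used_2` (group
#'   sizes after outlier removal). Features whose group mean is non-positive
#'   after outlier removal get `NA` fold change and are never significant.
#' @export
volcano <- function(block, groups, lfc_threshold = 0.6, q_threshold = 0.05,
                    log_values = TRUE) {
  x <- ensure_colnames(block_matrix(block))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("'groups' must have exactly 2 levels")
  if (length(groups) != nrow(x))
    stop("'groups' length must match the number of subjects")
  if (min(table(groups)) < 3) stop("each group needs >= 3 subjects")
  g1 <- groups == levels(groups)[1]
  res <- lapply(seq_len(ncol(x)), function(j) {
    a <- suppressWarnings(remove_outliers(x[g1, j]))
    b <- suppressWarnings(remove_outliers(x[!g1, j]))
    ma <- mean(a); mb <- mean(b)
    lfc <- if (ma > 0 && mb > 0) log2(mb / ma) else NA_real_
    ta <- x[g1, j]; tb <- x[!g1, j]
    ta <- ta[!is.na(ta)]; tb <- tb[!is.na(tb)]
    if (log_values) {
      ta <- log(pmax(ta, .Machine$double.xmin))
      tb <- log(pmax(tb, .Machine$double.xmin))
    }
    p <- if (stats::sd(ta) == 0 && stats::sd(tb) == 0) {
      if (isTRUE(all.equal(mean(ta), mean(tb)))) 1 else 0
    } else tryCatch(stats::t.test(tb, ta)$p.value, error = function(e) NA_real_)
    c(lfc = lfc, p = p, n1 = length(a), n2 = length(b))
  })
  res <- do.call(rbind, res)
  q <- stats::p.adjust(res[, "p"], method = "BH")
  out <- data.frame(feature = colnames(x), log2_fc = res[, "lfc"],
                    p_value = res[, "p"], q_value = q,
                    significant = !is.na(res[, "lfc"]) & !is.na(q) &
                      abs(res[, "lfc"]) > lfc_threshold & q < q_threshold,
                    n_used_1 = as.integer(res[, "n1"]),
                    n_used_2 = as.integer(res[, "n2"]),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("volcano_table", "data.frame")
  attr(out, "reference") <- levels(groups)[1]
  attr(out, "comparison") <- levels(groups)[2]
  out
}

#' Empirical cumulative distribution of fold changes
#'
#' @param records A [volcano()] table (or numeric vector of log2 fold
#'   changes).
#' @return A step function (`stats::ecdf`) over the finite log2 fold
#'   changes.
#' @export
cumulative_fc <- function(records) {
  lfc <- if (is.data.frame(records)) records$log2_fc else records
  lfc <- lfc[is.finite(lfc)]
  if (!length(lfc)) stop("no finite fold changes")
  stats::ecdf(lfc)
}

#' Pathway-level aggregation of a volcano table
#'
#' Averages log2 fold changes within pathway labels (the heatmap view of a
#' differential screen) and collects per-feature `-log10(q)` with a
#' significance star flag (`q < 0.05`) per pathway. Aggregation only; no
#' ontology enrichment. An optional hypergeometric over-representation test
#' of significant features per pathway is available via `enrichment = TRUE`.
#'
#' @param records A [volcano()] table.
#' @param pathways Character vector of pathway labels, parallel to
#'   `records$feature`; missing/empty labels become `"unassigned"`.
#' @param enrichment If TRUE, adds a two-sided hypergeometric p-value for
#'   over/under-representation of significant features in each pathway.
#' @return data.frame: `pathway`, `mean_log2_fc`, `n_features`,
#'   `n_significant`; attribute `"per_feature"` holds the feature-level
#'   table with `minus_log10_q` and `star`.
#' @export
pathway_summary <- function(records, pathways, enrichment = FALSE) {
  stopifnot(is.data.frame(records))
  if (length(pathways) != nrow(records))
    stop("'pathways' must be parallel to the volcano table")
  pathways <- as.character(pathways)
  pathways[is.na(pathways) | pathways == ""] <- "unassigned"
  per_feature <- data.frame(
    feature = records$feature, pathway = pathways,
    log2_fc = records$log2_fc,
    minus_log10_q = -log10(records$q_value),
    star = !is.na(records$q_value) & records$q_value < 0.05,
    stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(per_feature, per_feature$pathway),
    function(d) data.frame(pathway = d$pathway[1],
                           mean_log2_fc = mean(d$log2_fc, na.rm = TRUE),
                           n_features = nrow(d),
                           n_significant = sum(d$star),
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  if (enrichment) {
    N <- nrow(per_feature); K <- sum(per_feature$star)
    agg$enrichment_p <- vapply(seq_len(nrow(agg)), function(i) {
      n <- agg$n_features[i]; k <- agg$n_significant[i]
      lo <- stats::phyper(k, K, N - K, n)
      hi <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      min(1, 2 * min(lo, hi))
    }, numeric(1))
  }
  attr(agg, "per_feature") <- per_feature
  agg
}
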