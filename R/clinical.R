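#' PCA-based PAH exposure score
#'
#' Summarizes a panel of hair PAH concentrations into a single exposure score
#' per subject: the first principal component of the log-transformed,
#' centered and scaled concentrations. PCA is run on the correlation matrix
#' because individual PAHs span orders of magnitude. The component sign is
#' fixed so that the score correlates positively with the per-subject mean of
#' log concentrations, i.e. higher score = higher overall exposure.
#'
#' @param pah_block An [omics_block] (or matrix) of strictly positive PAH
#'   concentrations, subjects in rows.
#' @param lod_impute Optional positive scalar: values `<= 0` are replaced by
#'   `lod_impute / 2` (half the limit of detection) before the log transform.
#'   Without it, non-positive values are an error.
#' @return An object of class `pah_score`: list with `scores` (named numeric,
#'   zero mean), `loadings` (per-PAH weights), `variance_explained_pc1`
#'   (fraction of total variance on PC1).
#' @export
pah_score <- function(pah_block, lod_impute = NULL) {
  x <- block_matrix(pah_block)
  if (any(x <= 0, na.rm = TRUE)) {
    if (is.null(lod_impute))
      stop("non-positive PAH concentrations found; supply 'lod_impute' ",
           "(limit of detection) to impute LOD/2 before the log transform")
    stopifnot(lod_impute > 0)
    x[x <= 0] <- lod_impute / 2
  }
  lx <- log(x)
  pc <- stats::prcomp(lx, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  ref <- rowMeans(lx)
  s <- stats::cor(scores, ref)
  if (is.finite(s) && s < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  structure(list(scores = scores, loadings = loadings,
                 variance_explained_pc1 = unname(pc$sdev[1]^2 /
                                                   sum(pc$sdev^2))),
            class = "pah_score")
}

#' @export
print.pah_score <- function(x, ...) {
  cat(sprintf("<pah_score: %d subjects, PC1 explains %.1f%% of variance>\n",
              length(x$scores), 100 * x$variance_explained_pc1))
  invisible(x)
}

#' Split subjects at the median of a score
#'
#' @param scores Named numeric vector (e.g. `pah_score()$scores`).
#' @return Factor with levels `below`/`above`; values strictly greater than
#'   the median are `above`, ties at the median go to `below`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 subjects")
  med <- stats::median(scores)
  grp <- factor(ifelse(scores > med, "above", "below"),
                levels = c("below", "above"))
  if (all(grp == "below"))
    warning("all scores at or below the median (constant scores?)")
  names(grp) <- names(scores)
  grp
}

#' Two-sample Wilcoxon rank-sum test on an ordered contingency table
#'
#' Rank-sum test for ordinal clinical scores tabulated as a 2 x k table of
#' counts over ordered categories, in the convention of classical clinical
#' reporting software: midranks within tied categories, tie-corrected
#' variance, a 0.5 continuity correction on the rank-sum statistic, and a
#' two-sided p-value referred by default to a Student-t distribution with
#' N - 1 degrees of freedom (`method = "wilcoxon_t_approx"`). The plain
#' normal approximation is available as `method = "wilcoxon_normal"`.
#'
#' @param table 2 x k matrix of nonnegative counts; rows are the two groups,
#'   columns are the ordered categories (left = lowest).
#' @param method `"wilcoxon_t_approx"` (default) or `"wilcoxon_normal"`.
#' @return List of class `clin_test`: `statistic` (rank sum of group 1),
#'   `z_or_chi2` (continuity-corrected z), `p_value`, `method`, `df`.
#' @export
wilcoxon_ordinal <- function(table,
                             method = c("wilcoxon_t_approx",
                                        "wilcoxon_normal")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (nrow(table) != 2 || ncol(table) < 2)
    stop("'table' must be 2 x k with k >= 2 ordered categories")
  if (any(table < 0) || any(table != round(table)))
    stop("'table' must contain nonnegative integer counts")
  n1 <- sum(table[1, ]); n2 <- sum(table[2, ])
  if (n1 == 0 || n2 == 0) stop("each group must have at least one subject")
  N <- n1 + n2
  tot <- colSums(table)
  midranks <- cumsum(tot) - (tot - 1) / 2
  S <- sum(table[1, ] * midranks)
  E <- n1 * (N + 1) / 2
  tie <- sum(tot^3 - tot) / (N * (N - 1))
  V <- n1 * n2 / 12 * ((N + 1) - tie)
  d <- S - E
  z <- if (V > 0) (d - sign(d) * 0.5) / sqrt(V) else 0
  if (d == 0) z <- 0
  df <- if (method == "wilcoxon_t_approx") N - 1 else Inf
  p <- if (z == 0) 1 else 2 * stats::pt(-abs(z), df = df)
  structure(list(statistic = S, z_or_chi2 = z, p_value = min(p, 1),
                 method = method, df = df),
            class = "clin_test")
}

#' Pearson chi-squared test on a 2 x 2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-squared test with
#' 1 degree of freedom, for binary clinical signs tabulated by group.
#'
#' @param table 2 x 2 matrix of nonnegative counts.
#' @return List of class `clin_test` as in [wilcoxon_ordinal()];
#'   `z_or_chi2` carries the chi-squared statistic.
#' @export
chi2_binary <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("'table' must be 2 x 2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in 2 x 2 table")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 z_or_chi2 = unname(ct$statistic),
                 p_value = unname(ct$p.value),
                 method = "chi2_pearson", df = 1),
            class = "clin_test")
}

#' @export
print.clin_test <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, p = %.4g>\n", x$method,
              x$z_or_chi2, x$p_value))
  invisible(x)
}

#' Prevalence of a clinical sign from one row of counts
#'
#' Percentage of subjects presenting the sign at any intensity, i.e.
#' `100 * (total - n_No) / total`, reported to one decimal.
#'
#' @param counts Named nonnegative integer vector of category counts for one
#'   group; one category must be the reference absence category.
#' @param no_category Name of the absence category (default `"No"`).
#' @return Prevalence percent, rounded to 1 decimal.
#' @export
prevalence <- function(counts, no_category = "No") {
  if (!no_category %in% names(counts))
    stop("no category named '", no_category, "' in counts")
  total <- sum(counts)
  if (total == 0) stop("zero total count")
  round_half_away(100 * (total - counts[[no_category]]) / total, 1)
}

#' Recompute the full two-city clinical summary table
#'
#' Applies [wilcoxon_ordinal()] to ordinal signs and [chi2_binary()] to
#' binary signs of a [table1_fixture()]-shaped list, for both the city and
#' PAH median-split tabulations, and adds prevalences per group.
#'
#' @param fixture Output of [table1_fixture()] (or same shape).
#' @return data.frame with one row per sign x grouping: sign, type, grouping,
#'   p_value, prevalence of each group.
#' @export
clinical_summary <- function(fixture = table1_fixture()) {
  rows <- lapply(names(fixture), function(nm) {
    s <- fixture[[nm]]
    do.call(rbind, lapply(c("city", "pah"), function(g) {
      tab <- s[[g]]
      res <- if (s$type == "ordinal") wilcoxon_ordinal(tab)
             else chi2_binary(tab)
      data.frame(sign = nm, label = s$label, type = s$type, grouping = g,
                 group1 = rownames(tab)[1], group2 = rownames(tab)[2],
                 prevalence1 = prevalence(tab[1, ]),
                 prevalence2 = prevalence(tab[2, ]),
                 p_value = res$p_value, method = res$method,
                 row.names = NULL)
    }))
  })
  do.call(rbind, rows)
}
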