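#' Read an omics block from a delimited file
#'
#' Reads a TSV (or CSV, by extension) with subject IDs in the first column
#' and one header column per feature, into an [omics_block]. Missing values
#' are allowed and propagate as `NA`; duplicate subject IDs, ragged rows and
#' non-numeric cells are rejected with descriptive errors.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` file.
#' @param name Block name; defaults to the file name without extension.
#' @param feature_meta_path Optional sidecar TSV with a `feature` column of
#'   per-feature metadata (e.g. pathway labels).
#' @return An [omics_block].
#' @export
read_block <- function(path, name = NULL, feature_meta_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA)
  if (ncol(raw) < 2) stop("expected a subject-ID column plus >= 1 feature")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate subject ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- raw[, -1, drop = FALSE]
  bad <- names(m)[!vapply(m, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric cells in feature column(s): ",
         paste(bad, collapse = ", "))
  x <- as.matrix(m)
  rownames(x) <- ids
  meta <- if (!is.null(feature_meta_path))
    utils::read.table(feature_meta_path, header = TRUE, sep = sep,
                      check.names = FALSE, stringsAsFactors = FALSE)
  else NULL
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  omics_block(x, name = name, feature_meta = meta)
}

#' Write an omics block to TSV
#'
#' Inverse of [read_block()]: subjects in rows, first column `subject_id`,
#' then one column per feature.
#'
#' @param block An [omics_block] or matrix.
#' @param path Output TSV path.
#' @export
write_block <- function(block, path) {
  x <- block_matrix(block)
  df <- data.frame(subject_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generated cohort to a directory
#'
#' Writes each block, the clinical table, and the ground truth (latent
#' scores, subject labels and active feature sets) as plain TSV sidecars.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$blocks))
    write_block(cohort$blocks[[nm]], file.path(dir, paste0(nm, ".tsv")))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  utils::write.table(
    data.frame(subject_id = rownames(tr$latent_scores), tr$latent_scores),
    file.path(dir, "truth_latent_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(subject_id = names(tr$cluster_labels),
               cluster = as.integer(tr$cluster_labels),
               city = as.character(tr$city_labels)),
    file.path(dir, "truth_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  act <- do.call(rbind, lapply(names(tr$active_feature_sets), function(b) {
    sets <- tr$active_feature_sets[[b]]
    do.call(rbind, lapply(names(sets), function(s) {
      if (!length(sets[[s]])) return(NULL)
      data.frame(block = b, set = s, index = sets[[s]],
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(act, file.path(dir, "truth_active_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the full multi-block analysis pipeline
#'
#' Chains all stages of the analysis on a cohort (real, read with
#' [read_block()], or synthetic from [generate_cohort()]):
#'
#' 1. PAH exposure score and median split ([pah_score()],
#'    [median_split()]); clinical sign tests by city ([wilcoxon_ordinal()]
#'    / [chi2_binary()]);
#' 2. metabolite volcano screen by city ([volcano()]) with pathway
#'    aggregation when pathway labels are available;
#' 3. random-forest city classification with permutation importance
#'    ([fit_forest()], [permutation_vimp()]);
#' 4. sparse CCA of PAH vs metabolites, and OTU vs metabolites adjusted for
#'    city ([permute_tune()]), with cross-correlation matrices;
#' 5. diversity links: Shannon index, Pearson screen, PLS1 variance
#'    explained ([shannon()], [metabolite_diversity_correlations()],
#'    [pls_variance_explained()]);
#' 6. MAXVAR-A consensus over the sCCA-selected PAH, metabolite and OTU
#'    features, Ward clustering ([maxvar_a()], [consensus_clustering()]);
#' 7. v-test characterization of the clusters
#'    ([characterize_clusters()]).
#'
#' Blocks enter sCCA and the consensus on the log scale (OTUs on relative
#' abundances). All randomness flows from `seed`.
#'
#' @param blocks Named list with elements `metabolites`, `pah`,
#'   `bacterial_otu` ([omics_block]s).
#' @param clinical data.frame with `subject_id`, `city`, plus clinical sign
#'   columns (ordinal integer or 0/1).
#' @param nperms Permutations for sCCA tuning (study value 500).
#' @param scca_grid Sparsity fraction grid for [permute_tune()].
#' @param n_trees Trees for the random forest.
#' @param k Number of consensus clusters; `NULL` = dendrogram gap rule.
#' @param use_full_blocks If TRUE the consensus uses full blocks instead of
#'   the sCCA-selected features.
#' @param seed Master seed.
#' @param out_dir Optional directory; if given, all result tables are
#'   written as TSVs.
#' @return List of class `pipeline_report` with elements `pah_score`,
#'   `pah_groups`, `clinical_tests`, `volcano`, `pathways`, `vimp`,
#'   `scca_pah`, `scca_otu`, `cross_cor_pah`, `cross_cor_otu`,
#'   `diversity`, `diversity_correlations`, `pls`, `consensus`, `clusters`,
#'   `city_by_cluster`, `vtests`, `seed`.
#' @export
run_pipeline <- function(blocks, clinical, nperms = 100,
                         scca_grid = seq(0.1, 0.7, by = 0.1),
                         n_trees = 300, k = NULL, use_full_blocks = FALSE,
                         seed = 1, out_dir = NULL) {
  for (nm in c("metabolites", "pah", "bacterial_otu"))
    if (is.null(blocks[[nm]])) stop("missing block '", nm, "' in input")
  if (is.null(clinical$city)) stop("clinical table must have a 'city' column")
  metab <- block_matrix(blocks$metabolites)
  pah <- block_matrix(blocks$pah)
  otu <- block_matrix(blocks$bacterial_otu)
  city <- factor(clinical$city)
  stopifnot(nrow(metab) == nrow(pah), nrow(pah) == nrow(otu),
            nrow(metab) == nrow(clinical))

  # 1. exposure score and clinical tests
  ps <- pah_score(pah)
  grp <- median_split(ps$scores)
  sign_cols <- setdiff(names(clinical), c("subject_id", "city"))
  clin_tests <- do.call(rbind, lapply(sign_cols, function(cn) {
    col <- clinical[[cn]]
    res <- lapply(list(city = city, pah = grp), function(g) {
      tab <- table(g, factor(col, levels = sort(unique(col))))
      if (length(unique(col)) <= 2 && all(dim(tab) == c(2, 2)) &&
          all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        chi2_binary(tab)
      else wilcoxon_ordinal(tab)
    })
    data.frame(sign = cn, grouping = c("city", "pah"),
               p_value = vapply(res, `[[`, numeric(1), "p_value"),
               method = vapply(res, `[[`, character(1), "method"),
               stringsAsFactors = FALSE)
  }))

  # 2. volcano by city (first level = reference)
  volc <- volcano(metab, city)
  pathways <- if (!is.null(blocks$metabolites$feature_meta$sub_pathway))
    pathway_summary(volc, blocks$metabolites$feature_meta$sub_pathway)
  else NULL

  # 3. random forest + VIMP
  forest <- fit_forest(metab, city, n_trees = n_trees, seed = seed)
  vimp <- permutation_vimp(forest, metab, seed = seed)

  # 4. sparse CCA: PAH <-> metabolites; OTU <-> metabolites (city-adjusted)
  lmetab <- log(metab)
  lpah <- log(pah)
  lotu <- log(otu + min(otu[otu > 0]) / 2)
  scca_pah <- permute_tune(lpah, lmetab, grid = scca_grid, nperms = nperms,
                           seed = seed)
  scca_otu <- permute_tune(lotu, lmetab, grid = scca_grid, nperms = nperms,
                           seed = seed + 1, confounder = city)
  adj_m <- residualize_on_confounder(lmetab, city)
  adj_o <- residualize_on_confounder(lotu, city)
  cc_pah <- cross_correlation(
    lpah[, scca_pah$pair$support_x, drop = FALSE],
    lmetab[, scca_pah$pair$support_y, drop = FALSE])
  cc_otu <- cross_correlation(
    adj_o[, scca_otu$pair$support_x, drop = FALSE],
    adj_m[, scca_otu$pair$support_y, drop = FALSE])

  # 5. diversity links
  div <- shannon(otu, kingdom = "bacterial")
  div_cor <- metabolite_diversity_correlations(lmetab, div)
  pls <- pls_variance_explained(lmetab, div, n_components = 2, seed = seed)

  # 6. consensus space on sCCA-selected features, Ward clustering
  sel <- if (use_full_blocks)
    list(pah = lpah, metabolites = lmetab, bacterial_otu = lotu)
  else list(
    pah = lpah[, scca_pah$pair$support_x, drop = FALSE],
    metabolites = lmetab[, union(scca_pah$pair$support_y,
                                 scca_otu$pair$support_y), drop = FALSE],
    bacterial_otu = lotu[, scca_otu$pair$support_x, drop = FALSE])
  consensus <- maxvar_a(sel, n_components = 2)
  clusters <- consensus_clustering(consensus, k = k)
  city_by_cluster <- cluster_composition(clusters, city)

  # 7. v-test characterization
  vt_blocks <- list(metabolites = metab, pah = pah)
  vt_clinical <- clinical[, sign_cols, drop = FALSE]
  vtests <- characterize_clusters(clusters, vt_blocks, vt_clinical)

  report <- structure(
    list(pah_score = ps, pah_groups = grp, clinical_tests = clin_tests,
         volcano = volc, pathways = pathways, vimp = vimp,
         scca_pah = scca_pah, scca_otu = scca_otu,
         cross_cor_pah = cc_pah, cross_cor_otu = cc_otu,
         diversity = div, diversity_correlations = div_cor, pls = pls,
         consensus = consensus, clusters = clusters,
         city_by_cluster = city_by_cluster, vtests = vtests, seed = seed),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  volcano: %d/%d significant features\n",
              sum(x$volcano$significant), nrow(x$volcano)))
  cat(sprintf("  RF OOB error: %.3f\n", attr(x$vimp, "oob_error")))
  cat(sprintf("  sCCA PAH-metab: rho = %.3f, p = %.4g (support %d x %d)\n",
              x$scca_pah$pair$rho, x$scca_pah$p_value,
              length(x$scca_pah$pair$support_x),
              length(x$scca_pah$pair$support_y)))
  cat(sprintf("  sCCA OTU-metab: rho = %.3f, p = %.4g (support %d x %d)\n",
              x$scca_otu$pair$rho, x$scca_otu$p_value,
              length(x$scca_otu$pair$support_x),
              length(x$scca_otu$pair$support_y)))
  cat(sprintf("  PLS R2Y/Q2 (2 comp): %.3f / %.3f\n",
              x$pls$r2y[x$pls$n_components], x$pls$q2[x$pls$n_components]))
  cat(sprintf("  consensus: %.1f%% variance on 2 components, k = %d\n",
              100 * sum(x$consensus$variance_explained), x$clusters$k))
  invisible(x)
}

# Write every tabular element of a pipeline report as TSV.
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, nm) utils::write.table(
    df, file.path(out_dir, paste0(nm, ".tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(data.frame(subject_id = names(report$pah_score$scores),
               score = report$pah_score$scores,
               group = as.character(report$pah_groups)), "pah_score")
  w(report$clinical_tests, "clinical_tests")
  w(report$volcano, "volcano")
  if (!is.null(report$pathways)) w(report$pathways, "pathways")
  w(report$vimp, "vimp")
  for (nm in c("scca_pah", "scca_otu")) {
    pr <- report[[nm]]$pair
    w(data.frame(side = c(rep("x", length(pr$support_x)),
                          rep("y", length(pr$support_y))),
                 feature = c(names(pr$u)[pr$support_x],
                             names(pr$v)[pr$support_y]),
                 weight = c(pr$u[pr$support_x], pr$v[pr$support_y])),
      paste0(nm, "_weights"))
    w(data.frame(grid = report[[nm]]$grid, score = report[[nm]]$score,
                 z_obs = report[[nm]]$z_obs), paste0(nm, "_tuning"))
  }
  w(data.frame(feature_x = rep(rownames(report$cross_cor_pah),
                               ncol(report$cross_cor_pah)),
               feature_y = rep(colnames(report$cross_cor_pah),
                               each = nrow(report$cross_cor_pah)),
               r = as.vector(report$cross_cor_pah)), "cross_cor_pah")
  w(report$diversity_correlations, "diversity_correlations")
  w(data.frame(component = seq_along(report$pls$r2y),
               r2y = report$pls$r2y, q2 = report$pls$q2), "pls")
  w(data.frame(subject_id = rownames(report$consensus$consensus_scores),
               report$consensus$consensus_scores,
               cluster = report$clusters$cluster), "consensus_scores")
  w(as.data.frame(report$city_by_cluster), "city_by_cluster")
  w(report$vtests, "vtests")
  invisible(out_dir)
}
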