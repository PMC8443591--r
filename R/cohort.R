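#' Specification of a synthetic multi-block cohort
#'
#' Parameters of the generator in [generate_cohort()]. Defaults emulate the
#' two-city study design this package targets: 67 subjects per city, ~350
#' skin metabolites, 39 hair PAHs, 143 microbial OTUs, two planted sparse
#' canonical pairs (metabolites-PAH and metabolites-OTU), a city shift on the
#' PAH block, and 4 latent subject clusters expressed across all blocks.
#'
#' @param n_per_group Subjects per city (two cities).
#' @param n_metabolites,n_pah,n_otu Features per block.
#' @param n_latent_factors Number of planted cross-block canonical factors:
#'   1 (metabolites-PAH only) or 2 (adds metabolites-OTU).
#' @param sparse_support_size Number of active features per block and per
#'   canonical factor; the same number of disjoint features per block carry
#'   the cluster mean shifts.
#' @param canonical_correlation Target correlation, in `[0, 1]`, between the
#'   planted latent projections of each canonical pair (at
#'   `cluster_separation = 0`; cluster structure adds shared covariation on
#'   top, see [generate_cohort()]).
#' @param city_effect_size Standardized mean shift added to every log-PAH
#'   feature for subjects of the more polluted city.
#' @param n_clusters Number of latent subject clusters.
#' @param cluster_separation Distance between neighbouring cluster centers in
#'   the 2-D latent factor space, in within-cluster standard deviation units.
#' @param noise_sd Feature-level noise standard deviation on the log scale,
#'   relative to unit-variance latent factors.
#' @param zero_inflation_prob Probability of zeroing an OTU intensity before
#'   closure (default 0: plain compositional log-normal).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 67L, n_metabolites = 350L,
                        n_pah = 39L, n_otu = 143L, n_latent_factors = 2L,
                        sparse_support_size = 10L,
                        canonical_correlation = 0.7, city_effect_size = 1,
                        n_clusters = 4L, cluster_separation = 5,
                        noise_sd = 1, zero_inflation_prob = 0,
                        seed = 1L) {
  spec <- list(n_per_group = as.integer(n_per_group),
               n_metabolites = as.integer(n_metabolites),
               n_pah = as.integer(n_pah), n_otu = as.integer(n_otu),
               n_latent_factors = as.integer(n_latent_factors),
               sparse_support_size = as.integer(sparse_support_size),
               canonical_correlation = canonical_correlation,
               city_effect_size = city_effect_size,
               n_clusters = as.integer(n_clusters),
               cluster_separation = cluster_separation,
               noise_sd = noise_sd,
               zero_inflation_prob = zero_inflation_prob,
               seed = as.integer(seed))
  counts <- c("n_per_group", "n_metabolites", "n_pah", "n_otu",
              "n_latent_factors", "sparse_support_size", "n_clusters")
  for (f in counts)
    if (is.na(spec[[f]]) || spec[[f]] < 1L)
      stop("'", f, "' must be a count >= 1")
  if (spec$n_latent_factors > 2L)
    stop("'n_latent_factors' must be 1 or 2 (one canonical pair per ",
         "non-metabolite block)")
  if (spec$canonical_correlation < 0 || spec$canonical_correlation > 1)
    stop("'canonical_correlation' must be in [0, 1]")
  if (spec$noise_sd < 0 || spec$cluster_separation < 0)
    stop("'noise_sd' and 'cluster_separation' must be nonnegative")
  s <- spec$sparse_support_size
  need_metab <- s * spec$n_latent_factors + s
  if (need_metab > spec$n_metabolites)
    stop("sparse supports (", need_metab, " features) exceed metabolite ",
         "block width (", spec$n_metabolites, ")")
  if (2L * s > spec$n_pah)
    stop("sparse supports (", 2L * s, " features) exceed PAH block width (",
         spec$n_pah, ")")
  if (spec$n_latent_factors >= 2L && 2L * s > spec$n_otu)
    stop("sparse supports (", 2L * s, " features) exceed OTU block width (",
         spec$n_otu, ")")
  class(spec) <- "cohort_spec"
  spec
}

# Cluster centers on the 2-D latent grid, one row per cluster, scaled so
# neighbouring centers are 'sep' apart along each axis.
cluster_centers <- function(k, sep) {
  g1 <- rep(c(-1, 1), length.out = k)
  g2 <- rep(c(-1, -1, 1, 1), length.out = k)
  cbind(g1, g2) * sep / 2
}

#' Generate a synthetic multi-block cohort with known ground truth
#'
#' Simulates a two-city cohort with the multi-block structure this package
#' analyzes. All blocks derive from a latent Gaussian factor model on the log
#' scale: metabolite and PAH abundances are exponentiated (log-normal), OTU
#' intensities are additionally closed to relative abundances summing to 1
#' per subject. Planted structure, all recorded in the returned `truth`:
#'
#' * one sparse canonical pair per non-metabolite block: a latent factor
#'   loads only on `sparse_support_size` features of the metabolite block
#'   and of the partner block, with latent-projection correlation
#'   `canonical_correlation`;
#' * `n_clusters` subject clusters whose centers tilt the canonical factors
#'   (cross-block cluster structure) and additionally shift a disjoint set of
#'   `sparse_support_size` marker features per block;
#' * a city mean shift of `city_effect_size` on all log-PAH features;
#' * one ordinal (1-4) and one binary clinical sign obtained by thresholding
#'   a cluster-tied Gaussian latent variable at fixed quantiles.
#'
#' With `cluster_separation = 0` the clusters are pure labels without signal
#' and the canonical pairs have correlation exactly
#' `canonical_correlation`; with separation > 0 the shared cluster geometry
#' adds cross-block covariation on top (by design: clusters *are* cross-block
#' structure).
#'
#' @param spec A [cohort_spec()].
#' @return List with elements
#'   `blocks` (named list of [omics_block]: `metabolites`, `pah`,
#'   `bacterial_otu`), `clinical` (data.frame: `subject_id`, `city`,
#'   `spread_macules` ordinal 1-4, `lentigo` 0/1), and `truth` (list:
#'   `latent_scores`, `active_feature_sets`, `cluster_labels`,
#'   `city_labels`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- 2L * spec$n_per_group
    s <- spec$sparse_support_size
    r <- spec$canonical_correlation
    subjects <- sprintf("S%03d", seq_len(n))
    city <- factor(rep(c("Dalian", "Baoding"), each = spec$n_per_group),
                   levels = c("Dalian", "Baoding"))
    cluster <- sample(rep(seq_len(spec$n_clusters), length.out = n))
    centers <- cluster_centers(spec$n_clusters, spec$cluster_separation)
    tilt1 <- centers[cluster, 1]
    tilt2 <- centers[cluster, 2]

    # canonical factor pair 1 (metabolites <-> PAH), tied to cluster axis 1
    common1 <- stats::rnorm(n)
    u1 <- sqrt(r) * common1 + sqrt(1 - r) * stats::rnorm(n) + tilt1
    v1 <- sqrt(r) * common1 + sqrt(1 - r) * stats::rnorm(n) + tilt1
    # canonical factor pair 2 (metabolites <-> OTU), tied to cluster axis 2
    common2 <- stats::rnorm(n)
    u2 <- sqrt(r) * common2 + sqrt(1 - r) * stats::rnorm(n) + tilt2
    v2 <- sqrt(r) * common2 + sqrt(1 - r) * stats::rnorm(n) + tilt2

    two_pairs <- spec$n_latent_factors >= 2L

    # log-scale block assembly: baseline feature means, latent loadings on
    # the sparse supports, cluster marker shifts, iid feature noise
    build_log_block <- function(p, active, marker, prefix) {
      mu <- stats::rnorm(p, mean = 0, sd = 1)
      L <- matrix(stats::rnorm(n * p, sd = 1), n, p)
      for (nm in names(active)) {
        idx <- active[[nm]]$idx
        L[, idx] <- active[[nm]]$latent +
          matrix(stats::rnorm(n * length(idx), sd = spec$noise_sd),
                 n, length(idx))
      }
      if (length(marker)) {
        delta <- matrix(sample(c(-1, 1),
                               spec$n_clusters * length(marker),
                               replace = TRUE),
                        spec$n_clusters, length(marker)) *
          spec$cluster_separation / 2
        L[, marker] <- matrix(stats::rnorm(n * length(marker)),
                              n, length(marker)) +
          delta[cluster, , drop = FALSE]
      }
      L <- sweep(L, 2, mu, "+")
      dimnames(L) <- list(subjects, paste0(prefix, seq_len(p)))
      L
    }

    metab_active <- list(pair_pah = list(idx = seq_len(s), latent = u1))
    if (two_pairs)
      metab_active$pair_otu <- list(idx = s + seq_len(s), latent = u2)
    metab_marker <- s * spec$n_latent_factors + seq_len(s)
    Lm <- build_log_block(spec$n_metabolites, metab_active, metab_marker, "M")

    pah_active <- list(pair = list(idx = seq_len(s), latent = v1))
    pah_marker <- s + seq_len(s)
    Lp <- build_log_block(spec$n_pah, pah_active, pah_marker, "PAH")
    Lp <- Lp + spec$city_effect_size * (city == "Baoding")

    otu_active <- if (two_pairs)
      list(pair = list(idx = seq_len(s), latent = v2)) else list()
    otu_marker <- (if (two_pairs) s else 0L) + seq_len(s)
    Lo <- build_log_block(spec$n_otu, otu_active, otu_marker, "OTU")

    Xo <- exp(Lo)
    if (spec$zero_inflation_prob > 0) {
      drop <- matrix(stats::runif(length(Xo)) < spec$zero_inflation_prob,
                     nrow(Xo), ncol(Xo))
      Xo[drop] <- 0
      zero_rows <- rowSums(Xo) == 0
      if (any(zero_rows)) Xo[zero_rows, 1] <- 1e-6
    }
    Xo <- Xo / rowSums(Xo)

    # clinical signs: threshold a cluster-tied latent at fixed quantiles
    # (sparse upper categories, as in typical dermatological score tables)
    tilt_norm <- if (spec$cluster_separation > 0)
      (tilt1 + tilt2) / (spec$cluster_separation) else rep(0, n)
    t_ord <- tilt_norm + stats::rnorm(n)
    cuts <- stats::qnorm(c(0.60, 0.85, 0.95), sd = stats::sd(t_ord))
    spread_macules <- as.integer(cut(t_ord - mean(t_ord),
                                     c(-Inf, cuts, Inf), labels = FALSE))
    t_bin <- tilt_norm + stats::rnorm(n)
    lentigo <- as.integer(t_bin - mean(t_bin) >
                            stats::qnorm(0.75, sd = stats::sd(t_bin)))

    metab_meta <- data.frame(
      feature = colnames(Lm),
      super_pathway = rep(c("Amino Acid", "Lipid", "Peptide", "Xenobiotics",
                            "Nucleotide", "Carbohydrate", "Cofactors"),
                          length.out = spec$n_metabolites),
      sub_pathway = rep(paste0("subpathway_", 1:20),
                        length.out = spec$n_metabolites),
      stringsAsFactors = FALSE)

    blocks <- list(
      metabolites = omics_block(exp(Lm), "metabolites", metab_meta),
      pah = omics_block(exp(Lp), "pah"),
      bacterial_otu = omics_block(Xo, "bacterial_otu"))

    latent <- cbind(u1 = u1, v1 = v1, u2 = u2, v2 = v2)
    rownames(latent) <- subjects
    truth <- list(
      latent_scores = latent,
      active_feature_sets = list(
        metabolites = c(lapply(metab_active, `[[`, "idx"),
                        list(cluster_markers = metab_marker)),
        pah = c(lapply(pah_active, `[[`, "idx"),
                list(cluster_markers = pah_marker)),
        bacterial_otu = c(lapply(otu_active, `[[`, "idx"),
                          list(cluster_markers = otu_marker))),
      cluster_labels = stats::setNames(cluster, subjects),
      city_labels = stats::setNames(city, subjects))

    clinical <- data.frame(subject_id = subjects, city = city,
                           spread_macules = spread_macules,
                           lentigo = lentigo, stringsAsFactors = FALSE)

    list(blocks = blocks, clinical = clinical, truth = truth)
  })
}
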