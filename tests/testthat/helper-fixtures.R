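# Shared helpers for the test suite. All fixtures are generated in code.

# A small, fast cohort spec for pipeline-level tests.
small_cohort_spec <- function(seed = 1, ...) {
  cohort_spec(n_per_group = 40, n_metabolites = 60, n_pah = 25, n_otu = 40,
              seed = seed, ...)
}

# Jaccard similarity of two index sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Exact two-sided p-value for the rank-sum statistic of a 2 x k ordered
# count table, by enumeration of all group-1 subject assignments.
wilcoxon_exact_p <- function(tab) {
  cats <- rep(seq_len(ncol(tab)), colSums(tab))
  tot <- colSums(tab)
  mid <- cumsum(tot) - (tot - 1) / 2
  ranks <- mid[cats]
  n1 <- sum(tab[1, ])
  S_obs <- sum(tab[1, ] * mid)
  E <- n1 * (sum(tab) + 1) / 2
  combs <- utils::combn(length(cats), n1)
  S <- apply(combs, 2, function(i) sum(ranks[i]))
  mean(abs(S - E) >= abs(S_obs - E) - 1e-9)
}

# Monte-Carlo two-sided permutation p-value for the same statistic.
wilcoxon_mc_p <- function(tab, nsim = 20000, seed = 1) {
  set.seed(seed)
  cats <- rep(seq_len(ncol(tab)), colSums(tab))
  tot <- colSums(tab)
  mid <- cumsum(tot) - (tot - 1) / 2
  ranks <- mid[cats]
  n1 <- sum(tab[1, ])
  S_obs <- sum(tab[1, ] * mid)
  E <- n1 * (sum(tab) + 1) / 2
  S <- replicate(nsim, sum(sample(ranks, n1)))
  mean(abs(S - E) >= abs(S_obs - E) - 1e-9)
}
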