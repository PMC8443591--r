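# Printed prevalence percentages for the seven facial pigmentary signs of the
# two-city cohort (67 women per group), tabulated by city and by PAH-score
# median split. These percentages are input data (a published summary table);
# integer counts are reconstructed from them at run time.

.table1_data <- function() {
  sign <- function(label, type, categories, dalian, baoding, pah_below,
                   pah_above) {
    list(label = label, type = type, categories = categories,
         pct = rbind(Dalian = dalian, Baoding = baoding,
                     `PAH<MED` = pah_below, `PAH>MED` = pah_above))
  }
  out <- list(
    spread_macules_forehead = sign(
      "Spread macules on forehead", "ordinal",
      c("No", "Weak", "Moderate", "Severe"),
      c(94.03, 2.99, 2.99, 0.00),
      c(74.63, 17.91, 2.99, 4.48),
      c(91.04, 7.46, 1.49, 0.00),
      c(77.61, 13.43, 4.48, 4.48)),
    spread_macules_cheeks = sign(
      "Spread macules on cheeks", "ordinal",
      c("No", "Weak", "Moderate", "Severe"),
      c(64.18, 32.84, 2.99, 0.00),
      c(43.28, 32.84, 19.40, 4.48),
      c(61.19, 34.33, 2.99, 1.49),
      c(46.27, 31.34, 19.40, 2.99)),
    hyperpigmented_spots_forehead = sign(
      "Hyperpigmented spots on forehead", "ordinal",
      c("No", "Weak", "Moderate"),
      c(26.87, 73.13, 0.00),
      c(20.90, 76.12, 2.99),
      c(25.37, 74.63, 0.00),
      c(22.39, 74.63, 2.99)),
    simplex_lentigo_cheek = sign(
      "Simplex lentigo on cheek", "binary", c("No", "Yes"),
      c(25.37, 74.63), c(13.43, 86.57), c(25.37, 74.63), c(13.43, 86.57)),
    actinic_lentigines_cheek = sign(
      "Actinic lentigines on cheek", "binary", c("No", "Yes"),
      c(77.61, 22.39), c(76.12, 23.88), c(82.09, 17.91), c(71.64, 28.36)),
    melasma_forehead = sign(
      "Melasma or melasma like on forehead", "binary", c("No", "Yes"),
      c(97.01, 2.99), c(91.04, 8.96), c(97.01, 2.99), c(91.04, 8.96)),
    melasma_cheek = sign(
      "Melasma or melasma like on cheek", "binary", c("No", "Yes"),
      c(80.60, 19.40), c(85.07, 14.93), c(80.60, 19.40), c(85.07, 14.93))
  )
  for (i in seq_along(out)) colnames(out[[i]]$pct) <- out[[i]]$categories
  out
}

#' Worked-example contingency tables for the two-city clinical summary
#'
#' Reconstructs integer contingency tables for the seven facial pigmentary
#' signs of the 134-subject cohort (67 women per city) from their published
#' group percentages. Counts are recovered as
#' `round(pct * 67 / 100)` with half-away-from-zero rounding; every group's
#' counts sum back to 67 and the percentages recomputed from the counts match
#' the printed ones to two decimals.
#'
#' @param n_per_group Group size behind the printed percentages (67).
#' @return A named list with one element per clinical sign, each a list with:
#'   `label`, `type` (`"ordinal"` or `"binary"`), `city` and `pah` (2 x k
#'   integer count matrices, grouping rows x ordered category columns), and
#'   `pct` (the 4 x k printed percentages).
#' @export
#' @examples
#' fx <- table1_fixture()
#' fx$spread_macules_forehead$city
table1_fixture <- function(n_per_group = 67L) {
  dat <- .table1_data()
  lapply(dat, function(s) {
    counts <- round_half_away(s$pct * n_per_group / 100)
    storage.mode(counts) <- "integer"
    bad <- rowSums(counts) != n_per_group
    if (any(bad))
      stop("reconstructed counts do not sum to ", n_per_group, " for '",
           s$label, "'")
    list(label = s$label, type = s$type,
         city = counts[c("Dalian", "Baoding"), , drop = FALSE],
         pah = counts[c("PAH<MED", "PAH>MED"), , drop = FALSE],
         pct = s$pct)
  })
}
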