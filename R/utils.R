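# Internal helpers shared across modules.

# Column-standardize a matrix to mean 0, sd 1 (denominator n-1). Columns with
# zero variance are dropped with a warning: they carry no correlation signal
# and would produce NaNs downstream.
standardize_columns <- function(x, drop_constant = TRUE) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (drop_constant && any(sdv == 0)) {
    warning("dropping ", sum(sdv == 0), " zero-variance column(s)")
    keep <- sdv > 0
    x <- x[, keep, drop = FALSE]
    mu <- mu[keep]
    sdv <- sdv[keep]
  }
  sweep(sweep(x, 2, mu, "-"), 2, pmax(sdv, .Machine$double.eps), "/")
}

# Ensure a matrix has feature (column) names.
ensure_colnames <- function(x, prefix = "F") {
  if (is.null(colnames(x))) colnames(x) <- paste0(prefix, seq_len(ncol(x)))
  x
}

# round() half-away-from-zero (base round() is half-to-even).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Draw a derived RNG seed stream: local, does not disturb the caller's RNG
# unless seed is NULL.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
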