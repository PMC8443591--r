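#' Construct an omics block
#'
#' An `omics_block` is the basic data container of the package: a numeric
#' subjects-by-features matrix together with a block name and optional
#' per-feature metadata (e.g. metabolite super-/sub-pathway labels). Subjects
#' are rows, features are columns; both must be named so that blocks measured
#' on the same cohort can be aligned by subject ID.
#'
#' @param x Numeric matrix (or data.frame coercible to one), subjects in rows
#'   with rownames, features in columns with colnames.
#' @param name Character scalar naming the block (e.g. `"metabolites"`,
#'   `"pah"`, `"bacterial_otu"`).
#' @param feature_meta Optional data.frame of per-feature metadata. Must
#'   contain a `feature` column matching `colnames(x)`.
#' @return An object of class `omics_block`: a list with elements `x`,
#'   `name`, `feature_meta`.
#' @export
omics_block <- function(x, name = "block", feature_meta = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric subjects x features matrix")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate subject IDs in block '", name, "': ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (!is.null(feature_meta)) {
    if (!is.data.frame(feature_meta) || is.null(feature_meta$feature))
      stop("'feature_meta' must be a data.frame with a 'feature' column")
    feature_meta <- feature_meta[match(colnames(x), feature_meta$feature), ,
                                 drop = FALSE]
  }
  structure(list(x = x, name = name, feature_meta = feature_meta),
            class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block '%s': %d subjects x %d features>\n",
              x$name, nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$x)

# Coerce an omics_block or plain matrix argument to the underlying matrix.
block_matrix <- function(x) {
  if (inherits(x, "omics_block")) x$x
  else if (is.data.frame(x)) as.matrix(x)
  else x
}
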