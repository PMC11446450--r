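#' Preprocess counts into a high-dimensional expression representation
#'
#' Standard single-cell preprocessing: per-cell depth normalisation to a
#' common target, optional natural-log `log(1 + x)` transform, and an optional
#' PCA reduction used as input for the nonlinear embedders. The un-reduced
#' normalised log matrix is what the benchmark treats as the
#' "high-dimensional gene space" when computing baseline metrics.
#'
#' @param counts A [count_matrix()].
#' @param normalize_target `"median_depth"` (scale every cell to the median
#'   total count) or `"fixed_value"` (scale to `target_value`).
#' @param target_value Depth target when `normalize_target = "fixed_value"`.
#' @param log1p Apply `log(1 + x)` after normalisation.
#' @param pca_dim Optional number of principal components to reduce to; must
#'   be smaller than both dimensions. The reduction is recorded in the
#'   provenance.
#' @return An object of class `expression_matrix`: list with `values`
#'   (cells x features numeric matrix), `cell_ids`, `feature_ids`, `labels`,
#'   and `provenance` (list of the steps applied).
#' @examples
#' cm <- simulate_nb_counts(nb_sim_config(
#'   n_classes = 2, cells_per_class = 10, n_genes = 40, seed = 1
#' ))
#' ex <- preprocess(cm)
#' ex$provenance
#' @export
preprocess <- function(counts, normalize_target = c("median_depth", "fixed_value"),
                       target_value = NULL, log1p = TRUE, pca_dim = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  normalize_target <- match.arg(normalize_target)
  x <- counts$counts
  if (nrow(x) == 0 || ncol(x) == 0) abort("empty count matrix")
  depths <- rowSums(x)
  if (any(depths == 0)) {
    abort(paste0("cell(s) with zero total count: ",
                 paste(counts$cell_ids[depths == 0], collapse = ", ")))
  }
  target <- switch(normalize_target,
    median_depth = median(depths),
    fixed_value = {
      if (is.null(target_value) || target_value <= 0) {
        abort("fixed_value normalisation needs a positive target_value")
      }
      target_value
    }
  )
  v <- x * (target / depths)
  if (log1p) v <- log1p(v)
  prov <- list(normalize_target = normalize_target, target = target,
               log1p = log1p, pca_dim = NULL)
  feature_ids <- counts$gene_ids
  if (!is.null(pca_dim)) {
    pca_dim <- as.integer(pca_dim)
    if (pca_dim >= min(dim(v))) {
      abort("pca_dim must be smaller than both matrix dimensions")
    }
    v <- reduce_pca(v, pca_dim)
    feature_ids <- sprintf("PC%d", seq_len(pca_dim))
    prov$pca_dim <- pca_dim
  }
  structure(
    list(values = v, cell_ids = counts$cell_ids, feature_ids = feature_ids,
         labels = counts$labels, provenance = prov),
    class = "expression_matrix"
  )
}

# Deterministic PCA reduction via eigendecomposition of the feature
# covariance (features are at most a few thousand here, so the dense
# symmetric eigenproblem is cheaper and more reproducible than iterative SVD).
reduce_pca <- function(v, k) {
  ctr <- sweep(v, 2, colMeans(v))
  cv <- crossprod(ctr) / (nrow(v) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  rot <- ev$vectors[, seq_len(k), drop = FALSE]
  # orient each axis so its largest-magnitude loading is positive
  for (j in seq_len(k)) {
    piv <- which.max(abs(rot[, j]))
    if (rot[piv, j] < 0) rot[, j] <- -rot[, j]
  }
  ctr %*% rot
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<expression_matrix> %d cells x %d features (normalize=%s target=%.3g log1p=%s%s)\n",
    nrow(x$values), ncol(x$values), p$normalize_target, p$target, p$log1p,
    if (is.null(p$pca_dim)) "" else sprintf(" pca=%d", p$pca_dim)
  ))
  invisible(x)
}
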