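#' Embedding container
#'
#' All embedders return a tibble of class `embedding2d` with columns
#' `cell_id`, `x`, `y` (row i corresponds to input cell i) and attributes
#' `method`, `seed`, `run_index` and `source_fingerprint` (hash of the input
#' matrix).
#'
#' @param coords n x 2 numeric matrix.
#' @param cell_ids Character vector of length n.
#' @param method Embedding method name.
#' @param seed Seed used (NA for deterministic methods).
#' @param run_index Run counter within a benchmark.
#' @param source_fingerprint Hash of the embedded matrix.
#' @return An `embedding2d` tibble.
#' @keywords internal
#' @export
new_embedding <- function(coords, cell_ids, method, seed = NA_integer_,
                          run_index = 1L, source_fingerprint = NA_character_) {
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  check_finite(coords, paste0(method, " embedding"))
  out <- tibble(cell_id = cell_ids, x = coords[, 1], y = coords[, 2])
  class(out) <- c("embedding2d", class(out))
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  attr(out, "run_index") <- run_index
  attr(out, "source_fingerprint") <- source_fingerprint
  out
}

embed_input <- function(x) {
  m <- as_coords(x)
  check_finite(m, "embedding input")
  ids <- if (inherits(x, "expression_matrix")) x$cell_ids else
    sprintf("cell_%04d", seq_len(nrow(m)))
  list(m = m, ids = ids, fp = fingerprint(m))
}

#' 2D principal component embedding
#'
#' Projects mean-centred data onto its top two principal axes. Each axis is
#' oriented so that its largest-magnitude loading is positive, which makes the
#' result deterministic across linear-algebra backends.
#'
#' @param x An `expression_matrix` or numeric matrix (observations in rows).
#' @return An `embedding2d` (method `"pca"`).
#' @export
embed_pca2 <- function(x) {
  inp <- embed_input(x)
  m <- inp$m
  if (nrow(m) < 3 || ncol(m) < 2) abort("need >= 3 observations and >= 2 features")
  ctr <- sweep(m, 2, colMeans(m))
  sv <- svd(ctr, nu = 0, nv = min(dim(ctr)))
  tol <- max(dim(ctr)) * .Machine$double.eps * sv$d[1]
  if (sum(sv$d > tol) < 2) {
    abort("input is rank-deficient: fewer than 2 nonzero singular values")
  }
  rot <- sv$v[, 1:2, drop = FALSE]
  for (j in 1:2) {
    piv <- which.max(abs(rot[, j]))
    if (rot[piv, j] < 0) rot[, j] <- -rot[, j]
  }
  new_embedding(ctr %*% rot, inp$ids, "pca",
                source_fingerprint = inp$fp)
}

#' t-SNE embedding
#'
#' Thin seeded wrapper around [Rtsne::Rtsne()] with library defaults. The
#' caller's RNG state is preserved; the same seed and input give
#' bitwise-identical coordinates.
#'
#' @inheritParams embed_pca2
#' @param seed Integer seed.
#' @param run_index Run counter recorded in the result.
#' @param ... Passed to [Rtsne::Rtsne()] (e.g. `perplexity`).
#' @return An `embedding2d` (method `"tsne"`).
#' @export
embed_tsne <- function(x, seed = 0L, run_index = 1L, ...) {
  inp <- embed_input(x)
  if (nrow(inp$m) < 10) abort("need >= 10 observations for t-SNE")
  fit <- with_seed(seed, Rtsne::Rtsne(inp$m, dims = 2, pca = FALSE,
                                      check_duplicates = FALSE, ...))
  new_embedding(fit$Y, inp$ids, "tsne", seed = as.integer(seed),
                run_index = run_index, source_fingerprint = inp$fp)
}

#' UMAP embedding
#'
#' Thin seeded wrapper around [uwot::umap()] with library defaults, run
#' single-threaded so that a seed fully determines the output.
#'
#' @inheritParams embed_tsne
#' @param ... Passed to [uwot::umap()] (e.g. `n_neighbors`).
#' @return An `embedding2d` (method `"umap"`).
#' @export
embed_umap <- function(x, seed = 0L, run_index = 1L, ...) {
  inp <- embed_input(x)
  if (nrow(inp$m) < 10) abort("need >= 10 observations for UMAP")
  coords <- with_seed(seed, uwot::umap(inp$m, n_components = 2,
                                       n_threads = 1, n_sgd_threads = 1, ...))
  new_embedding(coords, inp$ids, "umap", seed = as.integer(seed),
                run_index = run_index, source_fingerprint = inp$fp)
}

#' Write / read an embedding as TSV
#'
#' Columns `cell_id`, `x`, `y`; one file per (method, seed).
#'
#' @param emb An `embedding2d`.
#' @param path Output file.
#' @return `path` invisibly; `read_embedding()` returns an `embedding2d`.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "embedding2d"))
  readr::write_tsv(as_tibble(emb), path)
  invisible(path)
}

#' @rdname write_embedding
#' @param method,seed Metadata to attach on read (the TSV stores none).
#' @export
read_embedding <- function(path, method = "unknown", seed = NA_integer_) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_embedding(cbind(tab$x, tab$y), tab$cell_id, method, seed = seed)
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> method=%s seed=%s n=%d\n", attr(x, "method"),
              attr(x, "seed"), nrow(x)))
  NextMethod()
}

#' Scatter plot of a 2D embedding
#'
#' @param object An `embedding2d`.
#' @param labels Optional per-cell class labels used for colouring.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.embedding2d <- function(object, labels = NULL, ...) {
  df <- as_tibble(object)
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  } else {
    df$label <- labels
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$label))
  }
  p + ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = attr(object, "method")) +
    ggplot2::theme_minimal()
}
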