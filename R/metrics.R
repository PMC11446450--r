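# Label-based and neighborhood-based embedding quality metrics.
# All are first-principles implementations over exact brute-force neighbours;
# each returns a bare numeric scalar so calls compose freely, and
# evaluate_embedding() assembles them into tidy records.

resolve_graph <- function(x, k, space_tag = NA_character_) {
  if (inherits(x, "knn_graph")) {
    if (x$k < k) abort(sprintf("supplied knn_graph has k = %d < %d", x$k, k))
    return(x)
  }
  knn_graph(x, k, space_tag = space_tag)
}

#' Leave-one-out kNN classification accuracy
#'
#' Each point is assigned the majority label among its `k` nearest neighbours
#' (majority ties fall back to the label of the single nearest neighbour);
#' the metric is the fraction of points whose assigned label matches their
#' true label. Quantifies how often a point's neighbours in the given space
#' are from its own class.
#'
#' @param x Coordinate matrix, `embedding2d`, `expression_matrix`, or a
#'   precomputed [knn_graph()] with at least `k` neighbours.
#' @param labels Per-point class labels; every class must have >= 2 members.
#' @param k Number of neighbours (default 10).
#' @param mode `"vote"` (leave-one-out classification, the default) or
#'   `"fraction"` (mean fraction of same-label neighbours).
#' @return Numeric scalar in \[0, 1\].
#' @export
knn_accuracy <- function(x, labels, k = 10, mode = c("vote", "fraction")) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  g <- resolve_graph(x, k)
  n <- nrow(g$indices)
  if (length(labels) != n) abort("labels length does not match points")
  if (length(unique(labels)) < 2) {
    warn("single class: kNN accuracy is trivially 1")
    return(1)
  }
  tab <- table(labels)
  if (any(tab < 2)) abort("every class must have >= 2 members")
  nb <- matrix(labels[g$indices[, seq_len(k), drop = FALSE]], nrow = n)
  if (mode == "fraction") {
    return(mean(rowMeans(nb == labels)))
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    votes <- table(nb[i, ])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1) top else nb[i, 1]
  }
  mean(pred == labels)
}

#' kNN recall between a high-dimensional space and an embedding
#'
#' Mean over points of the fraction of a point's `k` nearest high-dimensional
#' neighbours that are also among its `k` nearest embedding neighbours.
#' Quantifies neighbourhood preservation without using labels; chance level
#' for an uninformative embedding is `k / (n - 1)`.
#'
#' @param hd High-dimensional coordinates (or precomputed [knn_graph()]).
#' @param emb Embedding coordinates (or precomputed [knn_graph()]).
#' @inheritParams knn_accuracy
#' @return Numeric scalar in \[0, 1\].
#' @export
knn_recall <- function(hd, emb, k = 10) {
  g_hd <- resolve_graph(hd, k, "HD")
  g_emb <- resolve_graph(emb, k, "2D")
  if (nrow(g_hd$indices) != nrow(g_emb$indices)) {
    abort(sprintf("row-count mismatch: hd has %d points, emb has %d",
                  nrow(g_hd$indices), nrow(g_emb$indices)))
  }
  a <- g_hd$indices[, seq_len(k), drop = FALSE]
  b <- g_emb$indices[, seq_len(k), drop = FALSE]
  n <- nrow(a)
  overlap <- vapply(seq_len(n),
                    function(i) length(intersect(a[i, ], b[i, ])),
                    integer(1))
  mean(overlap) / k
}

#' Mean silhouette coefficient of given classes
#'
#' For each point, `a(i)` is its mean distance to other members of its class
#' and `b(i)` the smallest mean distance to any other class;
#' `s(i) = (b - a) / max(a, b)`. Members of singleton classes score 0 by
#' convention. The metric is the mean of `s(i)`, measuring how compact and
#' mutually separated the classes are in the given space.
#'
#' @param x Coordinate matrix or coordinate-bearing object.
#' @param labels Per-point class labels; at least two classes required.
#' @return Numeric scalar in \[-1, 1\].
#' @export
silhouette_score <- function(x, labels) {
  labels <- as.character(labels)
  D <- pairwise_dist(x)
  n <- nrow(D)
  if (length(labels) != n) abort("labels length does not match points")
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("silhouette is undefined for a single class")
  sizes <- table(labels)[classes]
  # mean distance from every point to every class, via column-group sums
  member <- vapply(classes, function(cl) labels == cl, logical(n))
  sums <- D %*% member                      # n x C total distance to class
  s <- numeric(n)
  for (i in seq_len(n)) {
    cl <- labels[i]
    ci <- match(cl, classes)
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1)
    b <- min(sums[i, -ci] / sizes[-ci])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

class_centroids <- function(m, labels, classes) {
  t(vapply(classes, function(cl) colMeans(m[labels == cl, , drop = FALSE]),
           numeric(ncol(m))))
}

#' Inter-class correlation (centroid distance preservation)
#'
#' Pearson (or Spearman) correlation between the `C(C-1)/2` pairwise
#' Euclidean distances of class centroids computed in the high-dimensional
#' space and in the embedding. This is one of the two distance-preservation
#' metrics under which linear projections excel by construction.
#'
#' @param hd High-dimensional coordinates.
#' @param emb Embedding coordinates.
#' @param labels Per-point class labels; at least 3 classes required.
#' @param method Correlation flavour, `"pearson"` (default) or `"spearman"`.
#' @return Numeric scalar in \[-1, 1\], or `NA` if either distance vector has
#'   zero variance.
#' @export
interclass_corr <- function(hd, emb, labels, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  mh <- as_coords(hd)
  me <- as_coords(emb)
  if (nrow(mh) != nrow(me)) abort("hd and emb have different numbers of points")
  classes <- sort(unique(labels))
  if (length(classes) < 3) abort("need >= 3 classes for a centroid-distance correlation")
  dh <- as.vector(stats::dist(class_centroids(mh, labels, classes)))
  de <- as.vector(stats::dist(class_centroids(me, labels, classes)))
  if (sd(dh) == 0 || sd(de) == 0) {
    inform("zero variance in centroid distances; correlation undefined")
    return(NA_real_)
  }
  cor(dh, de, method = method)
}

#' Intra-class correlation (class variance preservation)
#'
#' Per class, the variance is the mean squared Euclidean distance of members
#' to their class centroid; the metric is the correlation of the per-class
#' variance vectors computed in the high-dimensional space and in the
#' embedding.
#'
#' @inheritParams interclass_corr
#' @return Numeric scalar in \[-1, 1\], or `NA` on zero variance.
#' @export
intraclass_corr <- function(hd, emb, labels, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  mh <- as_coords(hd)
  me <- as_coords(emb)
  if (nrow(mh) != nrow(me)) abort("hd and emb have different numbers of points")
  classes <- sort(unique(labels))
  if (length(classes) < 3) abort("need >= 3 classes")
  if (any(table(labels) < 2)) abort("every class must have >= 2 members")
  class_var <- function(m) {
    vapply(classes, function(cl) {
      sub <- m[labels == cl, , drop = FALSE]
      ctr <- colMeans(sub)
      mean(rowSums(sweep(sub, 2, ctr)^2))
    }, numeric(1))
  }
  vh <- class_var(mh)
  ve <- class_var(me)
  if (sd(vh) == 0 || sd(ve) == 0) {
    inform("zero variance across class variances; correlation undefined")
    return(NA_real_)
  }
  cor(vh, ve, method = method)
}

#' High-dimensional baselines for the label-based metrics
#'
#' kNN accuracy and silhouette evaluated directly in the high-dimensional
#' space; these are the dotted-baseline values against which 2D embeddings
#' are compared.
#'
#' @inheritParams knn_accuracy
#' @param hd High-dimensional coordinates (or a precomputed [knn_graph()]
#'   for the accuracy part, in which case `hd_points` must supply coordinates
#'   for the silhouette part).
#' @param hd_points Optional coordinates when `hd` is a graph.
#' @return A one-row tibble with `knn_accuracy_hd` and `silhouette_hd`.
#' @export
hd_baselines <- function(hd, labels, k = 10, hd_points = NULL) {
  pts <- if (inherits(hd, "knn_graph")) {
    if (is.null(hd_points)) abort("hd_points needed when hd is a knn_graph")
    hd_points
  } else hd
  tibble(
    knn_accuracy_hd = knn_accuracy(hd, labels, k = k),
    silhouette_hd = silhouette_score(pts, labels)
  )
}
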