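#' Density-based clustering with HDBSCAN*
#'
#' In-package implementation of the HDBSCAN* algorithm: core distances at
#' `min_samples` neighbours, mutual reachability distances, an exact minimum
#' spanning tree (Prim, compiled), the single-linkage hierarchy, condensation
#' at `min_cluster_size`, and excess-of-mass cluster selection on the
#' condensed tree. Points not captured by any selected cluster are noise.
#'
#' @param points Numeric matrix or coordinate-bearing object.
#' @param min_cluster_size Smallest cluster size kept during condensation
#'   (>= 2).
#' @param min_samples Neighbour count defining the core distance.
#' @return Integer vector of cluster labels, `1..K`; noise points are `0`.
#' @examples
#' pts <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 8), ncol = 2))
#' table(hdbscan(pts, min_cluster_size = 5, min_samples = 5))
#' @export
hdbscan <- function(points, min_cluster_size = 5, min_samples = 5) {
  m <- as_coords(points)
  check_finite(m, "points")
  D <- cpp_pairwise_dist(m)
  hdbscan_from_dist(D, min_cluster_size, min_samples)
}

hdbscan_from_dist <- function(D, min_cluster_size, min_samples,
                              sl_tree = NULL) {
  min_cluster_size <- as.integer(min_cluster_size)
  min_samples <- as.integer(min_samples)
  if (min_cluster_size < 2) abort("min_cluster_size must be >= 2")
  n <- nrow(D)
  if (n <= min_samples) abort("need n > min_samples")
  if (is.null(sl_tree)) {
    core <- cpp_knn_from_dist(D, min_samples)$dists[, min_samples]
    mst <- cpp_mst_mutual_reachability(D, core)
    sl_tree <- single_linkage(mst, n)
  }
  condensed <- condense_tree(sl_tree, n, min_cluster_size)
  extract_eom(condensed, n)
}

# Single-linkage hierarchy from MST edges: leaves are 1..n, internal nodes
# n+1..2n-1 in order of ascending merge distance.
single_linkage <- function(mst, n) {
  ord <- order(mst[, 3], mst[, 1], mst[, 2])
  mst <- mst[ord, , drop = FALSE]
  parent <- seq_len(2L * n - 1L)        # union-find over tree node ids
  comp <- seq_len(n)                    # component -> current tree node id
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  left <- integer(n - 1L)
  right <- integer(n - 1L)
  height <- numeric(n - 1L)
  size <- integer(2L * n - 1L)
  size[seq_len(n)] <- 1L
  for (e in seq_len(n - 1L)) {
    ra <- find(mst[e, 1])
    rb <- find(mst[e, 2])
    node <- n + e
    left[e] <- comp[ra]
    right[e] <- comp[rb]
    height[e] <- mst[e, 3]
    size[node] <- size[comp[ra]] + size[comp[rb]]
    parent[ra] <- rb
    comp[rb] <- node
  }
  list(left = left, right = right, height = height, size = size, n = n)
}

tree_leaves <- function(tree, node) {
  n <- tree$n
  out <- integer(tree$size[node])
  stack <- node
  m <- 0L
  while (length(stack)) {
    t <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (t <= n) {
      m <- m + 1L
      out[m] <- t
    } else {
      e <- t - n
      stack <- c(stack, tree$left[e], tree$right[e])
    }
  }
  out
}

# Condense the single-linkage tree: clusters persist until a split yields two
# children of size >= mcs; smaller offshoots fall out as candidate noise at
# the split's density level lambda = 1 / distance.
condense_tree <- function(tree, n, mcs) {
  lam_of <- function(d) 1 / max(d, 1e-12)
  parent_cl <- 0L
  birth <- 0
  stability <- 0
  pt_cluster <- integer(n)
  pt_lambda <- numeric(n)
  root <- 2L * n - 1L
  stack <- list(list(node = root, cl = 1L))
  n_cl <- 1L
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    t <- top$node
    cl <- top$cl
    e <- t - n
    lam <- lam_of(tree$height[e])
    kids <- c(tree$left[e], tree$right[e])
    big <- tree$size[kids] >= mcs
    if (all(big)) {
      for (kid in kids) {
        n_cl <- n_cl + 1L
        parent_cl[n_cl] <- cl
        birth[n_cl] <- lam
        stability[n_cl] <- 0
        stability[cl] <- stability[cl] + tree$size[kid] * (lam - birth[cl])
        stack[[length(stack) + 1L]] <- list(node = kid, cl = n_cl)
      }
    } else if (any(big)) {
      fall <- tree_leaves(tree, kids[!big])
      pt_cluster[fall] <- cl
      pt_lambda[fall] <- lam
      stability[cl] <- stability[cl] + length(fall) * (lam - birth[cl])
      stack[[length(stack) + 1L]] <- list(node = kids[big], cl = cl)
    } else {
      for (kid in kids) {
        fall <- tree_leaves(tree, kid)
        pt_cluster[fall] <- cl
        pt_lambda[fall] <- lam
        stability[cl] <- stability[cl] + length(fall) * (lam - birth[cl])
      }
    }
  }
  list(parent_cl = parent_cl, birth = birth, stability = stability,
       pt_cluster = pt_cluster, pt_lambda = pt_lambda, n_clusters = n_cl)
}

# Excess-of-mass cluster selection; the root is never selected (no
# single-cluster solution), matching the reference algorithm's default.
extract_eom <- function(condensed, n) {
  k <- condensed$n_clusters
  if (k == 1L) return(integer(n))  # only the root: everything is noise
  stab <- condensed$stability
  parent <- condensed$parent_cl
  selected <- rep(FALSE, k)
  children <- split(seq_len(k)[-1], parent[-1])
  descendants <- function(c0) {
    out <- integer(0)
    queue <- c0
    while (length(queue)) {
      c1 <- queue[1]
      queue <- queue[-1]
      kids <- children[[as.character(c1)]]
      out <- c(out, kids)
      queue <- c(queue, kids)
    }
    out
  }
  for (c0 in k:2) {
    kids <- children[[as.character(c0)]]
    if (is.null(kids)) {
      selected[c0] <- TRUE
    } else if (stab[c0] >= sum(stab[kids])) {
      selected[c0] <- TRUE
      selected[descendants(c0)] <- FALSE
    } else {
      stab[c0] <- sum(stab[kids])
    }
  }
  sel_ids <- which(selected)
  labels <- integer(n)
  up <- function(c1) {
    while (c1 != 0L) {
      if (selected[c1]) return(c1)
      c1 <- parent[c1]
    }
    0L
  }
  owner <- vapply(seq_len(k), up, 0L)  # resolved once per condensed cluster
  hit <- owner[condensed$pt_cluster]
  labels[hit > 0L] <- match(hit[hit > 0L], sel_ids)
  labels
}

#' Default HDBSCAN hyperparameter grid
#'
#' The sweep covers `min_cluster_size` in \{5, 10, 25, 50, 100, 250\} crossed
#' with `min_samples` in \{5, 10\}.
#'
#' @return A tibble with columns `min_cluster_size` and `min_samples`.
#' @export
hdbscan_grid <- function() {
  tidyr::expand_grid(min_cluster_size = c(5L, 10L, 25L, 50L, 100L, 250L),
                     min_samples = c(5L, 10L))
}

#' Maximum AMI between classes and HDBSCAN clusters over a grid
#'
#' Clusters the 2D coordinates with HDBSCAN at every grid entry, maps
#' noise-flagged points to one dedicated extra cluster (so an embedding that
#' defeats density clustering is penalised; `noise = "exclude"` drops them
#' instead), scores each clustering by [ami()] against the true classes, and
#' returns the maximum. The per-entry values are attached as attribute
#' `"sweep"` and the winning entry as `"best"`.
#'
#' @param emb `embedding2d` or n x 2 coordinate matrix.
#' @param labels Per-point class labels.
#' @param grid Tibble with `min_cluster_size`, `min_samples` columns
#'   (default [hdbscan_grid()]).
#' @param noise `"extra_cluster"` (default) or `"exclude"`.
#' @return Numeric scalar in \[0, 1\] with attributes `sweep` and `best`.
#' @export
ami_max_hdbscan <- function(emb, labels, grid = hdbscan_grid(),
                            noise = c("extra_cluster", "exclude")) {
  noise <- match.arg(noise)
  if (nrow(grid) == 0) abort("hyperparameter grid is empty")
  labels <- as.character(labels)
  m <- as_coords(emb)
  if (nrow(m) != length(labels)) abort("labels length does not match points")
  D <- cpp_pairwise_dist(m)
  vals <- numeric(nrow(grid))
  n_clusters <- integer(nrow(grid))
  # the single-linkage tree depends only on min_samples; share it across
  # min_cluster_size values
  for (ms in unique(grid$min_samples)) {
    core <- cpp_knn_from_dist(D, ms)$dists[, ms]
    mst <- cpp_mst_mutual_reachability(D, core)
    sl <- single_linkage(mst, nrow(D))
    rows <- which(grid$min_samples == ms)
    for (r in rows) {
      cl <- hdbscan_from_dist(D, grid$min_cluster_size[r], ms, sl_tree = sl)
      n_clusters[r] <- length(setdiff(unique(cl), 0L))
      if (all(cl == 0L)) {
        inform(sprintf(
          "all points flagged noise at min_cluster_size=%d min_samples=%d; AMI = 0",
          grid$min_cluster_size[r], ms))
        vals[r] <- 0
        next
      }
      if (noise == "extra_cluster") {
        vals[r] <- ami(ifelse(cl == 0L, "noise", paste0("c", cl)), labels)
      } else {
        keep <- cl != 0L
        vals[r] <- if (sum(keep) < 2) 0 else ami(cl[keep], labels[keep])
      }
    }
  }
  sweep_tab <- dplyr::mutate(grid, n_clusters = n_clusters, ami = vals)
  out <- max(vals)
  attr(out, "sweep") <- sweep_tab
  attr(out, "best") <- sweep_tab[which.max(vals), ]
  out
}
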