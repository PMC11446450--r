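# Independent brute-force oracles. Everything here is written against the
# metric definitions directly (double loops, stats::dist, stats::dhyper),
# never against the package's compiled code paths.

brute_dist <- function(X) as.matrix(stats::dist(X))

# k nearest neighbours by explicit sort over (distance, index)
brute_knn <- function(X, k) {
  D <- brute_dist(X)
  n <- nrow(D)
  t(vapply(seq_len(n), function(i) {
    ord <- order(D[i, -i], seq_len(n)[-i])
    (seq_len(n)[-i])[ord][seq_len(k)]
  }, integer(k)))
}

brute_knn_accuracy <- function(X, labels, k) {
  nb <- brute_knn(X, k)
  n <- nrow(nb)
  correct <- 0
  for (i in seq_len(n)) {
    votes <- table(labels[nb[i, ]])
    top <- names(votes)[votes == max(votes)]
    pred <- if (length(top) == 1) top else labels[nb[i, 1]]
    if (pred == labels[i]) correct <- correct + 1
  }
  correct / n
}

brute_knn_recall <- function(hd, emb, k) {
  a <- brute_knn(hd, k)
  b <- brute_knn(emb, k)
  mean(vapply(seq_len(nrow(a)),
              function(i) length(intersect(a[i, ], b[i, ])) / k,
              numeric(1)))
}

brute_silhouette <- function(X, labels) {
  D <- brute_dist(X)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i] & seq_len(n) != i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

brute_centroid_dists <- function(X, labels) {
  classes <- sort(unique(labels))
  cents <- t(sapply(classes, function(cl)
    colMeans(X[labels == cl, , drop = FALSE])))
  out <- c()
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      if (j > i) out <- c(out, sqrt(sum((cents[i, ] - cents[j, ])^2)))
    }
  }
  out
}

brute_interclass <- function(hd, emb, labels) {
  stats::cor(brute_centroid_dists(hd, labels),
             brute_centroid_dists(emb, labels))
}

brute_class_vars <- function(X, labels) {
  vapply(sort(unique(labels)), function(cl) {
    sub <- X[labels == cl, , drop = FALSE]
    ctr <- colMeans(sub)
    mean(apply(sub, 1, function(r) sum((r - ctr)^2)))
  }, numeric(1))
}

brute_intraclass <- function(hd, emb, labels) {
  stats::cor(brute_class_vars(hd, labels), brute_class_vars(emb, labels))
}

# AMI with E[MI] from the hypergeometric density in stats (independent of the
# package's log-factorial formulation).
brute_ami <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  ra <- rowSums(tab); cb <- colSums(tab)
  mi <- 0
  for (i in seq_along(ra)) for (j in seq_along(cb)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (ra[i] * cb[j]))
  }
  emi <- 0
  for (i in seq_along(ra)) for (j in seq_along(cb)) {
    nij <- max(1, ra[i] + cb[j] - n):min(ra[i], cb[j])
    nij <- nij[nij >= 1]
    if (length(nij) == 0) next
    p <- stats::dhyper(nij, ra[i], n - ra[i], cb[j])
    emi <- emi + sum(p * (nij / n) * log(n * nij / (ra[i] * cb[j])))
  }
  ent <- function(cnt) { p <- cnt[cnt > 0] / n; -sum(p * log(p)) }
  denom <- (ent(ra) + ent(cb)) / 2 - emi
  if (abs(denom) < 1e-12) return(0)
  unname((mi - emi) / denom)
}

# Random labelled instance with C >= 3 classes, each with >= 2 members.
rand_instance <- function(n, d_hd = 5, n_classes = 3) {
  labels <- c(rep(seq_len(n_classes), 2),
              sample(seq_len(n_classes), n - 2 * n_classes, replace = TRUE))
  list(hd = matrix(rnorm(n * d_hd), n),
       emb = matrix(rnorm(n * 2), n),
       labels = paste0("c", labels))
}

gaussian_blobs <- function(centers, n_per, sd = 1, d = 2) {
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(rnorm(n_per * d, sd = sd), n_per), 2,
          centers[i, ], "+")
  }))
  list(points = pts, labels = rep(seq_len(nrow(centers)), each = n_per))
}
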