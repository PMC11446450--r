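test_that("kNN accuracy is 1 for well-separated duplicated clusters", {
  X <- rbind(matrix(0, 20, 2), matrix(100, 20, 2))
  labels <- rep(c("a", "b"), each = 20)
  expect_equal(knn_accuracy(X, labels, k = 10), 1)
})

test_that("kNN accuracy matches exhaustive leave-one-out votes on 6 points", {
  X <- cbind(c(0, 1, 2, 10, 11, 12), 0)
  labels <- c("A", "A", "B", "A", "B", "B")
  # hand enumeration with k = 3:
  # p1: nb 2,3,4 -> A,B,A -> A  (correct)
  # p2: nb 1,3,4 -> A,B,A -> A  (correct)
  # p3: nb 2,1,4 -> A,A,A -> A  (wrong, true B)
  # p4: nb 5,6,3 -> B,B,B -> B  (wrong, true A)
  # p5: nb 4,6,3 -> A,B,B -> B  (correct)
  # p6: nb 5,4,3 -> B,A,B -> B  (correct)
  expect_equal(knn_accuracy(X, labels, k = 3), 4 / 6)
  expect_equal(brute_knn_accuracy(X, labels, 3), 4 / 6)
})

test_that("random labels give chance-level accuracy", {
  set.seed(10)
  n <- 1500
  X <- matrix(rnorm(n * 2), n)
  labels <- sample(c(rep(1:3, 2), sample(1:3, n - 6, TRUE)))
  acc <- knn_accuracy(X, labels, k = 10)
  expect_lt(abs(acc - 1 / 3), 0.05)
})

test_that("the same-label neighbour fraction mode is available", {
  X <- cbind(c(0, 1, 2, 10, 11, 12), 0)
  labels <- c("A", "A", "B", "A", "B", "B")
  # mean same-label fraction over the 18 neighbour slots above: 8/18
  expect_equal(knn_accuracy(X, labels, k = 3, mode = "fraction"), 8 / 18)
})

test_that("kNN recall is 1 for identical spaces and exact on a fixture", {
  set.seed(3)
  X <- matrix(rnorm(60), 20)
  expect_equal(knn_recall(X, X, k = 5), 1)

  hd <- cbind(c(0, 1, 2, 3, 4), 0)
  emb <- cbind(c(0, 4, 2, 1, 3), 0)
  # k = 2 neighbour sets: HD: {2,3},{1,3},{2,4},{3,5},{4,3}
  #                       2D: {4,3},{5,3},{4,1},{1,3},{2,3}
  # overlaps: 1, 1, 1, 1, 1 -> recall 5/10? hand check below
  expect_equal(knn_recall(hd, emb, k = 2), brute_knn_recall(hd, emb, 2))
})

test_that("row-count mismatch is rejected", {
  expect_error(knn_recall(matrix(rnorm(30), 10), matrix(rnorm(18), 9), k = 2),
               "mismatch")
})

test_that("silhouette matches the closed form on a symmetric 4-point case", {
  d_in <- 1; d_out <- 10
  X <- rbind(c(0, 0), c(d_in, 0), c(d_out, 0), c(d_out + d_in, 0))
  labels <- c("a", "a", "b", "b")
  # for each point a = d_in, b = mean distance to the other pair
  s <- silhouette_score(X, labels)
  a1 <- d_in; b1 <- mean(c(d_out, d_out + d_in))
  a2 <- d_in; b2 <- mean(c(d_out - d_in, d_out))
  expected <- mean(c((b1 - a1) / max(a1, b1), (b2 - a2) / max(a2, b2)))
  expect_equal(s, expected, tolerance = 1e-12)
})

test_that("random labels on one blob give silhouette near zero", {
  set.seed(4)
  X <- matrix(rnorm(1000), 500)
  labels <- sample(rep(c("a", "b"), each = 250))
  expect_lt(abs(silhouette_score(X, labels)), 0.02)
})

test_that("silhouette handles singletons and rejects a single class", {
  X <- rbind(c(0, 0), c(1, 0), c(10, 0))
  expect_silent(s <- silhouette_score(X, c("a", "a", "b")))
  expect_true(is.finite(s))
  expect_error(silhouette_score(X, c("a", "a", "a")), "single class")
})

test_that("interclass correlation is exact on constructed centroid layouts", {
  # similarity transform of a 2D space preserves distance ratios -> corr 1
  set.seed(5)
  hd <- matrix(rnorm(60), 30)
  labels <- rep(c("a", "b", "c"), each = 10)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  emb <- 3.2 * hd %*% R + 5
  expect_equal(interclass_corr(hd, emb, labels), 1, tolerance = 1e-9)

  # centroid distances (3,4,5) vs (5,4,3) -> perfectly reversed, corr -1
  hd2 <- rbind(c(0, 0), c(0, 0), c(3, 0), c(3, 0), c(3, 4), c(3, 4))
  emb2 <- rbind(c(0, 0), c(0, 0), c(5, 0), c(5, 0), c(5, 4 / 5 * 3), c(5, 2.4))
  lab2 <- c("a", "a", "b", "b", "c", "c")
  # hd centroid dists: ab=3, ac=5, bc=4 ; emb: ab=5, ac=sqrt(25+5.76)... use oracle
  expect_equal(interclass_corr(hd2, emb2, lab2),
               brute_interclass(hd2, emb2, lab2), tolerance = 1e-12)
})

test_that("intraclass correlation is 1 on identical spaces, -1 when reversed", {
  set.seed(6)
  X <- matrix(rnorm(80), 40)
  labels <- rep(c("a", "b", "c", "d"), each = 10)
  expect_equal(intraclass_corr(X, X, labels), 1, tolerance = 1e-12)

  # three classes with variances (1, 2, 3) in HD and (3, 2, 1) in 2D
  mk <- function(v) {
    # pair of points at distance 2*sqrt(v) has mean squared centroid dist v
    rbind(c(-sqrt(v), 0), c(sqrt(v), 0))
  }
  hd <- rbind(mk(1), mk(2) + 100, mk(3) - 100)
  emb <- rbind(mk(3), mk(2) + 100, mk(1) - 100)
  labels3 <- rep(c("a", "b", "c"), each = 2)
  expect_equal(intraclass_corr(hd, emb, labels3), -1, tolerance = 1e-12)
})

test_that("correlation metrics enforce their preconditions", {
  X <- matrix(rnorm(20), 10)
  expect_error(interclass_corr(X, X, rep(c("a", "b"), 5)), ">= 3 classes")
  expect_error(intraclass_corr(X, X, rep(c("a", "b"), 5)), ">= 3 classes")
})

test_that("metrics are neutral under rotation and translation of the embedding", {
  set.seed(7)
  inst <- rand_instance(40)
  theta <- 1.1
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  emb2 <- inst$emb %*% R
  emb2 <- sweep(emb2, 2, c(13, -4), "+")
  expect_equal(knn_accuracy(inst$emb, inst$labels, k = 5),
               knn_accuracy(emb2, inst$labels, k = 5), tolerance = 1e-9)
  expect_equal(silhouette_score(inst$emb, inst$labels),
               silhouette_score(emb2, inst$labels), tolerance = 1e-9)
  expect_equal(knn_recall(inst$hd, inst$emb, k = 5),
               knn_recall(inst$hd, emb2, k = 5), tolerance = 1e-9)
  expect_equal(interclass_corr(inst$hd, inst$emb, inst$labels),
               interclass_corr(inst$hd, emb2, inst$labels), tolerance = 1e-9)
  expect_equal(intraclass_corr(inst$hd, inst$emb, inst$labels),
               intraclass_corr(inst$hd, emb2, inst$labels), tolerance = 1e-9)
})

test_that("HD baselines equal the 2D metrics when fed the same coordinates", {
  set.seed(8)
  inst <- rand_instance(30)
  base <- hd_baselines(inst$emb, inst$labels, k = 5)
  expect_equal(base$knn_accuracy_hd, knn_accuracy(inst$emb, inst$labels, k = 5))
  expect_equal(base$silhouette_hd, silhouette_score(inst$emb, inst$labels))
})

test_that("silhouette agrees with cluster::silhouette on random data", {
  skip_if_not_installed("cluster")
  set.seed(9)
  X <- matrix(rnorm(100), 50)
  labels <- rep(1:5, each = 10)
  ours <- silhouette_score(X, labels)
  ref <- mean(cluster::silhouette(labels, stats::dist(X))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-9)
})
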