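test_that("simulator is deterministic and respects its configuration", {
  cfg <- nb_sim_config(n_classes = 3, cells_per_class = 10, n_genes = 50,
                       seed = 99)
  a <- simulate_nb_counts(cfg)
  b <- simulate_nb_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$labels, b$labels)
  expect_equal(dim(a$counts), c(30, 50))
  expect_equal(sort(unique(a$labels)), c("class_01", "class_02", "class_03"))
  expect_true(all(a$counts >= 0))
  markers <- attr(a, "marker_genes")
  expect_length(markers, 3)
  expect_equal(anyDuplicated(unlist(markers)), 0) # disjoint marker sets
})

test_that("NB moments match mu and mu + mu^2/theta by direct sampling", {
  # mu = 5, theta = 2: variance = 5 + 25/2 = 17.5
  cfg <- nb_sim_config(n_classes = 1, cells_per_class = 1000, n_genes = 100,
                       baseline_log_mean = log(5), baseline_log_sd = 0,
                       marker_fraction = 0.01, marker_log2_fc = 0,
                       dispersion = 2, seed = 5)
  x <- as.numeric(simulate_nb_counts(cfg)$counts) # 1e5 draws
  n <- length(x)
  v <- var(x)
  m4 <- mean((x - mean(x))^4)
  se_mean <- sd(x) / sqrt(n)
  se_var <- sqrt((m4 - v^2) / n)
  expect_lt(abs(mean(x) - 5), 3 * se_mean)
  expect_lt(abs(v - 17.5), 3 * se_var)
})

test_that("large dispersion approaches the Poisson limit (var/mean -> 1)", {
  cfg <- nb_sim_config(n_classes = 1, cells_per_class = 500, n_genes = 100,
                       baseline_log_mean = log(5), baseline_log_sd = 0,
                       marker_fraction = 0.01, marker_log2_fc = 0,
                       dispersion = 1e6, seed = 6)
  x <- as.numeric(simulate_nb_counts(cfg)$counts)
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
})

test_that("marker fold change controls the between-class mean ratio", {
  cfg <- nb_sim_config(n_classes = 2, cells_per_class = 2000, n_genes = 100,
                       baseline_log_mean = log(4), baseline_log_sd = 0,
                       marker_fraction = 0.1, marker_log2_fc = 2,
                       dispersion = 10, seed = 7)
  cm <- simulate_nb_counts(cfg)
  markers <- attr(cm, "marker_genes")
  in1 <- cm$labels == "class_01"
  m1 <- colMeans(cm$counts[in1, markers[[1]], drop = FALSE])
  m2 <- colMeans(cm$counts[!in1, markers[[1]], drop = FALSE])
  # expected ratio 2^2 = 4, checked within Monte-Carlo error per gene
  expect_lt(abs(mean(m1 / m2) - 4), 0.25)
})

test_that("zero fold change leaves classes statistically indistinguishable", {
  cfg <- nb_sim_config(n_classes = 2, cells_per_class = 2000, n_genes = 100,
                       marker_fraction = 0.1, marker_log2_fc = 0,
                       dispersion = 10, seed = 8)
  cm <- simulate_nb_counts(cfg)
  in1 <- cm$labels == "class_01"
  pvals <- vapply(seq_len(ncol(cm$counts)), function(g) {
    stats::t.test(cm$counts[in1, g], cm$counts[!in1, g])$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(nb_sim_config(dispersion = 0), "dispersion")
  expect_error(nb_sim_config(marker_fraction = 0.001, n_genes = 100),
               "marker_fraction")
  expect_error(nb_sim_config(n_classes = 20, n_genes = 100,
                             marker_fraction = 0.2), "disjoint")
})
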