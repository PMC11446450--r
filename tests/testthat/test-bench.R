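small_bench_config <- function(out_dir = NULL, embedders = "pca",
                               seeds = 0L) {
  bench_config(
    sim = nb_sim_config(n_classes = 3, cells_per_class = 30, n_genes = 100,
                        seed = 2),
    embedders = embedders, seeds = seeds, k = 5,
    hdbscan_grid = tibble::tibble(min_cluster_size = c(5L, 10L),
                                  min_samples = c(5L, 5L)),
    shape = make_shape("circle", 50),
    shape_config = shape_embed_config(epochs = 10, batch_size = 30),
    pca_dim = 10, out_dir = out_dir
  )
}

test_that("aggregate_runs computes mean/min/max and ignores order", {
  expect_equal(aggregate_runs(0.5), tibble::tibble(mean = 0.5, min = 0.5,
                                                   max = 0.5))
  expect_equal(aggregate_runs(c(0.2, 0.4, 0.9)),
               tibble::tibble(mean = 0.5, min = 0.2, max = 0.9))
  expect_equal(aggregate_runs(c(0.9, 0.2, 0.4)),
               aggregate_runs(c(0.2, 0.4, 0.9)))
  expect_error(aggregate_runs(numeric(0)), "empty")
})

test_that("a pca-only single-seed run yields 6 records plus HD baselines", {
  rep <- suppressMessages(run_benchmark(small_bench_config()))
  expect_equal(nrow(rep$records), 6)
  expect_setequal(rep$records$metric,
                  c("interclass_corr", "intraclass_corr", "knn_accuracy",
                    "knn_recall", "silhouette", "ami_max"))
  expect_equal(sum(!is.na(rep$records$baseline_hd)), 2)
  expect_equal(nrow(rep$baselines), 1)
  agg <- rep$aggregates
  expect_true(all(agg$min <= agg$mean & agg$mean <= agg$max))
})

test_that("stochastic embedders run once per seed, deterministic ones once", {
  rep <- suppressMessages(run_benchmark(
    small_bench_config(embedders = c("pca", "umap"), seeds = 0:2)
  ))
  counts <- table(rep$records$method) / 6
  expect_equal(unname(counts[["pca"]]), 1)
  expect_equal(unname(counts[["umap"]]), 3)
  expect_equal(anyDuplicated(
    rep$records[, c("method", "metric", "seed")]
  ), 0)
})

test_that("rerunning an identical config reproduces all metric values", {
  cfg <- small_bench_config(embedders = c("pca", "umap"), seeds = 0L)
  a <- suppressMessages(run_benchmark(cfg))
  b <- suppressMessages(run_benchmark(cfg))
  expect_identical(a$records$value, b$records$value)
})

test_that("artifacts are written when an output directory is set", {
  dir <- withr::local_tempdir()
  rep <- suppressMessages(run_benchmark(small_bench_config(out_dir = dir)))
  expect_true(file.exists(file.path(dir, "report.tsv")))
  expect_true(file.exists(file.path(dir, "aggregates.tsv")))
  expect_true(file.exists(file.path(dir, "counts", "matrix.mtx")))
  expect_true(length(list.files(dir, pattern = "^embedding_")) >= 1)
  back <- readr::read_tsv(file.path(dir, "report.tsv"),
                          show_col_types = FALSE)
  expect_equal(back$value, rep$records$value, tolerance = 1e-9)

  out2 <- file.path(dir, "rendered")
  render_report(file.path(dir, "report.tsv"), out2)
  expect_true(file.exists(file.path(out2, "aggregates.tsv")))
})

test_that("tidy/glance/autoplot provide the tidyverse surface", {
  rep <- suppressMessages(run_benchmark(small_bench_config()))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("dataset", "method", "seed", "run", "metric", "value",
                     "baseline_hd"))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("invalid configurations are rejected up front", {
  expect_error(bench_config(embedders = c("pca", "phate")), "unknown")
  expect_error(bench_config(seeds = c(1, 1)), "distinct")
  expect_error(bench_config(seeds = integer(0)), "distinct|non-empty")
})

test_that("evaluate_embedding matches the benchmark's per-run records", {
  cm <- simulate_nb_counts(nb_sim_config(n_classes = 3, cells_per_class = 30,
                                         n_genes = 100, seed = 2))
  hd <- preprocess(cm)
  inp <- preprocess(cm, pca_dim = 10)
  emb <- embed_pca2(inp)
  rec <- suppressMessages(evaluate_embedding(
    emb, hd, cm$labels, k = 5,
    hdbscan_grid = tibble::tibble(min_cluster_size = c(5L, 10L),
                                  min_samples = c(5L, 5L))
  ))
  rep <- suppressMessages(run_benchmark(small_bench_config()))
  expect_equal(sort(rec$value), sort(rep$records$value), tolerance = 1e-9)
})
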