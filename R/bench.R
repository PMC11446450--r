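#' Benchmark configuration
#'
#' Bundles everything [run_benchmark()] needs: the simulation (or a dataset
#' supplied as a [count_matrix()]), which embedders to run, the seed list for
#' stochastic embedders, metric settings, and the target shape for the
#' adversarial embedder.
#'
#' @param sim An [nb_sim_config()] or a ready-made [count_matrix()] with
#'   labels.
#' @param embedders Subset of `c("pca", "tsne", "umap", "shape")`.
#' @param seeds Distinct integer seeds for stochastic embedders (default
#'   `0:4`, i.e. five runs); deterministic embedders run once.
#' @param k Neighbour count for kNN accuracy/recall.
#' @param hdbscan_grid Hyperparameter grid for the AMI sweep.
#' @param corr_method `"pearson"` or `"spearman"` for the correlation metrics.
#' @param shape A [make_shape()] spec for the shape embedder (default: the
#'   elephant contour with 200 points).
#' @param shape_config A [shape_embed_config()] (its seed is overridden per
#'   run).
#' @param pca_dim Dimensionality of the PCA representation fed to t-SNE,
#'   UMAP and the shape embedder (`NULL` = raw gene space). The
#'   high-dimensional reference space for metrics is always the un-reduced
#'   normalised log matrix.
#' @param dataset_name Free-text dataset tag recorded in the report.
#' @param out_dir Optional directory; when set, counts, embeddings and the
#'   report TSV are written there.
#' @return A list of class `bench_config`.
#' @export
bench_config <- function(sim = nb_sim_config(),
                         embedders = c("pca", "tsne", "umap", "shape"),
                         seeds = 0:4, k = 10,
                         hdbscan_grid = embedbench::hdbscan_grid(),
                         corr_method = "pearson",
                         shape = make_shape("elephant", 200),
                         shape_config = shape_embed_config(),
                         pca_dim = 50, dataset_name = "nb_simulation",
                         out_dir = NULL) {
  known <- c("pca", "tsne", "umap", "shape")
  if (!all(embedders %in% known)) {
    abort(paste0("unknown embedder(s): ",
                 paste(setdiff(embedders, known), collapse = ", ")))
  }
  seeds <- as.integer(seeds)
  if (length(seeds) == 0 || anyDuplicated(seeds)) {
    abort("seeds must be non-empty and distinct")
  }
  structure(
    list(sim = sim, embedders = embedders, seeds = seeds, k = as.integer(k),
         hdbscan_grid = hdbscan_grid, corr_method = corr_method,
         shape = shape, shape_config = shape_config, pca_dim = pca_dim,
         dataset_name = dataset_name, out_dir = out_dir),
    class = "bench_config"
  )
}

deterministic_embedders <- "pca"

#' Run the full embedding-quality benchmark
#'
#' Pipeline: simulate (or take) labelled counts, preprocess into the
#' high-dimensional gene space and the embedder input, run every configured
#' embedder across the seed list (deterministic embedders once), score every
#' embedding with the six metrics plus the high-dimensional baselines, and
#' aggregate per (method, metric) as mean/min/max across runs. Each stage
#' logs one line; a failing stage aborts with its name.
#'
#' @param config A [bench_config()].
#' @return An object of class `bench_report`: list with
#'   * `records`: tibble (dataset, method, seed, run, metric, value,
#'     baseline_hd),
#'   * `aggregates`: tibble (method, metric, mean, min, max),
#'   * `shape_adherence`: tibble of per-run mean nearest-shape distance as a
#'     fraction of the shape diameter (shape embedder only),
#'   * `config`, `provenance`.
#' @export
run_benchmark <- function(config = bench_config()) {
  stopifnot(inherits(config, "bench_config"))
  t0 <- as.numeric(proc.time()[["elapsed"]])
  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("benchmark stage '", stage, "' failed: ",
                   conditionMessage(e)))
    })
    stage_log(stage, t0)
    res
  }

  counts <- run_stage("simulate", {
    if (inherits(config$sim, "count_matrix")) config$sim
    else simulate_nb_counts(config$sim)
  })
  if (is.null(counts$labels)) abort("benchmark needs labelled counts")
  labels <- counts$labels

  hd <- run_stage("preprocess", preprocess(counts))
  emb_input <- if (is.null(config$pca_dim)) hd else
    run_stage("pca_reduce", preprocess(counts, pca_dim = config$pca_dim))

  hd_graph <- run_stage("hd_knn", knn_graph(hd, config$k, "HD"))
  base <- run_stage("hd_baselines", {
    tibble(
      knn_accuracy_hd = knn_accuracy(hd_graph, labels, k = config$k),
      silhouette_hd = silhouette_score(hd, labels)
    )
  })

  embeddings <- run_stage("embed", {
    out <- list()
    run <- 0L
    for (method in config$embedders) {
      seeds <- if (method %in% deterministic_embedders) config$seeds[1] else
        config$seeds
      for (s in seeds) {
        run <- run + 1L
        emb <- switch(method,
          pca = embed_pca2(emb_input),
          tsne = embed_tsne(emb_input, seed = s, run_index = run),
          umap = embed_umap(emb_input, seed = s, run_index = run),
          shape = {
            cfg <- config$shape_config
            cfg$seed <- as.integer(s)
            fit_shape_embedding(emb_input, config$shape, cfg)
          }
        )
        attr(emb, "run_index") <- run
        out[[paste(method, s, sep = "_")]] <- emb
      }
    }
    out
  })

  records <- run_stage("score", {
    purrr::map_dfr(embeddings, function(emb) {
      method <- attr(emb, "method")
      score_embedding(emb, hd = hd, hd_graph = hd_graph, labels = labels,
                      config = config, baselines = base,
                      dataset = config$dataset_name)
    })
  })

  aggregates <- records |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), min = min(.data$value),
      max = max(.data$value), .groups = "drop"
    )

  shape_adherence <- purrr::map_dfr(
    purrr::keep(embeddings, ~ attr(.x, "method") == "shape"),
    function(emb) tibble(
      seed = attr(emb, "seed"),
      mean_dist = attr(emb, "shape_distance"),
      diameter = config$shape$diameter,
      frac_of_diameter = attr(emb, "shape_distance") / config$shape$diameter,
      converged = attr(emb, "converged")
    )
  )

  report <- structure(
    list(records = records, aggregates = aggregates,
         shape_adherence = shape_adherence,
         baselines = base, config = config,
         provenance = list(
           config_hash = fingerprint(config),
           package_version = as.character(utils::packageVersion("embedbench")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
         )),
    class = "bench_report"
  )

  if (!is.null(config$out_dir)) {
    run_stage("write", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_counts(counts, file.path(config$out_dir, "counts"), format = "mtx")
      for (nm in names(embeddings)) {
        write_embedding(embeddings[[nm]],
                        file.path(config$out_dir, paste0("embedding_", nm, ".tsv")))
      }
      write_report(report, config$out_dir)
    })
  }
  report
}

# Six metrics + HD baseline columns for one embedding.
score_embedding <- function(emb, hd, hd_graph, labels, config, baselines,
                            dataset) {
  coords <- as_coords(emb)
  g2 <- knn_graph(coords, config$k, "2D")
  vals <- c(
    interclass_corr = interclass_corr(hd, coords, labels,
                                      method = config$corr_method),
    intraclass_corr = intraclass_corr(hd, coords, labels,
                                      method = config$corr_method),
    knn_accuracy = knn_accuracy(g2, labels, k = config$k),
    knn_recall = knn_recall(hd_graph, g2, k = config$k),
    silhouette = silhouette_score(coords, labels),
    ami_max = as.numeric(ami_max_hdbscan(coords, labels,
                                         grid = config$hdbscan_grid))
  )
  baseline_hd <- c(
    interclass_corr = NA_real_, intraclass_corr = NA_real_,
    knn_accuracy = baselines$knn_accuracy_hd, knn_recall = NA_real_,
    silhouette = baselines$silhouette_hd, ami_max = NA_real_
  )
  tibble(
    dataset = dataset,
    method = attr(emb, "method"),
    seed = attr(emb, "seed"),
    run = attr(emb, "run_index"),
    metric = names(vals),
    value = unname(vals),
    baseline_hd = unname(baseline_hd)
  )
}

#' Mean / min / max aggregation across runs
#'
#' @param values Non-empty numeric vector (one value per run).
#' @return One-row tibble with columns `mean`, `min`, `max`.
#' @examples
#' aggregate_runs(c(0.2, 0.4, 0.9))
#' @export
aggregate_runs <- function(values) {
  if (length(values) == 0) abort("cannot aggregate an empty value list")
  tibble(mean = mean(values), min = min(values), max = max(values))
}

#' Evaluate one embedding against its source data
#'
#' Convenience wrapper computing all six metrics (plus HD baselines) for a
#' single embedding, returned as tidy records.
#'
#' @param emb An `embedding2d`.
#' @param hd The high-dimensional reference (`expression_matrix` or matrix).
#' @param labels Per-cell class labels.
#' @param k Neighbour count.
#' @param hdbscan_grid Grid for the AMI sweep.
#' @param corr_method Correlation flavour.
#' @param dataset Dataset tag.
#' @return Tibble in the same layout as `bench_report$records`.
#' @export
evaluate_embedding <- function(emb, hd, labels, k = 10,
                               hdbscan_grid = embedbench::hdbscan_grid(),
                               corr_method = "pearson",
                               dataset = "dataset") {
  cfg <- list(k = as.integer(k), hdbscan_grid = hdbscan_grid,
              corr_method = corr_method)
  hd_graph <- knn_graph(hd, k, "HD")
  base <- tibble(
    knn_accuracy_hd = knn_accuracy(hd_graph, labels, k = k),
    silhouette_hd = silhouette_score(hd, labels)
  )
  score_embedding(emb, hd = hd, hd_graph = hd_graph, labels = labels,
                  config = cfg, baselines = base, dataset = dataset)
}
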