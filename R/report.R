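#' @export
print.bench_report <- function(x, ...) {
  cat(sprintf("<bench_report> %s: %d records, %d methods\n",
              x$config$dataset_name, nrow(x$records),
              length(unique(x$records$method))))
  print(tidyr::pivot_wider(x$aggregates[, c("method", "metric", "mean")],
                           names_from = "metric", values_from = "mean"))
  invisible(x)
}

#' Tidy a benchmark report
#'
#' `tidy()` returns the long-format per-run metric records; `glance()` a
#' one-row summary of the run.
#'
#' @param x A `bench_report`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.bench_report <- function(x, ...) x$records

#' @rdname tidy.bench_report
#' @export
glance.bench_report <- function(x, ...) {
  tibble(
    dataset = x$config$dataset_name,
    n_methods = length(unique(x$records$method)),
    n_runs = length(unique(x$records$run)),
    n_records = nrow(x$records),
    knn_accuracy_hd = x$baselines$knn_accuracy_hd,
    silhouette_hd = x$baselines$silhouette_hd,
    config_hash = x$provenance$config_hash
  )
}

#' Metric-panel plot of a benchmark report
#'
#' One panel per metric, one marker per method at the mean across runs with
#' min-max error bars; dotted horizontal lines show the high-dimensional
#' baselines for the metrics that have one (kNN accuracy and silhouette).
#'
#' @param object A `bench_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.bench_report <- function(object, ...) {
  agg <- object$aggregates
  base <- tibble(
    metric = c("knn_accuracy", "silhouette"),
    baseline = c(object$baselines$knn_accuracy_hd,
                 object$baselines$silhouette_hd)
  )
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$method, y = .data$mean,
                                    colour = .data$method)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                           width = 0.2) +
    ggplot2::geom_hline(data = base,
                        ggplot2::aes(yintercept = .data$baseline),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "method") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write the report TSV and figure
#'
#' Writes `report.tsv` (per-run records), `aggregates.tsv`, and
#' `report_figure.pdf` into `out_dir`.
#'
#' @param report A `bench_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "bench_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$records, file.path(out_dir, "report.tsv"))
  readr::write_tsv(report$aggregates, file.path(out_dir, "aggregates.tsv"))
  p <- autoplot(report)
  suppressMessages(ggplot2::ggsave(file.path(out_dir, "report_figure.pdf"),
                                   p, width = 9, height = 6))
  invisible(out_dir)
}

#' Render report artefacts from a report TSV
#'
#' Re-creates the aggregate table and figure from a previously written
#' `report.tsv` (columns dataset, method, seed, run, metric, value,
#' baseline_hd).
#'
#' @param report_tsv Path to a report TSV.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(report_tsv, out_dir) {
  records <- readr::read_tsv(report_tsv, show_col_types = FALSE,
                             progress = FALSE)
  if (nrow(records) == 0) abort("report TSV is empty")
  aggregates <- records |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), min = min(.data$value),
                     max = max(.data$value), .groups = "drop")
  base_acc <- records$baseline_hd[records$metric == "knn_accuracy"][1]
  base_sil <- records$baseline_hd[records$metric == "silhouette"][1]
  fake <- structure(
    list(records = records, aggregates = aggregates,
         baselines = tibble(knn_accuracy_hd = base_acc,
                            silhouette_hd = base_sil),
         config = list(dataset_name = records$dataset[1]),
         provenance = list(config_hash = NA_character_)),
    class = "bench_report"
  )
  write_report(fake, out_dir)
}
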