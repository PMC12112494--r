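#' Multi-seed training and evaluation protocol
#'
#' Runs the full protocol: the test split is fixed once (seed
#' `config$test_seed`); then for every seed in `config$seeds` the
#' remaining positives are re-partitioned into train/valid, the model is
#' trained on the seed's training graph and evaluated on the fixed test
#' set.  Metrics are reported as mean +/- sd over seeds, in percent, with
#' per-seed confusion counts; the per-pair inter-class attention weights
#' of the test pairs (last seed) are returned for export.
#'
#' @param graph a [hetero_graph()] containing the target relation.
#' @param config an [mda_config()].
#' @param verbose emit progress to stderr.
#' @return An object of class `metric_report`: `per_seed` (data.frame, one
#'   row per seed), `summary` (data.frame with `mean_pct`, `sd_pct` per
#'   metric), `beta` (test-pair weight matrix), `beta_pairs` (ids +
#'   labels), `config`.
#' @export
run_protocol <- function(graph, config = mda_config(), verbose = FALSE) {
  base <- make_splits(graph, config$ratios, seed = config$test_seed,
                      target = config$target)
  rows <- list()
  beta <- NULL; beta_pairs <- NULL
  for (s in config$seeds) {
    split <- make_splits(graph, config$ratios, seed = s,
                         target = config$target, fixed_test = base)
    fit <- train(graph, split, store = NULL, config = config, seed = s,
                 verbose = verbose)
    ev <- evaluate(fit, split_pairs(split, "test"))
    m <- ev$metrics
    rows[[as.character(s)]] <- data.frame(
      seed = s, auc = m$auc, ap = m$ap, precision = m$precision,
      recall = m$recall, f1 = m$f1, tp = m$tp, tn = m$tn, fp = m$fp,
      fn = m$fn, best_epoch = fit$best_epoch)
    beta <- ev$beta
    beta_pairs <- data.frame(miRNA_id = ev$scores$miRNA_id,
                             disease_id = ev$scores$disease_id,
                             label = ev$scores$label,
                             stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("seed %d: test AUC %.4f  AP %.4f", s, m$auc, m$ap))
  }
  per_seed <- do.call(rbind, rows)
  mets <- c("auc", "ap", "precision", "recall", "f1")
  summary <- data.frame(
    metric = mets,
    mean_pct = vapply(mets, function(k) 100 * mean(per_seed[[k]]), 0),
    sd_pct = vapply(mets, function(k)
      100 * (if (nrow(per_seed) > 1) sd(per_seed[[k]]) else 0), 0),
    row.names = NULL)
  structure(list(per_seed = per_seed, summary = summary, beta = beta,
                 beta_pairs = beta_pairs, config = config),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report over", nrow(x$per_seed), "seed(s):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-9s %6.2f +/- %.2f %%\n", x$summary$metric[i],
                x$summary$mean_pct[i], x$summary$sd_pct[i]))
  invisible(x)
}

#' Export per-pair inter-class attention weights as TSV
#'
#' Columns `pair_id  label  <one column per common metapath class>`, the
#' format used for attention-weight heatmaps.
#'
#' @param report a [run_protocol()] result (or any list with `beta` and
#'   `beta_pairs`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beta_weights <- function(report, path) {
  tab <- data.frame(
    pair_id = paste(report$beta_pairs$miRNA_id,
                    report$beta_pairs$disease_id, sep = "|"),
    label = report$beta_pairs$label,
    report$beta, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Serialize a metric report as JSON
#'
#' @param report a [run_protocol()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(list(per_seed = report$per_seed,
                            summary = report$summary),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
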