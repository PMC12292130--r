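# End-to-end orchestration: merge -> sequence model -> graph -> spectral
# features -> MNN -> GAT -> predictions (+ metrics), with ablation modes.

#' Run the full annotation pipeline
#'
#' Modes mirror the ablation design: `"full"` builds the KNN graph from
#' CNN sequence embeddings and uses spectral accessibility features as GAT
#' node inputs; `"genome-free"` skips the CNN and builds the graph from
#' the (corrected) accessibility features themselves; `"peak-free"` skips
#' the spectral branch and uses the sequence embeddings as node features.
#'
#' @param ref,query [atac_dataset] objects over the same peak set.
#' @param genome named character vector of contigs (not needed in
#'   genome-free mode).
#' @param outdir output directory for intermediate artifacts, or `NULL`
#'   to keep everything in memory.
#' @param mode one of `"full"`, `"genome-free"`, `"peak-free"`.
#' @param k KNN graph degree.
#' @param correction `"mnn"` or `"none"`.
#' @param n_features peaks retained by feature selection.
#' @param d_spec spectral embedding dimension.
#' @param seq_config a [seq_model_config()].
#' @param gat_cfg a [gat_config()].
#' @param use_domain_loss disable to drop the domain-adaptation loss.
#' @param seed master seed; per-stage seeds are derived from it,
#'   overriding the seeds inside `seq_config`/`gat_cfg`.
#' @param truth optional character vector of true query labels, enabling
#'   evaluation.
#' @param verbose log stage progress.
#' @return A list of class `pipeline_run`: `result`
#'   ([predict_gat()] output), `metrics` (a [macro_f1()] report or
#'   `NULL`), `seq_model`, `gat`, `graph`, `node_features`, `mode`,
#'   `manifest`.
#' @export
run_pipeline <- function(ref, query, genome = NULL, outdir = NULL,
                         mode = c("full", "genome-free", "peak-free"),
                         k = 15, correction = c("mnn", "none"),
                         n_features = 300000, d_spec = 32,
                         seq_config = seq_model_config(),
                         gat_cfg = gat_config(),
                         use_domain_loss = TRUE, seed = 1,
                         truth = NULL, verbose = TRUE) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  t0 <- Sys.time()
  if (!is.null(seed)) {
    seq_config$seed <- derive_seed(seed, "seq")
    gat_cfg$seed <- derive_seed(seed, "gat")
  }
  if (!use_domain_loss) gat_cfg$domain_loss_weight <- 0

  log_msg("merging reference (", ncol(ref$X), " cells) and query (",
          ncol(query$X), " cells)", verbose = verbose)
  merged <- merge_reference_query(ref, query)
  is_ref <- merged$cells$is_reference

  seq_model <- NULL
  emb <- NULL
  if (mode %in% c("full", "peak-free")) {
    abort_if(is.null(genome), "mode '", mode, "' needs a genome")
    log_msg("training sequence model (window ", seq_config$window_length,
            " bp)", verbose = verbose)
    seq_model <- train_sequence_model(merged, genome, seq_config,
                                      verbose = verbose)
    emb <- extract_cell_embeddings(seq_model)
  }

  feats <- NULL
  if (mode %in% c("full", "genome-free")) {
    log_msg("spectral embedding (", d_spec, " dims, up to ", n_features,
            " features)", verbose = verbose)
    selected <- select_features(merged, n_features)
    feats <- spectral_embed(selected, d_spec)
    if (correction == "mnn" && length(unique(merged$cells$batch)) > 1) {
      log_msg("MNN batch correction", verbose = verbose)
      feats <- mnn_correct(feats, merged$cells$batch, merged$cells$group)
    }
  }

  graph_basis <- switch(mode, full = emb, `peak-free` = emb,
                        `genome-free` = feats$features)
  node_feats <- switch(mode, full = feats, `genome-free` = feats,
                       `peak-free` = structure(
                         list(features = emb,
                              cell_ids = merged$cells$cell_id,
                              corrected = FALSE),
                         class = "node_features"))

  log_msg("building KNN graph (k = ", k, ")", verbose = verbose)
  graph <- knn_adjacency(graph_basis, k)

  log_msg("training GAT annotator", verbose = verbose)
  gat <- train_gat(node_feats, graph, merged$cells$label, is_ref,
                   gat_cfg, verbose = verbose)
  result <- predict_gat(gat, node_feats, graph, !is_ref,
                        cell_ids = merged$cells$cell_id)

  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- macro_f1(truth, result$predicted_label)
    log_msg(sprintf("query accuracy %.4f  macro-F1 %.4f",
                    metrics$accuracy, metrics$macro_f1), verbose = verbose)
  }

  manifest <- list(
    mode = mode, k = k, correction = correction, n_features = n_features,
    d_spec = d_spec, seed = seed, use_domain_loss = use_domain_loss,
    n_reference = sum(is_ref), n_query = sum(!is_ref),
    n_peaks = nrow(merged$X),
    seq_config = if (!is.null(seq_model)) unclass(seq_config),
    gat_config = unclass(gat_cfg),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_predictions(result, file.path(outdir, "predictions.tsv"))
    write.table(cbind(cell_id = merged$cells$cell_id,
                      as.data.frame(node_feats$features)),
                file.path(outdir, "node_features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(to_edge_index(graph), file.path(outdir, "edge_index.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(seq_model)) {
      saveRDS(seq_model, file.path(outdir, "sequence_model.rds"))
      write.table(as.data.frame(seq_model$history),
                  file.path(outdir, "seq_history.csv"), sep = ",",
                  quote = FALSE, row.names = FALSE)
    }
    saveRDS(gat, file.path(outdir, "gat_model.rds"))
    if (!is.null(metrics)) {
      jsonlite::write_json(list(accuracy = metrics$accuracy,
                                macro_f1 = metrics$macro_f1),
                           file.path(outdir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      write.table(as.data.frame(metrics$per_class),
                  file.path(outdir, "per_class.csv"), sep = ",",
                  quote = FALSE, row.names = FALSE)
    }
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }

  structure(list(result = result, metrics = metrics, seq_model = seq_model,
                 gat = gat, graph = graph, node_features = node_feats,
                 mode = mode, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> mode '%s', %d query cells annotated\n",
              x$mode, length(x$result$cell_id)))
  if (!is.null(x$metrics))
    cat(sprintf("  accuracy %.4f  macro-F1 %.4f\n",
                x$metrics$accuracy, x$metrics$macro_f1))
  invisible(x)
}

#' Evaluate a predictions file against a truth file
#'
#' @param predictions_tsv TSV with columns `cell_id`, `predicted_label`
#'   (as written by [write_predictions()]).
#' @param truth_tsv TSV with columns `cell_id` and `label`.
#' @return A [macro_f1()] `metric_report` (cells matched by `cell_id`).
#' @export
evaluate_predictions <- function(predictions_tsv, truth_tsv) {
  pred <- read.table(predictions_tsv, sep = "\t", header = TRUE,
                     colClasses = "character")
  truth <- read.table(truth_tsv, sep = "\t", header = TRUE,
                      colClasses = "character")
  abort_if(!all(pred$cell_id %in% truth$cell_id),
           "predictions contain cell ids absent from the truth file")
  y <- truth$label[match(pred$cell_id, truth$cell_id)]
  macro_f1(y, pred$predicted_label)
}
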