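# Shared fixtures. Small configurations keep unit tests fast; the heavier
# study-scale fixtures used by the acceptance tests are built (and cached
# for the session) in test-acceptance.R.

# a small but non-trivial synthetic dataset for plumbing tests
small_sim <- function(seed = 7, batch_shift = 0.1, n_batches = 2) {
  generate_dataset(synthetic_config(
    n_cell_types = 3, n_cells_ref = 60, n_cells_query = 30,
    n_peaks = 120, n_batches = n_batches, peak_width = 200,
    motif_length = 8, batch_shift = batch_shift, seed = seed))
}

# a sequence-model configuration small enough for unit tests
tiny_seq_config <- function(...) {
  cfg <- seq_model_config(window_length = 64, stem_kernel = 7,
                          stem_channels = 6, n_towers = 1, tower_kernel = 3,
                          pool_width = 4, post_conv_channels = 4,
                          bottleneck_d = 8, batch_size = 32, max_epochs = 3,
                          n_validation_peaks = 20, early_stop_patience = 3,
                          seed = 3)
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg
}

tiny_gat_config <- function(...) {
  cfg <- gat_config(hidden_dim_per_head = 8, learning_rate = 1e-2,
                    max_epochs = 60, early_stop_patience = 60, seed = 3)
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg
}

# brute-force KNN oracle: quadratic scan with explicit tie handling
oracle_knn_edges <- function(X, k) {
  n <- nrow(X)
  out <- NULL
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    out <- rbind(out, cbind(i = i, j = nb))
  }
  out[order(out[, 1], out[, 2]), ]
}

# brute-force confusion-count metrics oracle
oracle_metrics <- function(y_true, y_pred) {
  classes <- sort(unique(c(y_true, y_pred)))
  f1s <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == cl && y_true[i] == cl) tp <- tp + 1
      if (y_pred[i] == cl && y_true[i] != cl) fp <- fp + 1
      if (y_pred[i] != cl && y_true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[ci] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  acc <- sum(mapply(identical, y_true, y_pred)) / length(y_true)
  list(accuracy = acc, macro_f1 = mean(f1s))
}

edge_set_string <- function(edges) {
  e <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  paste(e[, 1], e[, 2], sep = ">", collapse = ";")
}
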