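# Accessibility-derived node features: feature selection, TF-IDF + SVD
# spectral embedding, and mutual-nearest-neighbour batch correction.

#' Select the most informative peaks
#'
#' Ranks peaks by total accessibility count across all cells (descending)
#' and keeps the top `min(n_features, n_peaks)`; ties at the cutoff keep
#' the earlier peak. The default of 300,000 is clamped to the actual peak
#' count on small datasets.
#'
#' @param merged an [atac_dataset].
#' @param n_features number of peaks to retain.
#' @return An [atac_dataset] restricted to the selected peaks (original
#'   relative order preserved).
#' @export
select_features <- function(merged, n_features = 300000) {
  stopifnot(inherits(merged, "atac_dataset"))
  abort_if(n_features < 1, "n_features must be >= 1")
  counts <- Matrix::rowSums(merged$X)
  n_keep <- min(n_features, length(counts))
  ranked <- order(-counts, seq_along(counts))   # tie-break: original order
  keep <- sort(ranked[seq_len(n_keep)])
  atac_dataset(merged$X[keep, , drop = FALSE],
               merged$peaks[keep, , drop = FALSE], merged$cells)
}

#' Spectral embedding of the peak-by-cell matrix
#'
#' TF-IDF weighting (`x * log(1 + N / (1 + n_accessible))` per peak),
#' L2 normalization of each cell, then the top `d_spec + 1` left singular
#' vectors of the cells-by-peaks matrix. The first component — which tracks
#' per-cell coverage (a size factor) — is dropped; components
#' `2..d_spec+1`, each scaled by its singular value, are returned.
#'
#' @param merged a binary [atac_dataset].
#' @param d_spec embedding dimension (default 32).
#' @return An object of class `node_features`: list with `features`
#'   (`N_cells x d_spec` matrix, cell ids as row names), `cell_ids` and
#'   `corrected = FALSE`.
#' @export
spectral_embed <- function(merged, d_spec = 32) {
  stopifnot(inherits(merged, "atac_dataset"))
  n_cells <- ncol(merged$X)
  n_peaks <- nrow(merged$X)
  abort_if(d_spec >= min(n_cells, n_peaks),
           "d_spec must be < min(n_cells, n_peaks)")
  zero <- which(Matrix::colSums(merged$X) == 0)
  abort_if(length(zero) > 0L,
           "cell(s) with no accessible peaks cannot be embedded: ",
           paste(head(merged$cells$cell_id[zero], 5), collapse = ", "),
           if (length(zero) > 5) sprintf(" (and %d more)", length(zero) - 5))
  idf <- log(1 + n_cells / (1 + Matrix::rowSums(merged$X)))
  Xw <- Matrix::Diagonal(x = idf) %*% merged$X      # peaks x cells
  norms <- sqrt(Matrix::colSums(Xw * Xw))
  Xw <- Xw %*% Matrix::Diagonal(x = 1 / norms)
  M <- t(as.matrix(Xw))                             # cells x peaks
  k <- d_spec + 1L
  sv <- svd(M, nu = k, nv = 0)
  feats <- sv$u[, 2:k, drop = FALSE] *
    rep(sv$d[2:k], each = n_cells)
  rownames(feats) <- merged$cells$cell_id
  structure(list(features = feats, cell_ids = merged$cells$cell_id,
                 corrected = FALSE),
            class = "node_features")
}

#' @export
print.node_features <- function(x, ...) {
  cat(sprintf("<node_features> %d cells x %d dims (%scorrected)\n",
              nrow(x$features), ncol(x$features),
              if (x$corrected) "MNN-" else "un"))
  invisible(x)
}

# k-nearest rows of B for each row of A (exact, Euclidean, ties by index).
knn_across <- function(A, B, k) {
  sqA <- rowSums(A * A)
  sqB <- rowSums(B * B)
  D <- outer(sqA, sqB, "+") - 2 * tcrossprod(A, B)
  res <- apply(D, 1, function(d) order(d, seq_along(d))[seq_len(k)])
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Mutual-nearest-neighbour batch correction
#'
#' Removes batch displacement from embedded features by the
#' Haghverdi-style correction-vector scheme: batches are merged
#' sequentially in descending size order; within each grouping-factor
#' level independently, mutual `k_mnn`-nearest-neighbour pairs between the
#' incoming batch and the current corrected pool define pair difference
#' vectors (pool minus incoming), and every incoming cell is shifted by
#' the Gaussian-kernel-weighted average of those differences (kernel on
#' the distance from the cell to each pair's incoming member, bandwidth
#' `sigma`). Groups with no MNN pairs are left unshifted with a warning;
#' single-batch input is returned unchanged.
#'
#' @param features a [spectral_embed()] result (or any `node_features`).
#' @param batch per-cell batch (sample identity) factor.
#' @param group per-cell grouping factor (e.g. tissue type); correction
#'   vectors never mix cells across groups.
#' @param k_mnn neighbours per side for the mutual-NN search.
#' @param sigma Gaussian bandwidth; `NULL` uses the mean distance over the
#'   MNN pairs of the current merge step.
#' @return A `node_features` object with `corrected = TRUE`.
#' @export
mnn_correct <- function(features, batch, group = NULL, k_mnn = 20,
                        sigma = NULL) {
  stopifnot(inherits(features, "node_features"))
  F0 <- features$features
  abort_if(any(!is.finite(F0)), "features contain non-finite values")
  batch <- as.character(batch)
  abort_if(length(batch) != nrow(F0), "batch must have one entry per cell")
  group <- if (is.null(group)) rep("all", nrow(F0)) else as.character(group)
  sizes <- sort(table(batch), decreasing = TRUE)
  if (length(sizes) == 1L)
    return(structure(list(features = F0, cell_ids = features$cell_ids,
                          corrected = TRUE), class = "node_features"))
  abort_if(k_mnn >= min(sizes),
           "k_mnn (", k_mnn, ") must be smaller than the smallest batch (",
           min(sizes), ")")

  Fc <- F0
  merge_order <- names(sizes)
  pool <- which(batch == merge_order[1])
  for (b in merge_order[-1]) {
    incoming <- which(batch == b)
    shift <- matrix(0, length(incoming), ncol(Fc))
    got_pairs <- rep(FALSE, length(incoming))
    for (g in unique(group[incoming])) {
      inc_g <- incoming[group[incoming] == g]
      pool_g <- pool[group[pool] == g]
      if (length(pool_g) == 0L || length(inc_g) == 0L) next
      kk <- min(k_mnn, length(inc_g), length(pool_g))
      nn_ip <- knn_across(Fc[inc_g, , drop = FALSE],
                          Fc[pool_g, , drop = FALSE], kk)
      nn_pi <- knn_across(Fc[pool_g, , drop = FALSE],
                          Fc[inc_g, , drop = FALSE], kk)
      # mutual pairs: (incoming a, pool b) with b in knn(a) and a in knn(b)
      pairs <- NULL
      inset <- matrix(FALSE, length(pool_g), length(inc_g))
      inset[cbind(rep(seq_len(nrow(nn_pi)), ncol(nn_pi)), as.vector(nn_pi))] <-
        TRUE
      for (a in seq_along(inc_g)) {
        mutual <- nn_ip[a, inset[nn_ip[a, ], a]]
        if (length(mutual))
          pairs <- rbind(pairs, cbind(a = a, p = mutual))
      }
      if (is.null(pairs)) next
      diffs <- Fc[pool_g[pairs[, "p"]], , drop = FALSE] -
        Fc[inc_g[pairs[, "a"]], , drop = FALSE]
      anchors <- Fc[inc_g[pairs[, "a"]], , drop = FALSE]
      pair_d <- sqrt(rowSums((diffs)^2))
      sg <- sigma %||% max(mean(pair_d), 1e-8)
      # distance from every incoming cell of this group to each anchor
      sqI <- rowSums(Fc[inc_g, , drop = FALSE]^2)
      sqA <- rowSums(anchors^2)
      D2 <- outer(sqI, sqA, "+") -
        2 * tcrossprod(Fc[inc_g, , drop = FALSE], anchors)
      W <- exp(-pmax(D2, 0) / (2 * sg^2))
      W <- W / pmax(rowSums(W), 1e-12)
      shift_g <- W %*% diffs
      sel <- match(inc_g, incoming)
      shift[sel, ] <- shift_g
      got_pairs[sel] <- TRUE
    }
    if (!all(got_pairs))
      warning(sum(!got_pairs), " cell(s) in batch '", b,
              "' had no MNN pairs in their group and were left unshifted")
    Fc[incoming, ] <- Fc[incoming, , drop = FALSE] + shift
    pool <- c(pool, incoming)
  }
  structure(list(features = Fc, cell_ids = features$cell_ids,
                 corrected = TRUE), class = "node_features")
}
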