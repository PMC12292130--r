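# Exact KNN cell-cell graph over embeddings, and its edge-index form.

#' Build the directed KNN adjacency over cells
#'
#' Connects every cell `i` to its `k` nearest other cells by Euclidean
#' distance in the embedding space: edge `(i, j)` records that `j` is among
#' the `k` nearest neighbours of `i` (information flows `j -> i`). The
#' search is exact; distance ties are broken toward the lower cell index
#' and self-matches are excluded.
#'
#' @param X numeric `n x d` embedding matrix (finite entries).
#' @param k number of neighbours, `1 <= k < n`.
#' @return An object of class `cell_graph`: list with `n_cells`, `k` and
#'   `edges`, an `(n*k) x 2` integer matrix with columns `i` (target) and
#'   `j` (neighbour/source).
#' @export
knn_adjacency <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  abort_if(anyNA(X) || any(!is.finite(X)), "embedding contains NaN/Inf")
  abort_if(k < 1 || k >= n, "need 1 <= k < n (k=", k, ", n=", n, ")")
  # squared Euclidean distances via the Gram-matrix expansion
  sq <- rowSums(X * X)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  diag(D) <- Inf                            # exclude self
  edges <- matrix(0L, n * k, 2L, dimnames = list(NULL, c("i", "j")))
  for (i in seq_len(n)) {
    nb <- order(D[i, ], seq_len(n))[seq_len(k)]   # tie-break: lower index
    edges[((i - 1L) * k + 1L):(i * k), ] <- cbind(i, nb)
  }
  structure(list(n_cells = n, k = as.integer(k), edges = edges),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d cells, k = %d, %d directed edges\n",
              x$n_cells, x$k, nrow(x$edges)))
  invisible(x)
}

#' Convert a cell graph to a (source, target) edge index
#'
#' One row per nonzero adjacency entry with `source = j` (the neighbour)
#' and `target = i`; with `add_self_loops`, `(i, i)` is appended exactly
#' once per node so every node attends to itself in the GAT.
#'
#' @param graph a [knn_adjacency()] result.
#' @param add_self_loops append one self-loop per node (default `TRUE`).
#' @return Integer matrix with columns `source`, `target`.
#' @export
to_edge_index <- function(graph, add_self_loops = TRUE) {
  stopifnot(inherits(graph, "cell_graph"))
  ei <- cbind(source = graph$edges[, "j"], target = graph$edges[, "i"])
  if (add_self_loops) {
    s <- seq_len(graph$n_cells)
    ei <- rbind(ei, cbind(source = s, target = s))
  }
  ei
}

#' Reconstruct a cell graph from an edge index
#'
#' Inverse of [to_edge_index()]: self-loops are discarded and the KNN edge
#' set restored.
#'
#' @param edge_index integer matrix with columns `source`, `target`.
#' @param n_cells number of cells.
#' @return A `cell_graph`.
#' @export
edge_index_to_graph <- function(edge_index, n_cells) {
  keep <- edge_index[, "source"] != edge_index[, "target"]
  e <- edge_index[keep, , drop = FALSE]
  edges <- cbind(i = e[, "target"], j = e[, "source"])
  edges <- edges[order(edges[, "i"], edges[, "j"]), , drop = FALSE]
  k <- nrow(edges) %/% n_cells
  structure(list(n_cells = as.integer(n_cells), k = as.integer(k),
                 edges = edges), class = "cell_graph")
}
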