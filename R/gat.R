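# Two-layer graph attention network for transductive label transfer.
#
# Layer parameters follow the standard GAT parameterization: per head, a
# linear map W (in -> F) and an attention vector a of length 2F split into
# a target half (applied to W h_i) and a source half (applied to W h_j);
# e_ij = LeakyReLU(a_i . Wh_i + a_j . Wh_j), normalized by softmax over
# each node's in-neighbourhood.

#' GAT configuration
#'
#' @param hidden_dim_per_head width per attention head in layer 1; layer 1
#'   output is `4 x hidden_dim_per_head` concatenated.
#' @param heads_layer1,heads_layer2 attention heads (4 and 1).
#' @param leaky_relu_slope negative slope of the attention LeakyReLU.
#' @param learning_rate Adam learning rate.
#' @param max_epochs full-batch training epoch cap.
#' @param domain_loss_weight weight `lambda` of the domain-adaptation
#'   binary cross-entropy (0 disables it).
#' @param early_stop_patience epochs without held-out improvement before
#'   stopping.
#' @param seed integer seed.
#' @return A list of class `gat_config`.
#' @export
gat_config <- function(hidden_dim_per_head = 64, heads_layer1 = 4,
                       heads_layer2 = 1, leaky_relu_slope = 0.2,
                       learning_rate = 1e-4, max_epochs = 500,
                       domain_loss_weight = 0.1, early_stop_patience = 30,
                       seed = 1) {
  cfg <- as.list(environment())
  abort_if(heads_layer1 < 1 || heads_layer2 < 1, "heads must be >= 1")
  abort_if(domain_loss_weight < 0, "domain_loss_weight must be >= 0")
  structure(cfg, class = "gat_config")
}

# Precomputed grouping of the edge list by target node. The KNN + self-loop
# graphs the pipeline builds have a uniform in-degree, enabling a reshape
# fast path for the per-neighbourhood softmax.
edge_layout <- function(edge_index, n) {
  src <- as.integer(edge_index[, "source"])
  tgt <- as.integer(edge_index[, "target"])
  sizes <- tabulate(tgt, n)
  abort_if(any(sizes == 0L),
           "node(s) with no in-edges: softmax over an empty neighbourhood ",
           "is undefined (enable self-loops)")
  ord <- order(tgt, src)
  uniform <- length(unique(sizes)) == 1L
  list(src = src, tgt = tgt, ord = ord, sizes = sizes,
       uniform = uniform, s = sizes[1], n = n)
}

# groupwise max/sum helpers on the sorted edge order
group_reduce <- function(x_sorted, lay, what = c("max", "sum")) {
  what <- match.arg(what)
  if (lay$uniform) {
    M <- matrix(x_sorted, lay$s, lay$n)
    if (what == "sum") return(colSums(M))
    r <- M[1, ]
    if (lay$s > 1) for (q in 2:lay$s) r <- pmax(r, M[q, ])
    return(r)
  }
  grp <- rep.int(seq_len(lay$n), lay$sizes)
  if (what == "sum") as.numeric(rowsum(x_sorted, grp))
  else vapply(split(x_sorted, grp), max, numeric(1))
}

# softmax of edge scores over each target's in-neighbourhood
edge_softmax <- function(e, lay) {
  es <- e[lay$ord]
  mx <- group_reduce(es, lay, "max")
  ex <- exp(es - rep.int(mx, lay$sizes))
  den <- group_reduce(ex, lay, "sum")
  alpha_sorted <- ex / rep.int(den, lay$sizes)
  alpha <- numeric(length(e))
  alpha[lay$ord] <- alpha_sorted
  alpha
}

# backward of edge_softmax: de = alpha * (dalpha - sum_grp(alpha * dalpha))
edge_softmax_bwd <- function(alpha, dalpha, lay) {
  ad <- (alpha * dalpha)[lay$ord]
  tot <- group_reduce(ad, lay, "sum")
  de <- numeric(length(alpha))
  de[lay$ord] <- ad - (alpha[lay$ord]) * rep.int(tot, lay$sizes)
  de
}

# scatter-add rows of M (one per edge) into an n x F matrix by index
scatter_rows <- function(M, index, n) {
  out <- rowsum(M, index)
  full <- matrix(0, n, ncol(M))
  full[as.integer(rownames(out)), ] <- out
  full
}

#' Attention coefficients of one GAT layer
#'
#' Computes the per-edge, per-head attention weights
#' `alpha_ij = softmax_{j in N(i)} LeakyReLU(a . [W h_i || W h_j])`,
#' where `N(i)` is the in-neighbourhood of target `i`.
#'
#' @param layer layer parameters: a list with element `heads`, itself a
#'   list of `list(W = in x F matrix, a = length 2F vector)` (target half
#'   first).
#' @param h node feature matrix (`n x in`).
#' @param edges edge index matrix with columns `source`, `target`
#'   (self-loops included as needed so every node has an in-edge).
#' @param slope LeakyReLU negative slope.
#' @return `n_edges x n_heads` matrix of attention weights in `(0, 1]`.
#' @export
attention_coefficients <- function(layer, h, edges, slope = 0.2) {
  lay <- edge_layout(edges, nrow(h))
  out <- sapply(layer$heads, function(hd) {
    Fdim <- ncol(hd$W)
    G <- h %*% hd$W
    ei <- as.numeric(G %*% hd$a[seq_len(Fdim)])
    ej <- as.numeric(G %*% hd$a[Fdim + seq_len(Fdim)])
    s <- ei[lay$tgt] + ej[lay$src]
    e <- ifelse(s > 0, s, slope * s)
    edge_softmax(e, lay)
  })
  matrix(out, ncol = length(layer$heads))
}

# forward one multi-head layer; returns concat head outputs + cache
gat_layer_fwd <- function(layer, H, lay, slope, keep_cache = FALSE) {
  heads_out <- vector("list", length(layer$heads))
  caches <- vector("list", length(layer$heads))
  for (hh in seq_along(layer$heads)) {
    hd <- layer$heads[[hh]]
    Fdim <- ncol(hd$W)
    G <- H %*% hd$W
    ei <- as.numeric(G %*% hd$a[seq_len(Fdim)])
    ej <- as.numeric(G %*% hd$a[Fdim + seq_len(Fdim)])
    s <- ei[lay$tgt] + ej[lay$src]
    e <- ifelse(s > 0, s, slope * s)
    alpha <- edge_softmax(e, lay)
    Gsrc <- G[lay$src, , drop = FALSE]
    out <- scatter_rows(alpha * Gsrc, lay$tgt, lay$n)
    heads_out[[hh]] <- out
    if (keep_cache)
      caches[[hh]] <- list(G = G, s = s, alpha = alpha)
  }
  list(out = do.call(cbind, heads_out), caches = caches)
}

# backward one layer; dOut is n x (F*heads); returns grads + dH
gat_layer_bwd <- function(layer, H, lay, slope, caches, dOut) {
  dH <- matrix(0, nrow(H), ncol(H))
  gheads <- vector("list", length(layer$heads))
  for (hh in seq_along(layer$heads)) {
    hd <- layer$heads[[hh]]
    Fdim <- ncol(hd$W)
    cache <- caches[[hh]]
    cols <- (hh - 1L) * Fdim + seq_len(Fdim)
    dout <- dOut[, cols, drop = FALSE]
    G <- cache$G
    alpha <- cache$alpha
    dtgt <- dout[lay$tgt, , drop = FALSE]
    Gsrc <- G[lay$src, , drop = FALSE]
    dalpha <- rowSums(Gsrc * dtgt)
    dG <- scatter_rows(alpha * dtgt, lay$src, lay$n)
    de <- edge_softmax_bwd(alpha, dalpha, lay)
    ds <- de * ifelse(cache$s > 0, 1, slope)
    dei <- scatter_rows(matrix(ds, ncol = 1), lay$tgt, lay$n)[, 1]
    dej <- scatter_rows(matrix(ds, ncol = 1), lay$src, lay$n)[, 1]
    ai <- hd$a[seq_len(Fdim)]
    aj <- hd$a[Fdim + seq_len(Fdim)]
    da <- c(as.numeric(crossprod(G, dei)), as.numeric(crossprod(G, dej)))
    dG <- dG + outer(dei, ai) + outer(dej, aj)
    dW <- crossprod(H, dG)
    dH <- dH + tcrossprod(dG, hd$W)
    gheads[[hh]] <- list(W = dW, a = da)
  }
  list(dH = dH, heads = gheads)
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

log_softmax_rows <- function(Z) {
  m <- apply(Z, 1, max)
  Zs <- Z - m
  Zs - log(rowSums(exp(Zs)))
}

#' Forward pass of the two-layer GAT
#'
#' Layer 1: multi-head attention, head outputs concatenated, then ELU;
#' layer 2: single-head attention mapping to the class dimension, then a
#' per-node log-softmax.
#'
#' @param params list with elements `layer1` and `layer2`, each as
#'   described in [attention_coefficients()].
#' @param features node feature matrix (`n x in_dim`).
#' @param edges edge index matrix (columns `source`, `target`).
#' @param slope attention LeakyReLU slope.
#' @return `n x n_classes` matrix of log-probabilities.
#' @export
gat_forward <- function(params, features, edges, slope = 0.2) {
  H <- as.matrix(features)
  lay <- edge_layout(edges, nrow(H))
  l1 <- gat_layer_fwd(params$layer1, H, lay, slope)
  H1 <- elu(l1$out)
  l2 <- gat_layer_fwd(params$layer2, H1, lay, slope)
  log_softmax_rows(l2$out)
}

init_gat_params <- function(in_dim, n_classes, config) {
  glorot <- function(nr, nc) {
    matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  }
  mk_head <- function(din, dout) {
    list(W = glorot(din, dout), a = as.numeric(glorot(2 * dout, 1)))
  }
  d1 <- config$hidden_dim_per_head
  layer1 <- list(heads = lapply(seq_len(config$heads_layer1),
                                function(i) mk_head(in_dim, d1)))
  hid <- d1 * config$heads_layer1
  layer2 <- list(heads = lapply(seq_len(config$heads_layer2),
                                function(i) mk_head(hid, n_classes)))
  list(layer1 = layer1, layer2 = layer2,
       Wd = numeric(hid), bd = 0)        # linear domain head on layer-1 output
}

# flatten/unflatten params for the Adam updater
gat_flatten <- function(p) {
  out <- list()
  for (ly in c("layer1", "layer2"))
    for (hh in seq_along(p[[ly]]$heads)) {
      out[[paste0(ly, "_W", hh)]] <- p[[ly]]$heads[[hh]]$W
      out[[paste0(ly, "_a", hh)]] <- p[[ly]]$heads[[hh]]$a
    }
  out$Wd <- p$Wd
  out$bd <- p$bd
  out
}

gat_unflatten <- function(flat, template) {
  p <- template
  for (ly in c("layer1", "layer2"))
    for (hh in seq_along(p[[ly]]$heads)) {
      p[[ly]]$heads[[hh]]$W <- flat[[paste0(ly, "_W", hh)]]
      p[[ly]]$heads[[hh]]$a <- flat[[paste0(ly, "_a", hh)]]
    }
  p$Wd <- flat$Wd
  p$bd <- flat$bd
  p
}

#' Train the GAT annotator
#'
#' Full-batch transductive training on the merged cell graph: the
#' cross-entropy of reference nodes drives classification, while an
#' optional domain-adaptation term — a linear domain classifier on the
#' layer-1 representation trained through a gradient-reversal coupling to
#' predict reference-vs-query membership — pushes representations to be
#' domain-indistinguishable (weight `lambda =`
#' `config$domain_loss_weight`). A stratified 10% of reference nodes is
#' held out; the best-epoch parameters by held-out cross-entropy are kept.
#'
#' @param features `node_features` or a numeric matrix (`n x in_dim`).
#' @param graph a [knn_adjacency()] graph over the same cells.
#' @param labels character vector length `n`; `NA` for query cells.
#' @param is_reference logical mask of reference cells.
#' @param config a [gat_config()].
#' @param add_self_loops include self-loops in the edge index.
#' @param verbose print progress.
#' @return An object of class `gat_model`: `params`, `classes`, `config`,
#'   `history` (epoch, train_loss, ce, domain_bce, holdout_ce),
#'   `best_epoch`, `single_class` flag.
#' @export
train_gat <- function(features, graph, labels, is_reference,
                      config = gat_config(), add_self_loops = TRUE,
                      verbose = TRUE) {
  H <- if (inherits(features, "node_features")) features$features
       else as.matrix(features)
  n <- nrow(H)
  stopifnot(length(labels) == n, length(is_reference) == n)
  classes <- sort(unique(labels[is_reference]))
  if (length(classes) < 2L) {
    warning("single reference class '", classes,
            "': bypassing training; all query cells get this class")
    return(structure(list(params = NULL, classes = classes, config = config,
                          history = tibble::tibble(), best_epoch = 0L,
                          single_class = TRUE, slope = config$leaky_relu_slope,
                          add_self_loops = add_self_loops),
                     class = "gat_model"))
  }
  y <- match(labels, classes)
  counts <- table(y[is_reference])
  small <- names(counts)[counts < 2]
  abort_if(length(small) > 0L, "class(es) with a single reference cell: ",
           paste(classes[as.integer(small)], collapse = ", "))

  edges <- to_edge_index(graph, add_self_loops = add_self_loops)
  lay <- edge_layout(edges, n)
  slope <- config$leaky_relu_slope
  lambda <- config$domain_loss_weight
  dom_target <- as.numeric(is_reference)

  with_seed(config$seed, {
    params <- init_gat_params(ncol(H), length(classes), config)
    flat <- gat_flatten(params)
    opt <- adam_init(flat)

    ref_idx <- which(is_reference)
    hold <- unlist(lapply(split(ref_idx, y[ref_idx]), function(ix) {
      nh <- floor(length(ix) / 10)
      if (nh > 0) sample(ix, nh) else integer(0)
    }), use.names = FALSE)
    train_nodes <- setdiff(ref_idx, hold)

    best <- list(loss = Inf, flat = flat, epoch = 0L)
    hist <- list()
    stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      params <- gat_unflatten(flat, params)
      l1 <- gat_layer_fwd(params$layer1, H, lay, slope, keep_cache = TRUE)
      H1 <- elu(l1$out)
      l2 <- gat_layer_fwd(params$layer2, H1, lay, slope, keep_cache = TRUE)
      logp <- log_softmax_rows(l2$out)

      ce <- -mean(logp[cbind(train_nodes, y[train_nodes])])
      dlogits <- matrix(0, n, length(classes))
      P <- exp(logp)
      dlogits[train_nodes, ] <- P[train_nodes, , drop = FALSE]
      dlogits[cbind(train_nodes, y[train_nodes])] <-
        dlogits[cbind(train_nodes, y[train_nodes])] - 1
      dlogits <- dlogits / length(train_nodes)

      # domain-adaptation head on the layer-1 representation
      if (lambda > 0) {
        dl <- as.numeric(H1 %*% params$Wd + params$bd)
        dom_bce <- bce_with_logits(dl, dom_target)
        ddl <- (sigmoid(dl) - dom_target) / n
        gWd <- as.numeric(crossprod(H1, ddl)) * lambda
        gbd <- sum(ddl) * lambda
        dH1_dom <- -lambda * outer(ddl, params$Wd)  # gradient reversal
      } else {
        dom_bce <- 0
        gWd <- params$Wd * 0
        gbd <- 0
        dH1_dom <- 0
      }
      total <- ce + lambda * dom_bce
      abort_if(!is.finite(total), "non-finite GAT loss at epoch ", epoch)

      b2 <- gat_layer_bwd(params$layer2, H1, lay, slope, l2$caches, dlogits)
      dH1 <- (b2$dH + dH1_dom) * elu_grad(l1$out)
      b1 <- gat_layer_bwd(params$layer1, H, lay, slope, l1$caches, dH1)

      grads <- list()
      for (hh in seq_along(b1$heads)) {
        grads[[paste0("layer1_W", hh)]] <- b1$heads[[hh]]$W
        grads[[paste0("layer1_a", hh)]] <- b1$heads[[hh]]$a
      }
      for (hh in seq_along(b2$heads)) {
        grads[[paste0("layer2_W", hh)]] <- b2$heads[[hh]]$W
        grads[[paste0("layer2_a", hh)]] <- b2$heads[[hh]]$a
      }
      grads$Wd <- gWd
      grads$bd <- gbd

      stp <- adam_step(flat, grads, opt, config$learning_rate)
      flat <- stp$params
      opt <- stp$opt

      monitor <- if (length(hold) > 0)
        -mean(logp[cbind(hold, y[hold])]) else ce
      hist[[epoch]] <- c(epoch = epoch, train_loss = total, ce = ce,
                         domain_bce = dom_bce, holdout_ce = monitor)
      if (epoch %% 50 == 0)
        log_msg(sprintf("gat epoch %3d  ce %.4f  holdout %.4f",
                        epoch, ce, monitor), verbose = verbose)
      if (monitor < best$loss - 1e-6) {
        best <- list(loss = monitor, flat = flat, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
      }
    }
    structure(list(params = gat_unflatten(best$flat, params),
                   classes = classes, config = config,
                   history = tibble::as_tibble(do.call(rbind, hist)),
                   best_epoch = best$epoch, single_class = FALSE,
                   slope = slope, add_self_loops = add_self_loops,
                   holdout = hold),
              class = "gat_model")
  })
}

#' @export
print.gat_model <- function(x, ...) {
  if (x$single_class) {
    cat("<gat_model> degenerate single-class model:", x$classes, "\n")
  } else {
    cat(sprintf("<gat_model> %d classes, %d+%d heads, best epoch %d\n",
                length(x$classes), x$config$heads_layer1,
                x$config$heads_layer2, x$best_epoch))
  }
  invisible(x)
}

#' Annotate query cells with a trained GAT
#'
#' Runs the forward pass on the full merged graph and restricts the
#' log-softmax outputs to query cells. Argmax ties resolve to the lowest
#' class index.
#'
#' @param model a [train_gat()] fit.
#' @param features node features for all cells (matrix or `node_features`).
#' @param graph the cell graph used in training.
#' @param query_mask logical mask of cells to annotate.
#' @param cell_ids optional cell identifiers (defaults to feature row
#'   names, then to `cell_<i>`).
#' @return An object of class `annotation_result`: tibble-compatible list
#'   with `cell_id`, `predicted_label`, `confidence` and the
#'   `log_prob` matrix (one column per class).
#' @export
predict_gat <- function(model, features, graph, query_mask,
                        cell_ids = NULL) {
  stopifnot(inherits(model, "gat_model"))
  H <- if (inherits(features, "node_features")) features$features
       else as.matrix(features)
  n <- nrow(H)
  cell_ids <- cell_ids %||% rownames(H) %||% paste0("cell_", seq_len(n))
  query_mask <- as.logical(query_mask)
  if (model$single_class) {
    nq <- sum(query_mask)
    lp <- matrix(0, nq, 1, dimnames = list(NULL, model$classes))
    return(structure(list(cell_id = cell_ids[query_mask],
                          predicted_label = rep(model$classes, nq),
                          confidence = rep(1, nq), log_prob = lp),
                     class = "annotation_result"))
  }
  edges <- to_edge_index(graph, add_self_loops = model$add_self_loops)
  logp <- gat_forward(model$params, H, edges, model$slope)
  colnames(logp) <- model$classes
  lp <- logp[query_mask, , drop = FALSE]
  if (nrow(lp) == 0L) {
    pred <- character(0)
    conf <- numeric(0)
  } else {
    pred <- model$classes[max.col(lp, ties.method = "first")]
    conf <- exp(apply(lp, 1, max))
  }
  structure(list(cell_id = cell_ids[query_mask], predicted_label = pred,
                 confidence = conf, log_prob = lp),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %d query cells, %d classes\n",
              length(x$cell_id), ncol(x$log_prob)))
  if (length(x$predicted_label))
    print(table(x$predicted_label))
  invisible(x)
}

#' @rdname predict_gat
#' @param x an `annotation_result`.
#' @param ... unused.
#' @method tidy annotation_result
#' @export
tidy.annotation_result <- function(x, ...) {
  tibble::tibble(cell_id = x$cell_id, predicted_label = x$predicted_label,
                 confidence = x$confidence)
}
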