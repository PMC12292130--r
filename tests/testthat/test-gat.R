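# Attention mechanics, forward-pass contracts and GAT training behaviour.

rand_layer <- function(din, dout, heads, seed = 1) {
  set.seed(seed)
  list(heads = lapply(seq_len(heads), function(i)
    list(W = matrix(rnorm(din * dout, sd = 0.5), din, dout),
         a = rnorm(2 * dout, sd = 0.5))))
}

rand_params <- function(din, hid, ncls, heads = 4, seed = 1) {
  list(layer1 = rand_layer(din, hid, heads, seed),
       layer2 = rand_layer(hid * heads, ncls, 1, seed + 1))
}

test_that("attention weights are positive and sum to 1 per neighbourhood", {
  set.seed(20)
  X <- matrix(rnorm(50 * 6), 50, 6)
  g <- knn_adjacency(X, 5)
  edges <- to_edge_index(g, TRUE)
  layer <- rand_layer(6, 4, 3, seed = 2)
  al <- attention_coefficients(layer, X, edges, slope = 0.2)
  expect_true(all(al > 0 & al <= 1))
  for (h in 1:3) {
    sums <- tapply(al[, h], edges[, "target"], sum)
    expect_equal(as.numeric(sums), rep(1, 50), tolerance = 1e-6)
  }
})

test_that("a single in-edge gets attention exactly 1", {
  h <- matrix(rnorm(6), 3, 2)
  edges <- cbind(source = c(2, 3, 1), target = c(1, 2, 3))  # one edge each
  layer <- rand_layer(2, 3, 1, seed = 3)
  al <- attention_coefficients(layer, h, edges)
  expect_equal(as.numeric(al), rep(1, 3))
})

test_that("identical node features give uniform attention", {
  h <- matrix(1, 6, 3)
  g <- knn_adjacency(matrix(rnorm(12), 6, 2), 2)
  edges <- to_edge_index(g, TRUE)
  layer <- rand_layer(3, 4, 2, seed = 4)
  al <- attention_coefficients(layer, h, edges)
  expect_equal(as.numeric(al), rep(1 / 3, nrow(edges) * 2),
               tolerance = 1e-9)  # in-degree 3 (k=2 + self)
})

test_that("a node with no in-edges errors when self-loops are off", {
  h <- matrix(rnorm(6), 3, 2)
  edges <- cbind(source = c(1, 1), target = c(2, 3))  # node 1 uncovered
  layer <- rand_layer(2, 2, 1)
  expect_error(attention_coefficients(layer, h, edges), "no in-edges")
})

test_that("log-softmax outputs exponentiate-sum to one", {
  set.seed(6)
  X <- matrix(rnorm(30 * 5), 30, 5)
  g <- knn_adjacency(X, 4)
  params <- rand_params(5, 7, 4, seed = 8)
  logp <- gat_forward(params, X, to_edge_index(g, TRUE))
  expect_equal(dim(logp), c(30, 4))
  expect_equal(rowSums(exp(logp)), rep(1, 30), tolerance = 1e-6)
})

test_that("a 3-node forward pass matches the hand-computed oracle", {
  # uniform attention by construction: identical features everywhere
  h <- matrix(1, 3, 2)
  edges <- cbind(source = c(1, 2, 3, 1, 2, 3),
                 target = c(2, 3, 1, 1, 2, 3))  # ring + self-loops
  W1 <- matrix(c(1, 0, 0, 1), 2, 2)             # identity
  params <- list(
    layer1 = list(heads = list(list(W = W1, a = rep(0, 4)))),
    layer2 = list(heads = list(list(W = matrix(c(1, 0, 0, 1), 2, 2),
                                    a = rep(0, 4)))))
  logp <- gat_forward(params, h, edges)
  # layer 1: alpha = 1/2 over {self, predecessor}; Wh_j = (1,1);
  # aggregation = (1,1); ELU(1) = 1. layer 2 similarly -> logits (1,1);
  # log-softmax of equal logits = log(1/2)
  expect_equal(unname(logp), matrix(log(0.5), 3, 2), tolerance = 1e-12)

  # asymmetric variant: distinct features, single neighbour each
  h2 <- matrix(c(1, 2, 4, 0, 0, 0), 3, 2)
  edges2 <- cbind(source = c(2, 3, 1), target = c(1, 2, 3))
  logp2 <- gat_forward(params, h2, edges2)
  # alpha = 1 on the unique in-edge; layer1 out_i = h_{pred(i)}; ELU keeps
  # non-negatives; layer2 shifts one more hop, so node 1's logits = h_3
  expect_equal(unname(logp2[1, ]), c(4, 0) - log(sum(exp(c(4, 0)))),
               tolerance = 1e-9)
  expect_equal(unname(logp2[2, ]), c(1, 0) - log(sum(exp(c(1, 0)))),
               tolerance = 1e-9)
  expect_equal(unname(logp2[3, ]), c(2, 0) - log(sum(exp(c(2, 0)))),
               tolerance = 1e-9)
})

test_that("training with lambda = 0 reduces the loss to cross-entropy", {
  sim <- small_sim()
  merged <- merge_reference_query(sim$reference, sim$query)
  nf <- spectral_embed(merged, 6)
  g <- knn_adjacency(nf$features, 5)
  fit <- train_gat(nf, g, merged$cells$label, merged$cells$is_reference,
                   tiny_gat_config(domain_loss_weight = 0), verbose = FALSE)
  expect_equal(fit$history$train_loss, fit$history$ce, tolerance = 1e-12)
  expect_true(all(fit$history$domain_bce == 0))
})

test_that("training is deterministic under a fixed seed", {
  sim <- small_sim()
  merged <- merge_reference_query(sim$reference, sim$query)
  nf <- spectral_embed(merged, 6)
  g <- knn_adjacency(nf$features, 5)
  cfg <- tiny_gat_config(max_epochs = 15)
  f1 <- train_gat(nf, g, merged$cells$label, merged$cells$is_reference,
                  cfg, verbose = FALSE)
  f2 <- train_gat(nf, g, merged$cells$label, merged$cells$is_reference,
                  cfg, verbose = FALSE)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("class relabeling permutes prediction columns equivariantly", {
  sim <- small_sim()
  merged <- merge_reference_query(sim$reference, sim$query)
  nf <- spectral_embed(merged, 6)
  g <- knn_adjacency(nf$features, 5)
  fit <- train_gat(nf, g, merged$cells$label, merged$cells$is_reference,
                   tiny_gat_config(max_epochs = 20), verbose = FALSE)
  res <- predict_gat(fit, nf, g, !merged$cells$is_reference)

  # permute the trained model's class columns by hand
  perm <- c(2, 3, 1)
  fitp <- fit
  fitp$classes <- fit$classes[perm]
  fitp$params$layer2$heads[[1]]$W <-
    fit$params$layer2$heads[[1]]$W[, perm]
  nc <- length(fit$classes)
  fitp$params$layer2$heads[[1]]$a <-
    fit$params$layer2$heads[[1]]$a[c(perm, nc + perm)]
  resp <- predict_gat(fitp, nf, g, !merged$cells$is_reference)
  expect_equal(unname(resp$log_prob), unname(res$log_prob[, perm]))
  expect_equal(resp$predicted_label, res$predicted_label)
})

test_that("empty query mask yields an empty result", {
  sim <- small_sim()
  merged <- merge_reference_query(sim$reference, sim$query)
  nf <- spectral_embed(merged, 6)
  g <- knn_adjacency(nf$features, 5)
  fit <- train_gat(nf, g, merged$cells$label, merged$cells$is_reference,
                   tiny_gat_config(max_epochs = 5), verbose = FALSE)
  res <- predict_gat(fit, nf, g, rep(FALSE, nrow(nf$features)))
  expect_length(res$cell_id, 0)
  expect_equal(nrow(res$log_prob), 0)
  expect_equal(nrow(tidy(res)), 0)
})

test_that("single-class reference bypasses training with a warning", {
  sim <- small_sim()
  merged <- merge_reference_query(sim$reference, sim$query)
  labels <- ifelse(merged$cells$is_reference, "only", NA)
  nf <- spectral_embed(merged, 6)
  g <- knn_adjacency(nf$features, 5)
  expect_warning(
    fit <- train_gat(nf, g, labels, merged$cells$is_reference,
                     tiny_gat_config(), verbose = FALSE),
    "single reference class")
  res <- predict_gat(fit, nf, g, !merged$cells$is_reference)
  expect_true(all(res$predicted_label == "only"))
})

test_that("a class with one reference cell is rejected by name", {
  sim <- small_sim()
  merged <- merge_reference_query(sim$reference, sim$query)
  labels <- merged$cells$label
  labels[which(merged$cells$is_reference)[1]] <- "rare"
  nf <- spectral_embed(merged, 6)
  g <- knn_adjacency(nf$features, 5)
  expect_error(train_gat(nf, g, labels, merged$cells$is_reference,
                         tiny_gat_config(), verbose = FALSE), "rare")
})
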