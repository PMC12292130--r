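# Backpropagation of both networks against central-difference gradients.

test_that("CNN analytic gradients match numerical differentiation", {
  ns <- asNamespace("atacGAT")
  cfg <- seq_model_config(window_length = 32, stem_kernel = 5,
                          stem_channels = 6, n_towers = 2,
                          tower_channel_growth = 1.3, tower_kernel = 3,
                          pool_width = 2, post_conv_channels = 5,
                          bottleneck_d = 4, dropout_p = 0, seed = 7)
  arch <- ns$seq_arch(cfg)
  set.seed(42)
  init <- ns$init_seq_params(arch, n_cells = 7, n_batches = 2, cfg)
  params <- init$params
  state <- init$state
  codes <- matrix(sample(0:4, 3 * 32, replace = TRUE), 3, 32)
  Bmat <- ns$batch_indicator(sample(c("a", "b"), 7, replace = TRUE))
  Y <- matrix(rbinom(21, 1, 0.5), 3, 7)

  loss_fn <- function(p) {
    fw <- ns$seq_forward(p, state, arch, cfg, codes, Bmat, train = TRUE)
    ns$bce_with_logits(fw$logits, Y)
  }
  fw <- ns$seq_forward(params, state, arch, cfg, codes, Bmat, train = TRUE)
  dlogits <- (ns$sigmoid(fw$logits) - Y) / length(fw$logits)
  g <- ns$seq_backward(params, arch, cfg, fw$cache, dlogits, Bmat)

  eps <- 1e-6
  for (nm in names(g)) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      rel <- abs(num - g[[nm]][i]) / max(1e-8, abs(num) + abs(g[[nm]][i]))
      expect_lt(rel, 1e-4, label = paste0("rel err of d", nm, "[", i, "]"))
    }
  }
})

test_that("GAT analytic gradients match numerical differentiation", {
  ns <- asNamespace("atacGAT")
  set.seed(1)
  n <- 12; d <- 5; ncls <- 3
  H <- matrix(rnorm(n * d), n, d)
  gcfg <- gat_config(hidden_dim_per_head = 4, heads_layer1 = 2, seed = 3)
  gp <- atacGAT:::with_seed(3, ns$init_gat_params(d, ncls, gcfg))
  edges <- to_edge_index(knn_adjacency(H, 3), TRUE)
  lay <- ns$edge_layout(edges, n)
  y <- sample(seq_len(ncls), n, replace = TRUE)
  train_nodes <- 1:8
  dom_target <- as.numeric(seq_len(n) <= 8)
  lambda <- 0.1
  slope <- 0.2

  loss_fn <- function(p) {
    l1 <- ns$gat_layer_fwd(p$layer1, H, lay, slope)
    H1 <- ns$elu(l1$out)
    l2 <- ns$gat_layer_fwd(p$layer2, H1, lay, slope)
    logp <- ns$log_softmax_rows(l2$out)
    ce <- -mean(logp[cbind(train_nodes, y[train_nodes])])
    ce + lambda * ns$bce_with_logits(as.numeric(H1 %*% p$Wd + p$bd),
                                     dom_target)
  }

  l1 <- ns$gat_layer_fwd(gp$layer1, H, lay, slope, keep_cache = TRUE)
  H1 <- ns$elu(l1$out)
  l2 <- ns$gat_layer_fwd(gp$layer2, H1, lay, slope, keep_cache = TRUE)
  logp <- ns$log_softmax_rows(l2$out)
  P <- exp(logp)
  dlogits <- matrix(0, n, ncls)
  dlogits[train_nodes, ] <- P[train_nodes, ]
  dlogits[cbind(train_nodes, y[train_nodes])] <-
    dlogits[cbind(train_nodes, y[train_nodes])] - 1
  dlogits <- dlogits / length(train_nodes)
  dl <- as.numeric(H1 %*% gp$Wd + gp$bd)
  ddl <- (ns$sigmoid(dl) - dom_target) / n
  gWd <- as.numeric(crossprod(H1, ddl)) * lambda
  # true (non-reversed) gradient here: the check differentiates the loss
  dH1_dom <- lambda * outer(ddl, gp$Wd)
  b2 <- ns$gat_layer_bwd(gp$layer2, H1, lay, slope, l2$caches, dlogits)
  dH1 <- (b2$dH + dH1_dom) * ns$elu_grad(l1$out)
  b1 <- ns$gat_layer_bwd(gp$layer1, H, lay, slope, l1$caches, dH1)

  eps <- 1e-6
  checks <- list(
    list(g = b1$heads[[1]]$W,
         bump = function(p, i, e) { p$layer1$heads[[1]]$W[i] <-
           p$layer1$heads[[1]]$W[i] + e; p }),
    list(g = b1$heads[[2]]$a,
         bump = function(p, i, e) { p$layer1$heads[[2]]$a[i] <-
           p$layer1$heads[[2]]$a[i] + e; p }),
    list(g = b2$heads[[1]]$W,
         bump = function(p, i, e) { p$layer2$heads[[1]]$W[i] <-
           p$layer2$heads[[1]]$W[i] + e; p }),
    list(g = gWd,
         bump = function(p, i, e) { p$Wd[i] <- p$Wd[i] + e; p }))
  for (ck in checks) {
    idx <- sample(length(ck$g), min(4, length(ck$g)))
    for (i in idx) {
      num <- (loss_fn(ck$bump(gp, i, eps)) -
                loss_fn(ck$bump(gp, i, -eps))) / (2 * eps)
      rel <- abs(num - ck$g[i]) / max(1e-8, abs(num) + abs(ck$g[i]))
      expect_lt(rel, 1e-5)
    }
  }
})
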