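# Sequence accessibility model: a 1-D CNN trained to predict each peak's
# binary accessibility across all N cells from the peak's DNA window. The
# transposed weights of the per-cell output layer are the cell embeddings.

#' Sequence model configuration
#'
#' Architecture and training hyperparameters of the peak-sequence CNN.
#' Defaults follow the scBasset-style lineage: a 17-bp stem convolution with
#' 288 channels, a stack of conv towers with ~1.12x channel growth and
#' 2x max-pooling, a 1x1 condensing convolution, and a 64-unit bottleneck
#' whose per-cell output weights double as cell embeddings.
#'
#' @param window_length input DNA window in bp, centered on the peak midpoint.
#' @param stem_kernel stem convolution width (bp).
#' @param stem_channels stem output channels.
#' @param n_towers number of conv-tower blocks.
#' @param tower_channel_growth multiplicative channel growth per tower
#'   (rounded).
#' @param tower_kernel tower convolution width (bp).
#' @param pool_width max-pooling width after the stem and after each tower;
#'   a trailing remainder of the sequence length is dropped.
#' @param post_conv_channels channels of the 1x1 condensing convolution.
#' @param bottleneck_d bottleneck width; equals the cell-embedding dimension.
#' @param dropout_p dropout probability after the bottleneck.
#' @param learning_rate,batch_size,max_epochs Adam learning rate, minibatch
#'   size (in peaks) and epoch cap.
#' @param weight_decay decoupled (AdamW-style) L2 decay applied to the
#'   convolution and dense weights of the trunk (never to biases,
#'   normalization parameters or the per-cell/batch output weights);
#'   discourages peak memorization in favour of reusable sequence
#'   features on small peak sets.
#' @param n_validation_peaks peaks held out for validation/early stopping
#'   (clamped to 20% of available peaks).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param min_epochs epochs to run before early stopping may trigger.
#'   Motif discovery on small peak sets shows a characteristic plateau at
#'   the base-rate loss before the validation loss drops; a burn-in
#'   prevents stopping inside that plateau.
#' @param seed integer seed for initialization, splits, shuffling, dropout.
#' @return A list of class `seq_model_config`.
#' @export
seq_model_config <- function(window_length = 1344, stem_kernel = 17,
                             stem_channels = 288, n_towers = 6,
                             tower_channel_growth = 1.12, tower_kernel = 5,
                             pool_width = 2, post_conv_channels = 256,
                             bottleneck_d = 64, dropout_p = 0.2,
                             learning_rate = 1e-3, batch_size = 256,
                             max_epochs = 300, n_validation_peaks = 2000,
                             early_stop_patience = 20, min_epochs = 0,
                             weight_decay = 0, seed = 1) {
  cfg <- as.list(environment())
  abort_if(bottleneck_d <= 0, "bottleneck_d must be positive")
  abort_if(stem_kernel %% 2 == 0 || tower_kernel %% 2 == 0,
           "convolution kernels must be odd (same-padding)")
  structure(cfg, class = "seq_model_config")
}

# Static shape plan: lengths and channel counts at every stage.
seq_arch <- function(config) {
  p <- config$pool_width
  L <- config$window_length %/% p            # after stem pool
  ch <- config$stem_channels
  towers <- vector("list", config$n_towers)
  for (t in seq_len(config$n_towers)) {
    cout <- as.integer(round(config$stem_channels *
                               config$tower_channel_growth^t))
    towers[[t]] <- list(cin = ch, cout = cout, L_in = L,
                        k_eca = eca_kernel_size(cout))
    ch <- cout
    L <- L %/% p
  }
  abort_if(L < 1, "window_length too short for ", config$n_towers,
           " towers with pool_width ", p)
  list(stem = list(k = config$stem_kernel, cout = config$stem_channels,
                   L_in = config$window_length),
       towers = towers, L_final = L, post_cout = config$post_conv_channels,
       flat_dim = L * config$post_conv_channels, d = config$bottleneck_d)
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

init_seq_params <- function(arch, n_cells, n_batches, config) {
  p <- list()
  st <- list()
  p$stem_W <- he_init(arch$stem$k * 4L, arch$stem$cout, arch$stem$k * 4L)
  p$stem_b <- numeric(arch$stem$cout)
  k <- config$tower_kernel
  for (t in seq_along(arch$towers)) {
    tw <- arch$towers[[t]]
    pre <- paste0("t", t, "_")
    p[[paste0(pre, "c1_W")]] <- he_init(k * tw$cin, tw$cout, k * tw$cin)
    p[[paste0(pre, "c1_b")]] <- numeric(tw$cout)
    p[[paste0(pre, "c2_W")]] <- he_init(k * tw$cout, tw$cout, k * tw$cout)
    p[[paste0(pre, "c2_b")]] <- numeric(tw$cout)
    p[[paste0(pre, "bn1_g")]] <- rep(1, tw$cout)
    p[[paste0(pre, "bn1_b")]] <- numeric(tw$cout)
    p[[paste0(pre, "bn2_g")]] <- rep(1, tw$cout)
    p[[paste0(pre, "bn2_b")]] <- numeric(tw$cout)
    p[[paste0(pre, "eca_w")]] <- rnorm(tw$k_eca, sd = sqrt(1 / tw$k_eca))
    if (tw$cin != tw$cout)
      p[[paste0(pre, "proj_W")]] <- he_init(tw$cin, tw$cout, tw$cin)
    st[[paste0(pre, "bn1_mean")]] <- numeric(tw$cout)
    st[[paste0(pre, "bn1_var")]] <- rep(1, tw$cout)
    st[[paste0(pre, "bn2_mean")]] <- numeric(tw$cout)
    st[[paste0(pre, "bn2_var")]] <- rep(1, tw$cout)
  }
  cin_post <- if (length(arch$towers))
    arch$towers[[length(arch$towers)]]$cout else arch$stem$cout
  p$post_W <- he_init(cin_post, arch$post_cout, cin_post)
  p$post_b <- numeric(arch$post_cout)
  p$dense_W <- he_init(arch$flat_dim, arch$d, arch$flat_dim)
  p$dense_b <- numeric(arch$d)
  p$Wcell <- matrix(rnorm(n_cells * arch$d, sd = 0.01), n_cells, arch$d)
  p$bcell <- numeric(n_cells)
  p$Wbatch <- matrix(rnorm(n_batches * arch$d, sd = 0.01), n_batches, arch$d)
  p$bbatch <- numeric(n_batches)
  list(params = p, state = st)
}

# One-hot (B*L) x 4 design matrix from an integer code matrix (B x L).
codes_to_design <- function(codes) {
  B <- nrow(codes); L <- ncol(codes)
  cv <- as.integer(t(codes))               # b-major, position fastest
  X <- matrix(0, B * L, 4L)
  nz <- which(cv > 0L)
  X[cbind(nz, cv[nz])] <- 1
  X
}

# Full forward pass for a minibatch of peaks. Returns per-peak, per-cell
# logits (B x N), updated BN state, and caches for backprop (train only).
seq_forward <- function(params, state, arch, config, codes, Bmat = NULL,
                        train = FALSE, keep_cache = train) {
  B <- nrow(codes)
  pool <- config$pool_width
  cc <- list()
  X <- codes_to_design(codes)
  L <- arch$stem$L_in

  f <- conv1d_fwd(X, B, L, params$stem_W, params$stem_b, arch$stem$k)
  r <- relu_fwd(f$out)
  m <- maxpool_fwd(r$out, B, L, pool)
  if (keep_cache) cc$stem <- list(conv = f$cache, relu = r$cache,
                                  pool = m$cache)
  X <- m$out; L <- m$L2

  for (t in seq_along(arch$towers)) {
    tw <- arch$towers[[t]]
    pre <- paste0("t", t, "_")
    Xin <- X
    c1 <- conv1d_fwd(X, B, L, params[[paste0(pre, "c1_W")]],
                     params[[paste0(pre, "c1_b")]], config$tower_kernel)
    b1 <- bn_fwd(c1$out, params[[paste0(pre, "bn1_g")]],
                 params[[paste0(pre, "bn1_b")]],
                 state[[paste0(pre, "bn1_mean")]],
                 state[[paste0(pre, "bn1_var")]], train)
    state[[paste0(pre, "bn1_mean")]] <- b1$run_mean
    state[[paste0(pre, "bn1_var")]] <- b1$run_var
    r1 <- relu_fwd(b1$out)
    c2 <- conv1d_fwd(r1$out, B, L, params[[paste0(pre, "c2_W")]],
                     params[[paste0(pre, "c2_b")]], config$tower_kernel)
    b2 <- bn_fwd(c2$out, params[[paste0(pre, "bn2_g")]],
                 params[[paste0(pre, "bn2_b")]],
                 state[[paste0(pre, "bn2_mean")]],
                 state[[paste0(pre, "bn2_var")]], train)
    state[[paste0(pre, "bn2_mean")]] <- b2$run_mean
    state[[paste0(pre, "bn2_var")]] <- b2$run_var
    e <- eca_fwd(b2$out, B, L, params[[paste0(pre, "eca_w")]])
    res <- if (tw$cin != tw$cout) Xin %*% params[[paste0(pre, "proj_W")]]
           else Xin
    r2 <- relu_fwd(e$out + res)
    mp <- maxpool_fwd(r2$out, B, L, pool)
    if (keep_cache)
      cc[[paste0("tower", t)]] <- list(Xin = Xin, c1 = c1$cache,
                                       bn1 = b1$cache, r1 = r1$cache,
                                       c2 = c2$cache, bn2 = b2$cache,
                                       eca = e$cache, r2 = r2$cache,
                                       pool = mp$cache)
    X <- mp$out; L <- mp$L2
  }

  Xpost <- add_row_vec(X %*% params$post_W, params$post_b)
  rp <- relu_fwd(Xpost)
  if (keep_cache) cc$post <- list(Xin = X, relu = rp$cache)

  # flatten (B*L) x C -> B x (L*C), channel-major within each peak
  Cf <- arch$post_cout
  A <- array(rp$out, c(L, B, Cf))
  Fl <- matrix(aperm(A, c(2, 1, 3)), nrow = B)

  Z0 <- add_row_vec(Fl %*% params$dense_W, params$dense_b)
  dr <- dropout_fwd(Z0, config$dropout_p, train)
  Z <- dr$out
  if (keep_cache) cc$head <- list(Fl = Fl, drop = dr$cache, L = L)

  logits <- add_row_vec(tcrossprod(Z, params$Wcell), params$bcell)
  if (!is.null(Bmat)) {
    U <- add_row_vec(tcrossprod(Z, params$Wbatch), params$bbatch)
    logits <- logits + tcrossprod(U, Bmat)
    if (keep_cache) cc$head$U <- TRUE
  }
  if (keep_cache) cc$head$Z <- Z
  list(logits = logits, state = state, cache = cc, Z = Z)
}

seq_backward <- function(params, arch, config, cache, dlogits, Bmat = NULL) {
  g <- list()
  Z <- cache$head$Z
  g$Wcell <- crossprod(dlogits, Z)
  g$bcell <- colSums(dlogits)
  dZ <- dlogits %*% params$Wcell
  if (!is.null(Bmat) && isTRUE(cache$head$U)) {
    dU <- dlogits %*% Bmat
    g$Wbatch <- crossprod(dU, Z)
    g$bbatch <- colSums(dU)
    dZ <- dZ + dU %*% params$Wbatch
  }
  dZ <- dropout_bwd(cache$head$drop, dZ)
  Fl <- cache$head$Fl
  g$dense_W <- crossprod(Fl, dZ)
  g$dense_b <- colSums(dZ)
  dFl <- tcrossprod(dZ, params$dense_W)

  B <- nrow(dFl); L <- cache$head$L; Cf <- arch$post_cout
  A <- array(dFl, c(B, L, Cf))
  dX <- matrix(aperm(A, c(2, 1, 3)), nrow = B * L)

  dX <- relu_bwd(cache$post$relu, dX)
  g$post_W <- crossprod(cache$post$Xin, dX)
  g$post_b <- colSums(dX)
  dX <- tcrossprod(dX, params$post_W)

  for (t in rev(seq_along(arch$towers))) {
    tw <- arch$towers[[t]]
    pre <- paste0("t", t, "_")
    tc <- cache[[paste0("tower", t)]]
    dX <- maxpool_bwd(tc$pool, dX)
    dX <- relu_bwd(tc$r2, dX)
    dres <- dX
    eb <- eca_bwd(tc$eca, dX)
    g[[paste0(pre, "eca_w")]] <- eb$dw
    b2 <- bn_bwd(tc$bn2, eb$dX)
    g[[paste0(pre, "bn2_g")]] <- b2$dgamma
    g[[paste0(pre, "bn2_b")]] <- b2$dbeta
    c2 <- conv1d_bwd(tc$c2, params[[paste0(pre, "c2_W")]], b2$dX)
    g[[paste0(pre, "c2_W")]] <- c2$dW
    g[[paste0(pre, "c2_b")]] <- c2$db
    dr1 <- relu_bwd(tc$r1, c2$dX)
    b1 <- bn_bwd(tc$bn1, dr1)
    g[[paste0(pre, "bn1_g")]] <- b1$dgamma
    g[[paste0(pre, "bn1_b")]] <- b1$dbeta
    c1 <- conv1d_bwd(tc$c1, params[[paste0(pre, "c1_W")]], b1$dX)
    g[[paste0(pre, "c1_W")]] <- c1$dW
    g[[paste0(pre, "c1_b")]] <- c1$db
    dX <- c1$dX
    if (tw$cin != tw$cout) {
      g[[paste0(pre, "proj_W")]] <- crossprod(tc$Xin, dres)
      dX <- dX + tcrossprod(dres, params[[paste0(pre, "proj_W")]])
    } else {
      dX <- dX + dres
    }
  }

  dX <- maxpool_bwd(cache$stem$pool, dX)
  dX <- relu_bwd(cache$stem$relu, dX)
  sc <- conv1d_bwd(cache$stem$conv, params$stem_W, dX)
  g$stem_W <- sc$dW
  g$stem_b <- sc$db
  g
}

# Cell x batch one-hot indicator in a fixed (sorted) batch-level order.
batch_indicator <- function(batch, levels = sort(unique(batch))) {
  M <- matrix(0, length(batch), length(levels),
              dimnames = list(NULL, levels))
  M[cbind(seq_along(batch), match(batch, levels))] <- 1
  M
}

#' Train the sequence accessibility model
#'
#' Each training example is one peak: the input is the one-hot DNA window
#' centered on the peak, the target is the peak's binary accessibility
#' across all N cells of the merged dataset. The loss is mean sigmoid
#' binary cross-entropy over cells; a parallel batch head predicts
#' batch-specific peak accessibility added to each cell's logit through the
#' cell-batch indicator, absorbing batch-wide accessibility shifts.
#' A random subset of peaks is held out for validation; training stops
#' early on stalled validation loss and the best-epoch parameters are kept.
#'
#' @param merged merged reference+query [atac_dataset] (see
#'   [merge_reference_query()]).
#' @param genome named character vector of contig sequences covering the
#'   peaks.
#' @param config a [seq_model_config()].
#' @param use_batch_head logical; disable to train without the batch
#'   covariate head.
#' @param verbose print per-epoch progress.
#' @return An object of class `sequence_model` with elements `params`,
#'   `state`, `arch`, `config`, `cell_ids`, `batch_levels`, `history`
#'   (tibble: epoch, train_bce, valid_bce), `val_peaks` and `kept_peaks`
#'   (indices into the input peak set).
#' @export
train_sequence_model <- function(merged, genome, config = seq_model_config(),
                                 use_batch_head = TRUE, verbose = TRUE) {
  stopifnot(inherits(merged, "atac_dataset"),
            inherits(config, "seq_model_config"))
  seqs <- extract_peak_sequences(merged$peaks, genome, config$window_length)
  codes <- encode_windows(seqs, config$window_length)
  covered <- rowSums(codes > 0L) > 0L
  if (any(!covered))
    warning(sum(!covered), " peak(s) with no genome coverage (all-N window) ",
            "dropped from sequence-model training")
  kept <- which(covered)
  codes <- codes[kept, , drop = FALSE]
  Y <- as.matrix(merged$X)[kept, , drop = FALSE]
  n_peaks <- nrow(codes)
  n_cells <- ncol(Y)
  batch_levels <- sort(unique(merged$cells$batch))
  Bmat <- if (use_batch_head) batch_indicator(merged$cells$batch, batch_levels)
          else NULL
  arch <- seq_arch(config)

  with_seed(config$seed, {
    init <- init_seq_params(arch, n_cells, length(batch_levels), config)
    params <- init$params
    state <- init$state
    n_val <- max(1L, min(config$n_validation_peaks, n_peaks %/% 5L))
    val_idx <- sort(sample.int(n_peaks, n_val))
    train_idx <- setdiff(seq_len(n_peaks), val_idx)
    opt <- adam_init(params)

    valid_bce <- function(par, st) {
      tot <- 0
      for (i in split(val_idx, ceiling(seq_along(val_idx) /
                                         config$batch_size))) {
        fw <- seq_forward(par, st, arch, config, codes[i, , drop = FALSE],
                          Bmat, train = FALSE, keep_cache = FALSE)
        tot <- tot + bce_with_logits(fw$logits, Y[i, , drop = FALSE]) *
          length(i)
      }
      tot / length(val_idx)
    }

    best <- list(loss = Inf, params = params, state = state, epoch = 0L)
    hist <- list()
    stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tr_loss <- 0
      for (i in batches) {
        fw <- seq_forward(params, state, arch, config,
                          codes[i, , drop = FALSE], Bmat, train = TRUE)
        state <- fw$state
        yb <- Y[i, , drop = FALSE]
        loss <- bce_with_logits(fw$logits, yb)
        abort_if(!is.finite(loss),
                 "non-finite training loss at epoch ", epoch,
                 "; lower the learning rate or check the inputs")
        tr_loss <- tr_loss + loss * length(i)
        dlogits <- (sigmoid(fw$logits) - yb) / length(fw$logits)
        grads <- seq_backward(params, arch, config, fw$cache, dlogits, Bmat)
        decay_names <- grep("(_W$)|(^stem_W$)|(^post_W$)|(^dense_W$)",
                            names(params), value = TRUE)
        stp <- adam_step(params, grads, opt, config$learning_rate,
                         weight_decay = config$weight_decay,
                         decay_names = decay_names)
        params <- stp$params
        opt <- stp$opt
      }
      tr_loss <- tr_loss / length(ord)
      vl <- valid_bce(params, state)
      hist[[epoch]] <- c(epoch = epoch, train_bce = tr_loss, valid_bce = vl)
      log_msg(sprintf("seq epoch %3d  train %.4f  valid %.4f",
                      epoch, tr_loss, vl), verbose = verbose)
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = params, state = state,
                     epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience &&
              epoch >= config$min_epochs) break
      }
    }
    history <- tibble::as_tibble(do.call(rbind, hist))
    structure(list(params = best$params, state = best$state,
                   arch = arch, config = config,
                   cell_ids = merged$cells$cell_id,
                   batch_levels = batch_levels,
                   use_batch_head = use_batch_head,
                   history = history, best_epoch = best$epoch,
                   val_peaks = kept[val_idx], kept_peaks = kept),
              class = "sequence_model")
  })
}

#' @export
print.sequence_model <- function(x, ...) {
  cat(sprintf(paste0("<sequence_model> %d cells, window %d bp, %d towers, ",
                     "bottleneck %d\n  best epoch %d (valid BCE %.4f)\n"),
              nrow(x$params$Wcell), x$config$window_length,
              x$config$n_towers, x$arch$d, x$best_epoch,
              min(x$history$valid_bce)))
  invisible(x)
}

#' Per-cell accessibility logits for one peak sequence
#'
#' Runs the trained model in inference mode on a single DNA window and
#' returns the per-cell logits. When `batch_onehot` (the cell-by-batch
#' indicator) is supplied, the batch head's peak logit for each cell's
#' batch is added; an all-zero indicator is equivalent to disabling the
#' head.
#'
#' @param model a trained [train_sequence_model()] fit (an untrained,
#'   initialized model works too).
#' @param x a DNA string or a one-hot `L x 4` matrix (columns A, C, G, T).
#' @param batch_onehot optional `N_cells x N_batches` indicator matrix.
#' @return Numeric vector of length `N_cells`.
#' @export
forward_peak <- function(model, x, batch_onehot = NULL) {
  stopifnot(inherits(model, "sequence_model"))
  if (is.character(x)) {
    codes <- encode_windows(x, model$config$window_length)
  } else {
    stopifnot(is.matrix(x), ncol(x) == 4L)
    abort_if(nrow(x) != model$config$window_length,
             "sequence length ", nrow(x), " does not match the model window ",
             model$config$window_length)
    codes <- matrix(as.integer(x %*% 1:4), nrow = 1L)
  }
  fw <- seq_forward(model$params, model$state, model$arch, model$config,
                    codes, Bmat = batch_onehot, train = FALSE,
                    keep_cache = FALSE)
  as.numeric(fw$logits)
}

#' Predicted accessibility probabilities for a set of peaks
#'
#' Inference-mode forward pass over many peak windows; used for held-out
#' peak evaluation.
#'
#' @param model a trained `sequence_model`.
#' @param sequences character vector of DNA windows (any length; centered /
#'   padded to the model window).
#' @param batch_onehot optional cell-by-batch indicator matrix; `NULL`
#'   disables the batch head at inference.
#' @return `length(sequences) x N_cells` matrix of probabilities.
#' @export
predict_peak_accessibility <- function(model, sequences, batch_onehot = NULL) {
  stopifnot(inherits(model, "sequence_model"))
  codes <- encode_windows(sequences, model$config$window_length)
  out <- matrix(NA_real_, nrow(codes), nrow(model$params$Wcell))
  idx <- split(seq_len(nrow(codes)),
               ceiling(seq_len(nrow(codes)) / model$config$batch_size))
  for (i in idx) {
    fw <- seq_forward(model$params, model$state, model$arch, model$config,
                      codes[i, , drop = FALSE], Bmat = batch_onehot,
                      train = FALSE, keep_cache = FALSE)
    out[i, ] <- sigmoid(fw$logits)
  }
  out
}

#' Extract per-cell sequence embeddings
#'
#' The embedding of cell `c` is row `c` of the per-cell output weight
#' matrix (the transposed dense layer); batch-head weights are excluded.
#'
#' @param model a `sequence_model`.
#' @return `N_cells x bottleneck_d` numeric matrix with cell ids as row
#'   names.
#' @export
extract_cell_embeddings <- function(model) {
  stopifnot(inherits(model, "sequence_model"))
  emb <- model$params$Wcell
  rownames(emb) <- model$cell_ids
  emb
}

#' Area under the ROC curve for binary outcomes
#'
#' Rank-based (Mann-Whitney) AUC with midrank handling of score ties.
#'
#' @param scores numeric prediction scores.
#' @param labels binary outcomes (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
binary_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- as.numeric(sum(labels == 1))
  n0 <- as.numeric(sum(labels == 0))
  abort_if(n1 == 0 || n0 == 0, "need both positive and negative outcomes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
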