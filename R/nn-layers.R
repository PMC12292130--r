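# Minimal 1-D CNN engine with hand-derived backpropagation.
#
# A minibatch of B sequences of length L with C channels is stored as a
# (B*L) x C matrix in b-major order: row (b-1)*L + l holds position l of
# sequence b. Convolutions are computed as im2col gathers followed by one
# BLAS GEMM, which keeps the whole training loop in vectorized R.

# --- row-index helpers -------------------------------------------------

# index of row (b, l) blocks for all b = 1..B, l = 1..L, l fastest
rows_blocked <- function(B, L, stride_len) {
  rep.int((0:(B - 1)) * stride_len, rep.int(L, B)) + rep(seq_len(L), times = B)
}

add_row_vec <- function(M, v) M + rep(v, each = nrow(M))

# --- convolution (same padding, stride 1, odd kernel) ------------------
# im2col + GEMM, implemented in src/nn_ops.cpp

conv1d_fwd <- function(X, B, L, W, bias, k) {
  Y <- cpp_conv1d_fwd(X, B, L, k, W, bias)
  list(out = Y, cache = list(X = X, B = B, L = L, k = k))
}

conv1d_bwd <- function(cache, W, dY) {
  r <- cpp_conv1d_bwd(cache$X, cache$B, cache$L, cache$k, W, dY)
  list(dX = r$dX, dW = r$dW, db = as.numeric(r$db))
}

# --- max pooling (non-overlapping width p; trailing remainder dropped) --

maxpool_fwd <- function(X, B, L, p) {
  r <- cpp_maxpool_fwd(X, B, L, p)
  list(out = r$Y, L2 = L %/% p,
       cache = list(chosen = r$chosen, B = B, L = L, p = p))
}

maxpool_bwd <- function(cache, dY) {
  cpp_maxpool_bwd(cache$chosen, dY, cache$B, cache$L, cache$p)
}

# --- batch normalization (per channel over batch x positions) ----------

bn_fwd <- function(X, gamma, beta, run_mean, run_var, train,
                   momentum = 0.9, eps = 1e-5) {
  n <- nrow(X)
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu * mu
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- add_row_vec(X, -mu) * rep(inv_sd, each = n)
  Y <- add_row_vec(xhat * rep(gamma, each = n), beta)
  list(out = Y, run_mean = new_mean, run_var = new_var,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma))
}

bn_bwd <- function(cache, dY) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(cache$gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- (dxhat - add_row_vec(xhat * rep(s2 / n, each = n), s1 / n)) *
    rep(cache$inv_sd, each = n)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- efficient channel attention (ECA) ---------------------------------

#' Adaptive ECA kernel size
#'
#' Kernel width for the channel-attention 1-D convolution as a function of
#' the channel count: `k` is the odd integer nearest to
#' `log2(C)/gamma + b/gamma` with `gamma = 2`, `b = 1` (the standard
#' ECA-Net rule), floored at 1.
#'
#' @param channels number of channels (>= 1).
#' @return An odd integer kernel size.
#' @export
#' @examples
#' eca_kernel_size(288)  # 5
eca_kernel_size <- function(channels) {
  abort_if(channels < 1, "channels must be >= 1")
  t <- log2(channels) / 2 + 0.5
  k <- 2L * as.integer(round((t - 1) / 2)) + 1L
  max(k, 1L)
}

eca_fwd <- function(X, B, L, w) {
  C <- ncol(X)
  k <- length(w)
  pe <- (k - 1L) %/% 2L
  grp <- rep.int(seq_len(B), rep.int(L, B))
  S <- rowsum(X, grp, reorder = FALSE) / L                 # B x C pooled
  Spad <- cbind(matrix(0, B, pe), S, matrix(0, B, pe))
  Tm <- matrix(0, B, C)
  for (o in seq_len(k)) Tm <- Tm + w[o] * Spad[, o:(o + C - 1L), drop = FALSE]
  G <- sigmoid(Tm)
  Y <- X * G[grp, , drop = FALSE]
  list(out = Y, cache = list(X = X, S = S, Spad = Spad, G = G, grp = grp,
                             L = L, k = k, pe = pe, w = w))
}

eca_bwd <- function(cache, dY) {
  G <- cache$G; grp <- cache$grp; k <- cache$k; pe <- cache$pe
  C <- ncol(G); B <- nrow(G)
  dX <- dY * G[grp, , drop = FALSE]
  dG <- rowsum(cache$X * dY, grp, reorder = FALSE)
  dT <- dG * G * (1 - G)
  dw <- numeric(k)
  dSpad <- matrix(0, B, C + 2L * pe)
  for (o in seq_len(k)) {
    cols <- o:(o + C - 1L)
    dw[o] <- sum(dT * cache$Spad[, cols, drop = FALSE])
    dSpad[, cols] <- dSpad[, cols] + cache$w[o] * dT
  }
  dS <- dSpad[, pe + seq_len(C), drop = FALSE]
  dX <- dX + dS[grp, , drop = FALSE] / cache$L
  list(dX = dX, dw = dw)
}

# --- activations / dropout --------------------------------------------

relu_fwd <- function(X) {
  Y <- X * (X > 0)
  list(out = Y, cache = X > 0)
}
relu_bwd <- function(mask, dY) dY * mask

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, cache = NULL))
  mask <- matrix((runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(out = X * mask, cache = mask)
}
dropout_bwd <- function(mask, dY) if (is.null(mask)) dY else dY * mask

# --- Adam optimizer ----------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, decay_names = character()) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
    if (weight_decay > 0 && nm %in% decay_names)
      step <- step + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, opt = opt)
}
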