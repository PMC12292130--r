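# Feature selection, spectral embedding and MNN correction.

toy_dataset <- function(X, batch = rep("b1", ncol(X)),
                        group = rep("g", ncol(X))) {
  peaks <- data.frame(chrom = "c", start = seq_len(nrow(X)) * 10 - 10,
                      end = seq_len(nrow(X)) * 10)
  cells <- tibble::tibble(cell_id = paste0("c", seq_len(ncol(X))),
                          batch = batch, group = group,
                          label = "x", is_reference = TRUE)
  atac_dataset(X, peaks, cells)
}

test_that("feature selection ranks by total count with stable ties", {
  set.seed(2)
  X <- matrix(rbinom(10 * 5, 1, 0.5), 10, 5)
  ds <- toy_dataset(X)
  sel <- select_features(ds, 3)
  counts <- rowSums(X)
  # brute-force ranking oracle
  expected <- sort(order(-counts, seq_along(counts))[1:3])
  expect_equal(sel$peaks$start, ds$peaks$start[expected])
  expect_equal(as.matrix(sel$X), as.matrix(ds$X)[expected, ])

  # saturation: keep everything
  expect_equal(dim(select_features(ds, 100)$X), dim(ds$X))

  # tie at the cutoff keeps the earlier peak
  Xt <- rbind(c(1, 1), c(1, 1), c(1, 1))
  dst <- toy_dataset(Xt)
  sel2 <- select_features(dst, 2)
  expect_equal(sel2$peaks$start, dst$peaks$start[1:2])

  # retained column sums are monotone non-increasing in rank order
  ranked <- order(-counts, seq_along(counts))[1:3]
  expect_true(all(diff(counts[ranked]) <= 0))
})

test_that("spectral embedding separates disconnected blocks", {
  # two cell blocks sharing no accessible peaks
  set.seed(1)
  X <- matrix(0, 20, 16)
  X[1:10, 1:8] <- rbinom(80, 1, 0.9)
  X[11:20, 9:16] <- rbinom(80, 1, 0.9)
  X[1, ] <- pmax(X[1, ], c(rep(1, 8), rep(0, 8)))  # no empty cells
  X[11, ] <- pmax(X[11, ], c(rep(0, 8), rep(1, 8)))
  ds <- toy_dataset(X)
  nf <- spectral_embed(ds, 3)
  v <- nf$features[, 1]
  a <- v[1:8]; b <- v[9:16]
  # a 1-D threshold separates the blocks perfectly
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("identical cells embed identically; zero cells error", {
  X <- cbind(c(1, 0, 1, 1), c(1, 0, 1, 1), c(0, 1, 0, 1))
  ds <- toy_dataset(X)
  nf <- spectral_embed(ds, 2)
  expect_equal(nf$features[1, ], nf$features[2, ], ignore_attr = TRUE)

  X0 <- cbind(c(1, 0, 1, 1), 0, c(0, 1, 0, 1))
  expect_error(spectral_embed(toy_dataset(X0), 2), "no accessible peaks")
})

test_that("spectral embedding is cell-permutation invariant up to sign", {
  sim <- small_sim()
  ds <- sim$reference
  d <- 5
  nf <- spectral_embed(ds, d)
  set.seed(4)
  perm <- sample(ncol(ds$X))
  dsp <- atac_dataset(ds$X[, perm], ds$peaks, ds$cells[perm, ])
  nfp <- spectral_embed(dsp, d)
  back <- nfp$features[order(perm), , drop = FALSE]
  for (j in seq_len(d)) {
    agree <- max(abs(back[, j] - nf$features[, j]))
    flipped <- max(abs(back[, j] + nf$features[, j]))
    expect_lt(min(agree, flipped), 1e-6)
  }
})

test_that("spectral width matches the requested dimension", {
  sim <- small_sim()
  nf <- spectral_embed(sim$reference, 32)
  expect_equal(ncol(nf$features), 32)
  expect_true(all(is.finite(nf$features)))
})

test_that("single-batch MNN is the identity", {
  set.seed(5)
  F0 <- structure(list(features = matrix(rnorm(40), 10, 4),
                       cell_ids = paste0("c", 1:10), corrected = FALSE),
                  class = "node_features")
  out <- mnn_correct(F0, rep("b1", 10))
  expect_identical(out$features, F0$features)
  expect_true(out$corrected)
})

test_that("a constant shift between copied batches is removed", {
  # batch displacement orthogonal to the biological subspace (the MNN
  # identifiability assumption): data spans dims 1-3, shift along dim 4
  set.seed(8)
  A <- cbind(matrix(rnorm(60 * 3), 60, 3), 0)
  v <- c(0, 0, 0, 2)
  B <- A + rep(v, each = 60)
  F0 <- structure(list(features = rbind(A, B),
                       cell_ids = paste0("c", 1:120), corrected = FALSE),
                  class = "node_features")
  out <- mnn_correct(F0, rep(c("ref", "qry"), each = 60), k_mnn = 5)
  d0 <- sqrt(sum((colMeans(B) - colMeans(A))^2))
  d1 <- sqrt(sum((colMeans(out$features[61:120, ]) -
                    colMeans(out$features[1:60, ]))^2))
  expect_lt(d1, 0.1 * d0)
})

test_that("correction vectors never mix grouping-factor levels", {
  set.seed(9)
  # tissue 2 of the incoming batch is shifted along an orthogonal dim;
  # tissue 1 is already aligned. Grouped correction must pull tissue 2
  # back while leaving tissue 1 untouched.
  A <- cbind(matrix(rnorm(80 * 3), 80, 3), 0)
  grpA <- rep(c("t1", "t2"), each = 40)
  B <- A
  B[grpA == "t2", 4] <- B[grpA == "t2", 4] + 3
  F0 <- structure(list(features = rbind(A, B),
                       cell_ids = paste0("c", 1:160), corrected = FALSE),
                  class = "node_features")
  out <- mnn_correct(F0, rep(c("x", "y"), each = 80), group = c(grpA, grpA),
                     k_mnn = 5)
  t2_resid <- abs(mean(out$features[121:160, 4]))
  expect_lt(t2_resid, 0.3)       # the shifted tissue is pulled back
  # partition contract: tissue 1 pairs all have zero dim-4 difference, so
  # tissue 1 cells never inherit tissue 2's correction component
  t1_dim4 <- max(abs(out$features[81:120, 4]))
  expect_lt(t1_dim4, 1e-8)
})

test_that("k_mnn larger than the smallest batch errors", {
  F0 <- structure(list(features = matrix(rnorm(24), 8, 3),
                       cell_ids = paste0("c", 1:8), corrected = FALSE),
                  class = "node_features")
  expect_error(mnn_correct(F0, rep(c("a", "b"), c(5, 3)), k_mnn = 3),
               "smaller than the smallest batch")
})
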