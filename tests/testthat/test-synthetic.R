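# Synthetic data generator: motifs, peak placement, accessibility model.

test_that("motifs respect length, distance constraint and determinism", {
  m <- generate_motifs(2, 8, seed = 1)
  expect_length(m, 2)
  expect_true(all(nchar(m) == 8))
  h <- sum(strsplit(m[1], "")[[1]] != strsplit(m[2], "")[[1]])
  expect_gte(h, 4)

  expect_length(generate_motifs(1, 4, seed = 99), 1)
  expect_identical(generate_motifs(4, 10, seed = 5),
                   generate_motifs(4, 10, seed = 5))
})

test_that("generated peaks fit in the contig and do not overlap", {
  sim <- small_sim()
  pk <- sim$reference$peaks
  expect_true(all(pk$start >= 0))
  expect_true(all(pk$end <= nchar(sim$genome[pk$chrom])))
  o <- order(pk$start)
  expect_true(all(pk$end[o][-nrow(pk)] <= pk$start[o][-1]))
})

test_that("explicit too-short contig errors with the required length", {
  cfg <- synthetic_config(n_cell_types = 2, n_cells_ref = 10,
                          n_cells_query = 5, n_peaks = 50,
                          contig_length = 1000, seed = 1)
  expect_error(generate_dataset(cfg), "need at least")
})

test_that("marker peaks are enriched in their own type", {
  sim <- small_sim()
  ref <- sim$reference
  prog <- sim$peak_program
  X <- as.matrix(ref$X)
  for (t in 1:3) {
    own <- mean(X[prog == t, ref$cells$label == paste0("type", t)])
    other <- mean(X[prog == t, ref$cells$label != paste0("type", t)])
    expect_gt(own, other)
  }
})

test_that("empirical marker accessibility matches p_open_marker within 3 sigma", {
  cfg <- synthetic_config(n_cell_types = 3, n_cells_ref = 150,
                          n_cells_query = 60, n_peaks = 300,
                          peak_width = 200, motif_length = 8,
                          batch_shift = 0, seed = 21)
  sim <- generate_dataset(cfg)
  prog <- sim$peak_program
  X <- as.matrix(sim$reference$X)
  lab <- sim$reference$cells$label
  for (t in 1:3) {
    block <- X[prog == t, lab == paste0("type", t)]
    n <- length(block)
    sigma <- sqrt(cfg$p_open_marker * (1 - cfg$p_open_marker) / n)
    expect_lt(abs(mean(block) - cfg$p_open_marker), 3 * sigma)
  }
})

test_that("batch_shift = 0 gives identical per-type means across ref/query", {
  cfg <- synthetic_config(n_cell_types = 2, n_cells_ref = 40,
                          n_cells_query = 40, n_peaks = 60,
                          peak_width = 100, motif_length = 8,
                          batch_shift = 0, seed = 3)
  sim <- generate_dataset(cfg)
  # with no batch effect the generating probabilities are identical, so
  # empirical means agree within binomial noise
  prog <- sim$peak_program
  Xr <- as.matrix(sim$reference$X)
  Xq <- as.matrix(sim$query$X)
  own_r <- mean(Xr[prog == 1, sim$reference$cells$label == "type1"])
  own_q <- mean(Xq[prog == 1, sim$query_labels == "type1"])
  expect_lt(abs(own_r - own_q), 0.1)
})

test_that("generation is deterministic under a fixed seed", {
  a <- small_sim(seed = 42)
  b <- small_sim(seed = 42)
  expect_identical(as.matrix(a$reference$X), as.matrix(b$reference$X))
  expect_identical(a$genome, b$genome)
  expect_identical(a$motifs, b$motifs)
  c <- small_sim(seed = 43)
  expect_false(identical(as.matrix(a$reference$X), as.matrix(c$reference$X)))
})

test_that("reference and query live in disjoint batches", {
  sim <- small_sim()
  expect_length(intersect(unique(sim$reference$cells$batch),
                          unique(sim$query$cells$batch)), 0)
})

test_that("planted motifs occur in program peaks and rarely elsewhere", {
  sim <- small_sim()
  seqs <- extract_peak_sequences(sim$reference$peaks, sim$genome, 200)
  prog <- sim$peak_program
  for (t in 1:3) {
    hit <- vapply(seqs[prog == t], grepl, TRUE,
                  pattern = sim$motifs[t], fixed = TRUE)
    expect_true(all(hit))
  }
  bg_hits <- vapply(seqs[prog == 0], function(s)
    any(vapply(sim$motifs, grepl, TRUE, x = s, fixed = TRUE)), TRUE)
  expect_lt(mean(bg_hits), 0.2)
})

test_that("simulated bundles serialize and re-read exactly", {
  sim <- small_sim()
  d <- withr::local_tempdir()
  write_dataset(sim$query, d)
  fa <- file.path(d, "genome.fa")
  write_genome_fasta(sim$genome, fa)
  expect_identical(read_genome_fasta(fa), sim$genome)
  back <- read_dataset(file.path(d, "matrix.mtx"),
                       file.path(d, "peaks.bed"), file.path(d, "cells.tsv"))
  expect_equal(as.matrix(back$X), as.matrix(sim$query$X))
})
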