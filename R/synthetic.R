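# Synthetic scATAC-seq generator: a random contig with motif-planted peaks,
# cell-type-specific accessible peak programs, Bernoulli sampling with a
# background (dropout-like) rate, and an additive per-batch probability shift.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the standard fixture: 5 cell types across 2 batches
#' (reference and query), 1000 reference + 500 query cells, 2000 peaks of
#' 500 bp carrying 10-bp type motifs, marker peaks open with probability
#' 0.8 against a 0.1 background, and a +/-0.1 accessibility shift on 10%
#' of peaks per batch.
#'
#' @param n_cell_types number of cell types (each with its own motif and
#'   marker-peak program).
#' @param n_cells_ref,n_cells_query number of reference / query cells.
#' @param n_peaks total number of peaks.
#' @param n_batches number of batches; reference and query cells are always
#'   assigned to disjoint batch sets.
#' @param peak_width peak width in bp.
#' @param motif_length motif length in bp.
#' @param p_open_marker probability that a marker peak is accessible in a
#'   cell of its own type.
#' @param p_open_background accessibility probability everywhere else.
#' @param batch_shift magnitude of the per-batch accessibility probability
#'   perturbation (applied with random sign to a fixed 10% subset of peaks,
#'   identically for all cells of the batch; clamped to `[0, 1]`).
#' @param contig_length length of the synthetic contig, or `NULL` to size it
#'   automatically so all peaks fit without overlapping.
#' @param seed integer seed; the whole generation is a deterministic
#'   function of the configuration.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cell_types = 5, n_cells_ref = 1000,
                             n_cells_query = 500, n_peaks = 2000,
                             n_batches = 2, peak_width = 500,
                             motif_length = 10, p_open_marker = 0.8,
                             p_open_background = 0.1, batch_shift = 0.1,
                             contig_length = NULL, seed = 1) {
  cfg <- as.list(environment())
  for (nm in c("n_cell_types", "n_cells_ref", "n_cells_query", "n_peaks",
               "n_batches", "peak_width", "motif_length", "contig_length",
               "seed"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.integer(cfg[[nm]])
  abort_if(p_open_background < 0 || p_open_marker > 1 ||
             p_open_background >= p_open_marker,
           "need 0 <= p_open_background < p_open_marker <= 1")
  abort_if(n_peaks < n_cell_types, "n_peaks must be >= n_cell_types")
  abort_if(motif_length < 4, "motif_length must be >= 4")
  abort_if(motif_length > peak_width, "motif must fit inside a peak")
  abort_if(n_batches < 2, "need >= 2 batches (reference and query are disjoint)")
  structure(cfg, class = "synthetic_config")
}

#' Generate distinct cell-type motifs
#'
#' Draws `n_cell_types` fixed nucleotide strings with pairwise Hamming
#' distance at least `motif_length / 2`, resampling conflicting candidates
#' up to a bounded number of times.
#'
#' @param n_cell_types number of motifs.
#' @param motif_length motif length (>= 4).
#' @param seed integer seed.
#' @return Character vector of `n_cell_types` motifs.
#' @export
generate_motifs <- function(n_cell_types, motif_length, seed = 1) {
  abort_if(motif_length < 4, "motif_length must be >= 4")
  bases <- c("A", "C", "G", "T")
  min_dist <- motif_length / 2
  hamming <- function(a, b) sum(a != b)
  with_seed(seed, {
    motifs <- list()
    for (i in seq_len(n_cell_types)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        cand <- sample(bases, motif_length, replace = TRUE)
        if (all(vapply(motifs, function(m) hamming(m, cand) >= min_dist,
                       logical(1)))) {
          motifs[[i]] <- cand
          ok <- TRUE
          break
        }
      }
      abort_if(!ok, "could not satisfy the motif distance constraint after ",
               "1000 resampling attempts (motif ", i, " of ", n_cell_types, ")")
    }
    vapply(motifs, paste, character(1), collapse = "")
  })
}

#' Generate a synthetic annotated dataset
#'
#' Builds one synthetic contig holding `n_peaks` non-overlapping peaks of
#' `peak_width` bp. Peaks are assigned round-robin over the cell-type
#' programs plus a background slot; each program peak carries its type's
#' motif planted at a random offset. Cell `c` of type `t` opens peak `p`
#' with probability `p_open_marker` when `p` belongs to program `t` and
#' `p_open_background` otherwise; per batch, a fixed random 10% of peaks
#' has its probability shifted by `+/-batch_shift` (random sign per peak,
#' identical for all cells of the batch, clamped to `[0,1]`). Reference and
#' query cells come from the same generative process but live in disjoint
#' batches.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `genome` (named character vector),
#'   `reference` and `query` ([atac_dataset]s; query labels withheld),
#'   `query_labels` (character), `motifs`, `peak_program` (integer, 0 =
#'   background) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  gap <- 100L
  margin <- 200L
  need <- cfg$n_peaks * (cfg$peak_width + gap) + 2L * margin
  contig_length <- cfg$contig_length %||% need
  abort_if(contig_length < need,
           "contig too short for ", cfg$n_peaks, " non-overlapping peaks of ",
           cfg$peak_width, " bp; need at least ", need, " bp")

  with_seed(cfg$seed, {
    motifs <- generate_motifs(cfg$n_cell_types, cfg$motif_length,
                              seed = sample.int(2^31 - 1, 1))
    motif_chars <- strsplit(motifs, "")
    # build the contig as a base vector so motif planting is O(motif_length)
    contig_vec <- sample(c("A", "C", "G", "T"), contig_length, replace = TRUE)

    starts <- margin + (seq_len(cfg$n_peaks) - 1L) * (cfg$peak_width + gap)
    ends <- starts + cfg$peak_width
    # program 0 = background, 1..T = cell-type programs, round-robin
    program <- (seq_len(cfg$n_peaks) - 1L) %% (cfg$n_cell_types + 1L)

    for (p in which(program > 0L)) {
      off <- sample.int(cfg$peak_width - cfg$motif_length + 1L, 1) - 1L
      at <- starts[p] + off + seq_len(cfg$motif_length)
      contig_vec[at] <- motif_chars[[program[p]]]
    }
    contig <- paste(contig_vec, collapse = "")

    n_ref <- cfg$n_cells_ref
    n_qry <- cfg$n_cells_query
    n_all <- n_ref + n_qry
    types <- c(rep_len(seq_len(cfg$n_cell_types), n_ref),
               rep_len(seq_len(cfg$n_cell_types), n_qry))
    type_names <- paste0("type", seq_len(cfg$n_cell_types))

    ref_batches <- paste0("batch", seq_len(ceiling(cfg$n_batches / 2)))
    qry_batches <- paste0("batch",
                          seq(ceiling(cfg$n_batches / 2) + 1, cfg$n_batches))
    batch <- c(rep_len(ref_batches, n_ref), rep_len(qry_batches, n_qry))

    # per-batch fixed probability perturbation on a random 10% of peaks
    n_shift <- max(1L, round(0.10 * cfg$n_peaks))
    shift_vec <- matrix(0, cfg$n_peaks, cfg$n_batches,
                        dimnames = list(NULL, paste0("batch",
                                                     seq_len(cfg$n_batches))))
    for (b in seq_len(cfg$n_batches)) {
      idx <- sample.int(cfg$n_peaks, n_shift)
      shift_vec[idx, b] <- sample(c(-1, 1), n_shift, replace = TRUE) *
        cfg$batch_shift
    }

    prob <- matrix(cfg$p_open_background, cfg$n_peaks, n_all)
    for (t in seq_len(cfg$n_cell_types)) {
      marker <- program == t
      prob[marker, types == t] <- cfg$p_open_marker
    }
    prob <- prob + shift_vec[, match(batch, colnames(shift_vec))]
    prob <- pmin(pmax(prob, 0), 1)

    X <- matrix(rbinom(length(prob), 1L, prob), nrow = cfg$n_peaks)

    peaks <- data.frame(chrom = "chrS", start = starts, end = ends)
    cell_id <- c(sprintf("ref_%04d", seq_len(n_ref)),
                 sprintf("qry_%04d", seq_len(n_qry)))
    labels <- type_names[types]
    cells <- tibble::tibble(
      cell_id = cell_id, batch = batch, group = "tissue1",
      label = c(labels[seq_len(n_ref)], rep(NA_character_, n_qry)),
      is_reference = rep(c(TRUE, FALSE), c(n_ref, n_qry)))

    is_ref <- cells$is_reference
    reference <- atac_dataset(X[, is_ref, drop = FALSE], peaks,
                              cells[is_ref, ])
    query <- atac_dataset(X[, !is_ref, drop = FALSE], peaks, cells[!is_ref, ])

    list(genome = c(chrS = contig), reference = reference, query = query,
         query_labels = labels[!is_ref], motifs = motifs,
         peak_program = program, config = cfg)
  })
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output path (`.gz` suffix triggers compression).
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
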