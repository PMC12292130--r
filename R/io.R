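# Readers/writers for the on-disk bundle (FASTA + MTX + BED3 + cell TSV)
# and the in-memory dataset container.

#' Read a genome FASTA file
#'
#' Reads a (possibly gzip-compressed) FASTA file into a named character
#' vector of uppercase sequences. Bases outside `A/C/G/T` are mapped to `N`.
#'
#' @param path path to a FASTA file (`.fa`, `.fasta`, optionally `.gz`).
#' @return Named character vector, one element per contig.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' read_genome_fasta(fa)
read_genome_fasta <- function(path) {
  abort_if(!file.exists(path), "FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  abort_if(length(seqs) == 0L, "FASTA file contains no records: ", path)
  abort_if(any(Biostrings::width(seqs) == 0L), "FASTA contains an empty record")
  nm <- sub("\\s.*$", "", names(seqs))
  abort_if(anyDuplicated(nm) > 0L,
           "duplicate contig name(s) in FASTA: ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  out <- gsub("[^ACGT]", "N", out)
  names(out) <- nm
  out
}

#' Assemble a peak-by-cell accessibility dataset
#'
#' Container for a binary peak-by-cell matrix with peak coordinates and
#' per-cell covariates. Any positive count is binarized to 1 on construction.
#'
#' @param X sparse (or dense) peaks-by-cells matrix of counts or 0/1 entries.
#' @param peaks data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open intervals), one row per matrix row.
#' @param cells data frame with columns `cell_id`, `batch`, `group`,
#'   `label` (`NA` allowed for query cells) and `is_reference` (logical),
#'   one row per matrix column.
#' @return An object of class `atac_dataset`.
#' @export
atac_dataset <- function(X, peaks, cells) {
  X <- as(as(Matrix::Matrix(X, sparse = TRUE), "dMatrix"), "CsparseMatrix")
  X@x[] <- as.numeric(X@x > 0)            # binarize: any positive count -> 1
  X <- Matrix::drop0(X)
  peaks <- as.data.frame(peaks)
  abort_if(!all(c("chrom", "start", "end") %in% names(peaks)),
           "peaks must have columns chrom, start, end")
  cells <- tibble::as_tibble(cells)
  abort_if(!all(c("cell_id", "batch", "group", "label", "is_reference") %in%
                  names(cells)),
           "cells must have columns cell_id, batch, group, label, is_reference")
  abort_if(nrow(peaks) != nrow(X), "peak table rows must match matrix rows")
  abort_if(nrow(cells) != ncol(X), "cell table rows must match matrix columns")
  abort_if(any(peaks$start < 0), "peak start coordinates must be >= 0")
  bad <- which(peaks$end <= peaks$start)
  abort_if(length(bad) > 0L,
           "malformed peak interval(s) with end <= start at row(s): ",
           paste(head(bad, 5), collapse = ", "))
  cells$label <- as.character(cells$label)
  cells$label[!is.na(cells$label) & cells$label == ""] <- NA_character_
  cells$is_reference <- as.logical(cells$is_reference)
  unl <- cells$is_reference & is.na(cells$label)
  abort_if(any(unl), "reference cell(s) without a label: ",
           paste(head(cells$cell_id[unl], 5), collapse = ", "))
  structure(list(X = X, peaks = peaks, cells = cells), class = "atac_dataset")
}

#' @export
print.atac_dataset <- function(x, ...) {
  cat(sprintf("<atac_dataset> %d peaks x %d cells (%.2f%% nonzero)\n",
              nrow(x$X), ncol(x$X),
              100 * Matrix::nnzero(x$X) / prod(dim(x$X))))
  cat(sprintf("  reference: %d  query: %d  batches: %d  groups: %d\n",
              sum(x$cells$is_reference), sum(!x$cells$is_reference),
              length(unique(x$cells$batch)), length(unique(x$cells$group))))
  invisible(x)
}

#' @export
dim.atac_dataset <- function(x) dim(x$X)

#' Read a dataset bundle (MTX + BED + cell TSV)
#'
#' @param mtx path to a MatrixMarket file, peaks as rows and cells as columns.
#' @param peaks_bed path to a BED3 file of peak intervals (0-based half-open).
#' @param cells_tsv path to a tab-separated file with header columns
#'   `cell_id`, `batch`, `group`, `label`, `is_reference`. `label` may be
#'   empty for query cells.
#' @return An [atac_dataset]; counts are binarized on load.
#' @export
read_dataset <- function(mtx, peaks_bed, cells_tsv) {
  for (p in c(mtx, peaks_bed, cells_tsv))
    abort_if(!file.exists(p), "file not found: ", p)
  X <- Matrix::readMM(mtx)
  peaks <- read.table(peaks_bed, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end"),
                      colClasses = c("character", "integer", "integer"))
  cells <- read.table(cells_tsv, sep = "\t", header = TRUE,
                      colClasses = "character", na.strings = c("NA", ""))
  abort_if(nrow(peaks) != nrow(X),
           "MTX has ", nrow(X), " rows but BED has ", nrow(peaks), " peaks")
  abort_if(nrow(cells) != ncol(X),
           "MTX has ", ncol(X), " columns but cell TSV has ", nrow(cells),
           " cells")
  cells$is_reference <- tolower(cells$is_reference) %in% c("true", "t", "1")
  atac_dataset(X, peaks, cells)
}

#' Write a dataset bundle to a directory
#'
#' Emits `matrix.mtx`, `peaks.bed` and `cells.tsv` in the formats
#' [read_dataset()] consumes; writing then reading round-trips exactly.
#'
#' @param ds an [atac_dataset].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "atac_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "peaks.bed", "cells.tsv"))
  Matrix::writeMM(ds$X, paths[1])
  peaks <- ds$peaks
  peaks$start <- as.integer(peaks$start)   # never scientific notation
  peaks$end <- as.integer(peaks$end)
  write.table(peaks, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cells <- ds$cells
  cells$is_reference <- ifelse(cells$is_reference, "true", "false")
  write.table(cells, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "")
  invisible(paths)
}

#' Merge a reference and a query dataset sharing one peak set
#'
#' Columns are concatenated (reference first); `is_reference` flags are
#' preserved and duplicate cell ids are disambiguated by suffixing.
#'
#' @param ref,query [atac_dataset] objects over the identical peak set
#'   (same contigs, starts and ends, in the same order).
#' @return The merged [atac_dataset].
#' @export
merge_reference_query <- function(ref, query) {
  stopifnot(inherits(ref, "atac_dataset"), inherits(query, "atac_dataset"))
  same <- nrow(ref$peaks) == nrow(query$peaks) &&
    identical(ref$peaks$chrom, query$peaks$chrom) &&
    identical(as.integer(ref$peaks$start), as.integer(query$peaks$start)) &&
    identical(as.integer(ref$peaks$end), as.integer(query$peaks$end))
  abort_if(!same, paste0(
    "reference and query peak sets differ; harmonize the peak sets upstream ",
    "(both datasets must be quantified over the same peaks, in the same order)"))
  cells <- rbind(ref$cells, query$cells)
  dup <- duplicated(cells$cell_id)
  if (any(dup))
    cells$cell_id[dup] <- paste0(cells$cell_id[dup], "_1")
  atac_dataset(cbind(ref$X, query$X), ref$peaks, cells)
}

#' Write per-cell annotation predictions to TSV
#'
#' One row per query cell in input order, with columns `cell_id`,
#' `predicted_label` and one `logprob_<class>` column per reference class.
#'
#' @param result an [annotation_result] (see [predict_gat()]).
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(result, path) {
  stopifnot(inherits(result, "annotation_result"))
  lp <- result$log_prob
  df <- data.frame(cell_id = result$cell_id,
                   predicted_label = result$predicted_label,
                   check.names = FALSE, stringsAsFactors = FALSE)
  lpdf <- as.data.frame(lp)
  names(lpdf) <- paste0("logprob_", colnames(lp))
  df <- cbind(df, lpdf)
  # fixed significant-digit formatting keeps reruns byte-identical
  for (j in seq(3, ncol(df)))
    df[[j]] <- sprintf("%.8g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
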