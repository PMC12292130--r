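# Peak window extraction and one-hot encoding of DNA for the sequence model.

#' One-hot encode a nucleotide sequence
#'
#' Encodes `A/C/G/T` as indicator rows in column order (A, C, G, T); `N`
#' encodes as an all-zero row. Sequences longer than `window_length` are
#' center-cropped; shorter ones are symmetrically padded with `N` (extra
#' base of padding on the right when the deficit is odd).
#'
#' @param sequence a single string over `A/C/G/T/N`.
#' @param window_length output length in bp.
#' @return A `window_length x 4` binary matrix with columns `A, C, G, T`.
#' @export
#' @examples
#' one_hot_encode("A", 1)
#' one_hot_encode("ACGT", 6)  # rows 1 and 6 are zero padding
one_hot_encode <- function(sequence, window_length) {
  abort_if(!is.character(sequence) || length(sequence) != 1L ||
             nchar(sequence) == 0L, "sequence must be one non-empty string")
  codes <- encode_windows(sequence, window_length)[1, ]
  oh <- matrix(0, window_length, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  known <- codes > 0L
  oh[cbind(which(known), codes[known])] <- 1
  oh
}

# Integer codes (A=1,C=2,G=3,T=4,N=0) for several sequences, center-cropped /
# N-padded to a common window. Returns an n x window integer matrix.
encode_windows <- function(sequences, window_length) {
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  n <- length(sequences)
  out <- matrix(0L, n, window_length)
  for (i in seq_len(n)) {
    s <- sequences[i]
    L <- nchar(s)
    if (L > window_length) {
      from <- (L - window_length) %/% 2 + 1L
      s <- substr(s, from, from + window_length - 1L)
      L <- window_length
    }
    codes <- lut[utf8ToInt(s)]
    left <- (window_length - L) %/% 2
    out[i, left + seq_len(L)] <- codes
  }
  out
}

#' Extract fixed-width genomic windows centered on peaks
#'
#' Each window is centered on the peak midpoint `floor((start + end) / 2)`
#' (0-based half-open coordinates): the window spans
#' `[mid - floor(w/2), mid - floor(w/2) + w)`. Overhang beyond the contig
#' is filled with `N`.
#'
#' @param peaks data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genome named character vector of contig sequences.
#' @param window_length window width in bp.
#' @return Character vector of `window_length`-bp sequences, in peak order.
#' @export
extract_peak_sequences <- function(peaks, genome, window_length) {
  peaks <- as.data.frame(peaks)
  missing <- setdiff(unique(peaks$chrom), names(genome))
  abort_if(length(missing) > 0L,
           "contig(s) absent from genome: ", paste(missing, collapse = ", "))
  w <- as.integer(window_length)
  mid <- (peaks$start + peaks$end) %/% 2L
  ws <- mid - w %/% 2L                      # 0-based inclusive window start
  we <- ws + w                              # 0-based exclusive end
  clen <- nchar(genome)[match(peaks$chrom, names(genome))]
  left_pad <- pmax(0L, -ws)
  right_pad <- pmax(0L, we - clen)
  core <- substring(genome[match(peaks$chrom, names(genome))],
                    ws + left_pad + 1L, we - right_pad)
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}
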