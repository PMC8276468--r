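#' Tetranucleotide (k-mer) frequency vector of a genome
#'
#' Counts every k-mer window on the given sequence(s) and on their reverse
#' complements (both-strand counting symmetrises the signature), skipping
#' windows that contain non-ACGT letters. Multi-sequence genomes aggregate
#' counts across sequences before normalising, so a MAG's signature is
#' computed over its concatenated contigs.
#'
#' @param x A character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a `genome_id`/`sequence` data frame; all
#'   sequences are treated as one genome.
#' @param k Word size (default 4: tetranucleotides, 256 components).
#' @param id Optional sequence/genome id stored on the result.
#' @return A named numeric vector of length `4^k` summing to 1, of class
#'   `kmer_vector`, with attributes `k`, `kmer_total` (number of counted
#'   windows), and `sequence_id`.
#' @export
#' @examples
#' v <- kmer_freq_vector("AAAATTTT")
#' v[c("AAAA", "TTTT")]
kmer_freq_vector <- function(x, k = 4, id = NULL) {
  check_number(k, "k", min = 1, integer = TRUE)
  seqs <- if (is.character(x) && is.null(names(x))) x else as_seq_tbl(x)$sequence
  if (any(nchar(seqs) < k)) {
    abort(sprintf("sequence shorter than k = %d", k))
  }
  dss <- Biostrings::DNAStringSet(seqs)
  counts <- colSums(Biostrings::oligonucleotideFrequency(dss, width = k)) +
    colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(dss), width = k))
  total <- sum(counts)
  if (total == 0) {
    abort("no countable k-mer windows (all windows contain ambiguous bases)")
  }
  structure(counts / total, k = as.integer(k), kmer_total = total,
            sequence_id = id, class = "kmer_vector")
}

#' Mean absolute error between two composition vectors
#'
#' `d = mean(|v1 - v2|)` over all `4^k` components; symmetric, zero iff the
#' vectors are equal, and bounded above by `2 / 4^k` for frequency vectors.
#' Virus-host composition links are accepted when `d` falls below a fixed
#' threshold (default 0.0015 in [assign_by_composition()]).
#'
#' @param v1,v2 `kmer_vector`s (or plain numeric vectors of equal length).
#' @return The distance `d`.
#' @export
mae_distance <- function(v1, v2) {
  k1 <- attr(v1, "k")
  k2 <- attr(v2, "k")
  if (!is.null(k1) && !is.null(k2) && k1 != k2) {
    abort(sprintf("k mismatch: %d vs %d", k1, k2))
  }
  if (length(v1) != length(v2)) {
    abort(sprintf("dimension mismatch: %d vs %d", length(v1), length(v2)))
  }
  mean(abs(as.numeric(v1) - as.numeric(v2)))
}
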