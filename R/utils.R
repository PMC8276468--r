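#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map_lgl imap pmap keep
#' @importFrom stats rgamma runif rmultinom setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Coerce sequence input to a two-column tibble
#'
#' Accepts a named character vector, a [Biostrings::DNAStringSet], or a data
#' frame with `genome_id`/`sequence` (or `id`/`sequence`) columns. Multiple
#' rows may share one `genome_id` (multi-contig genomes); downstream
#' composition code aggregates them before normalising.
#'
#' @param x Sequences in any of the accepted forms.
#' @param arg Name used in error messages.
#' @return A tibble with columns `genome_id` and `sequence`.
#' @keywords internal
as_seq_tbl <- function(x, arg = "x") {
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (is.character(x)) {
    if (length(x) == 0L) {
      return(tibble(genome_id = character(), sequence = character()))
    }
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      abort(sprintf("`%s` must be a *named* character vector of sequences", arg))
    }
    return(tibble(genome_id = names(x), sequence = unname(x)))
  }
  if (is.data.frame(x)) {
    id_col <- intersect(c("genome_id", "id", "contig_id", "virus_id"), names(x))[1]
    if (is.na(id_col) || !"sequence" %in% names(x)) {
      abort(sprintf(
        "`%s` must have an id column (genome_id/id/contig_id) and a `sequence` column", arg
      ))
    }
    return(tibble(genome_id = as.character(x[[id_col]]), sequence = x[["sequence"]]))
  }
  abort(sprintf("`%s` must be a named character vector, DNAStringSet, or data frame", arg))
}

#' Convert a sequence tibble to a DNAStringSet
#' @keywords internal
seq_tbl_to_dss <- function(tbl) {
  Biostrings::DNAStringSet(setNames(tbl$sequence, tbl$genome_id))
}

#' Write a sequence tibble as FASTA
#'
#' @param seqs Sequences in any form accepted by the package (named character
#'   vector, `DNAStringSet`, or `genome_id`/`sequence` data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_seq_fasta <- function(seqs, path) {
  tbl <- as_seq_tbl(seqs, "seqs")
  Biostrings::writeXStringSet(seq_tbl_to_dss(tbl), filepath = path, width = 80L)
  invisible(path)
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path FASTA file path.
#' @return A tibble with `genome_id` and `sequence` columns.
#' @export
read_seq_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  tibble(genome_id = names(dss), sequence = unname(as.character(dss)))
}

# Deterministic per-stage sub-seed so each generator is reproducible both
# standalone and inside the bundled run. Kept below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(
    hosts = 1L, prophages = 2L, crispr = 3L, annotations = 4L,
    reads = 5L, qc = 6L, viral_ann = 7L, abundance = 8L
  )
  off <- offsets[[stage]]
  as.integer((as.double(seed) + off * 1000003) %% 2147483647)
}

check_number <- function(x, field, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("field `%s` must be a single number", field))
  }
  if (integer && x != as.integer(x)) {
    abort(sprintf("field `%s` must be an integer", field))
  }
  if (x < min || x > max) {
    abort(sprintf("field `%s` must be in [%s, %s], got %s", field, min, max, x))
  }
  invisible(x)
}

reverse_complement_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
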