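# Independent brute-force oracles, deliberately kept free of the package's
# implementation paths (no Biostrings): plain string scans and counters.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_all_kmers <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                  stringsAsFactors = FALSE)))
}

# counts every k-length window on one strand, skipping windows with non-ACGT
oracle_kmer_counts_one_strand <- function(s, k) {
  n <- nchar(s)
  counts <- setNames(integer(4^k), oracle_all_kmers(k))
  if (n < k) return(counts)
  words <- substring(s, 1:(n - k + 1), k:n)
  words <- words[!grepl("[^ACGT]", words)]
  tab <- table(words)
  counts[names(tab)] <- as.integer(tab)
  counts
}

# both-strand frequency vector over one or more sequences of one genome
oracle_kmer_vector <- function(seqs, k = 4) {
  counts <- setNames(integer(4^k), oracle_all_kmers(k))
  for (s in seqs) {
    counts <- counts + oracle_kmer_counts_one_strand(s, k) +
      oracle_kmer_counts_one_strand(oracle_revcomp(s), k)
  }
  counts / sum(counts)
}

oracle_mae <- function(a, b) sum(abs(as.numeric(a) - as.numeric(b))) / length(a)

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# all-positions, both-strand full-length spacer scan; returns the minimal
# mismatch count (Inf when the spacer is longer than the target)
oracle_spacer_scan <- function(spacer, target) {
  L <- nchar(spacer)
  n <- nchar(target)
  if (L > n) return(Inf)
  best <- Inf
  for (pat in c(spacer, oracle_revcomp(spacer))) {
    for (i in 1:(n - L + 1)) {
      best <- min(best, oracle_hamming(pat, substr(target, i, i + L - 1)))
    }
  }
  best
}

# one-pass naive relative-abundance counter over rank-prefixed lineages
oracle_abundance <- function(lineages, rank) {
  prefix <- c(superkingdom = "sk", phylum = "p", class = "c", order = "o",
              family = "f", genus = "g", species = "s")[[rank]]
  assigned <- 0L
  counts <- list()
  for (lin in lineages) {
    if (is.na(lin) || lin == "" || lin == "unclassified") next
    assigned <- assigned + 1L
    for (f in strsplit(lin, ";", fixed = TRUE)[[1]]) {
      if (startsWith(f, paste0(prefix, "__"))) {
        taxon <- sub("^[^_]*__", "", f)
        counts[[taxon]] <- (counts[[taxon]] %||% 0L) + 1L
      }
    }
  }
  list(counts = counts, denominator = assigned)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
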