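#' Assign viral contigs to hosts by tetranucleotide composition
#'
#' Computes both-strand k-mer frequency vectors for every viral contig and
#' every host genome (aggregating multi-contig hosts), and assigns each
#' eligible virus to the single host with the lowest mean absolute error
#' `d`, accepted only when `d < d_max` (strict, default 0.0015). Viruses
#' shorter than `min_virus_len` are skipped (short contigs have unstable
#' signatures). Exact ties on the minimal `d` resolve to the
#' lexicographically smallest host id and are flagged.
#'
#' @param viral_contigs,host_genomes Sequences in any form accepted by
#'   [kmer_freq_vector()]; host rows sharing a `genome_id` are aggregated
#'   into one genome.
#' @param d_max Strict upper bound on the accepted distance.
#' @param min_virus_len Minimum viral contig length in bp (default 5000; set
#'   0 to disable).
#' @param k Word size (default 4).
#' @return A tibble of composition association edges: `virus_id`, `host_id`,
#'   `signal = "composition"`, `distance`, `tied`.
#' @export
assign_by_composition <- function(viral_contigs, host_genomes,
                                  d_max = 0.0015, min_virus_len = 5000,
                                  k = 4) {
  check_number(d_max, "d_max", min = 1e-12)
  vir <- as_seq_tbl(viral_contigs, "viral_contigs")
  hos <- as_seq_tbl(host_genomes, "host_genomes")
  if (nrow(hos) == 0L) abort("host set is empty")
  host_split <- split(hos$sequence, hos$genome_id)
  hvec <- imap(host_split, function(s, id) kmer_freq_vector(s, k = k, id = id))
  hids <- sort(names(hvec))
  edges <- list()
  for (i in seq_len(nrow(vir))) {
    if (nchar(vir$sequence[i]) < max(min_virus_len, k)) next
    vv <- kmer_freq_vector(vir$sequence[i], k = k, id = vir$genome_id[i])
    d <- map_dbl(hvec[hids], mae_distance, v2 = vv)
    dmin <- min(d)
    if (dmin < d_max) {
      best <- hids[d == dmin]
      edges[[length(edges) + 1L]] <- tibble(
        virus_id = vir$genome_id[i], host_id = best[1],
        signal = "composition", distance = dmin, tied = length(best) > 1L
      )
    }
  }
  if (length(edges) == 0L) {
    return(tibble(virus_id = character(), host_id = character(),
                  signal = character(), distance = double(), tied = logical()))
  }
  bind_rows(edges)
}

#' Detect CRISPR repeat-spacer arrays (minimal detector)
#'
#' Finds arrays of at least `min_repeats` exact copies of a repeat (length
#' 23-50 bp by default) separated by unique spacer segments of 20-60 bp, and
#' returns the inter-repeat segments as spacers. Longer repeat lengths take
#' precedence; arrays overlapping an already-reported array at a longer
#' repeat length are suppressed. This is a deliberately minimal stand-in for
#' a dedicated CRISPR detector, sufficient for well-formed arrays.
#'
#' @param host_sequences Sequences in any accepted form.
#' @param repeat_length_range,spacer_length_range Inclusive bp ranges.
#' @param min_repeats Minimum exact repeat copies per array (default 3).
#' @return A tibble of spacers: `host_id`, `array_id`, `repeat_seq`,
#'   `spacer_id`, `spacer_seq`, `start`, `end` (0-based half-open on the
#'   host sequence). Empty when no arrays are found.
#' @export
detect_spacers <- function(host_sequences,
                           repeat_length_range = c(23L, 50L),
                           spacer_length_range = c(20L, 60L),
                           min_repeats = 3L) {
  hosts <- as_seq_tbl(host_sequences, "host_sequences")
  out <- list()
  for (h in seq_len(nrow(hosts))) {
    hseq <- hosts$sequence[h]
    n <- nchar(hseq)
    covered <- logical(n)
    n_array <- 0L
    # seed at the minimum repeat length: any longer exact repeat begins with
    # a duplicated seed-length word, so only seed-duplicated positions need
    # to be examined at longer lengths
    L0 <- repeat_length_range[1]
    if (n < L0) next
    seed_starts <- seq_len(n - L0 + 1L)
    seed_words <- substring(hseq, seed_starts, seed_starts + L0 - 1L)
    seed_dup <- seed_starts[seed_words %in% seed_words[duplicated(seed_words)]]
    if (length(seed_dup) == 0L) next
    # longer repeat lengths first, so a 28 bp array is not re-reported at
    # every shorter repeat prefix
    for (L in seq(repeat_length_range[2], repeat_length_range[1])) {
      if (n < min_repeats * L + (min_repeats - 1L) * spacer_length_range[1]) next
      starts <- seed_dup[seed_dup <= n - L + 1L]
      if (length(starts) < min_repeats) next
      words <- substring(hseq, starts, starts + L - 1L)
      dup_vals <- unique(words[duplicated(words)])
      if (length(dup_vals) == 0L) next
      in_dup <- words %in% dup_vals
      pos_by_word <- split(starts[in_dup], words[in_dup])
      for (w in names(pos_by_word)) {
        pos <- sort(pos_by_word[[w]])
        if (length(pos) < min_repeats) next
        # partition occurrences into runs whose inter-repeat gaps are legal
        # spacer lengths; each qualifying run is a candidate array
        runs <- list()
        run <- pos[1]
        for (p in pos[-1]) {
          gap <- p - (run[length(run)] + L)
          if (gap >= spacer_length_range[1] && gap <= spacer_length_range[2]) {
            run <- c(run, p)
          } else if (p >= run[length(run)] + L) {
            runs[[length(runs) + 1L]] <- run
            run <- p
          }
        }
        runs[[length(runs) + 1L]] <- run
        for (run in runs) {
          if (length(run) < min_repeats) next
          span <- run[1]:(run[length(run)] + L - 1L)
          if (any(covered[span])) next
          spacer_start <- run[-length(run)] + L
          spacer_end <- run[-1] - 1L
          spacers <- substring(hseq, spacer_start, spacer_end)
          if (anyDuplicated(spacers)) next
          n_array <- n_array + 1L
          covered[span] <- TRUE
          out[[length(out) + 1L]] <- tibble(
            host_id = hosts$genome_id[h],
            array_id = sprintf("%s_array_%d", hosts$genome_id[h], n_array),
            repeat_seq = w,
            spacer_id = sprintf("%s_array_%d_sp_%d", hosts$genome_id[h],
                                n_array, seq_along(spacers)),
            spacer_seq = spacers,
            start = spacer_start - 1L,
            end = spacer_end
          )
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(host_id = character(), array_id = character(),
                  repeat_seq = character(), spacer_id = character(),
                  spacer_seq = character(), start = integer(), end = integer()))
  }
  bind_rows(out)
}

#' Match CRISPR spacers against viral contigs
#'
#' Scans both strands of every virus for full-length, ungapped spacer
#' alignments with at most `max_mismatch` substitutions, and emits one edge
#' per (virus, host) pair recording the minimal mismatch count, strand, and
#' virus coordinates (0-based half-open). Spacers shorter than 20 bp are
#' rejected with a warning.
#'
#' @param spacers A tibble from [detect_spacers()] (needs `host_id`,
#'   `spacer_id`, `spacer_seq`), or a named character vector of spacer
#'   sequences (names taken as host ids).
#' @param viral_contigs Sequences in any accepted form.
#' @param max_mismatch Maximum Hamming distance (default 2).
#' @return A tibble of CRISPR association edges: `virus_id`, `host_id`,
#'   `signal = "crispr"`, `mismatches`, `strand`, `start`, `end`,
#'   `spacer_id`.
#' @export
match_spacers <- function(spacers, viral_contigs, max_mismatch = 2) {
  if (!is.data.frame(spacers)) {
    spacers <- tibble(host_id = names(spacers), spacer_id = names(spacers),
                      spacer_seq = unname(spacers))
  }
  short <- nchar(spacers$spacer_seq) < 20L
  if (any(short)) {
    warn(sprintf("%d spacer(s) shorter than 20 bp rejected", sum(short)))
    spacers <- spacers[!short, , drop = FALSE]
  }
  vir <- as_seq_tbl(viral_contigs, "viral_contigs")
  hits <- list()
  for (v in seq_len(nrow(vir))) {
    vseq <- Biostrings::DNAString(vir$sequence[v])
    for (s in seq_len(nrow(spacers))) {
      sp <- spacers$spacer_seq[s]
      if (nchar(sp) > length(vseq)) next
      best <- NULL
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") sp else reverse_complement_chr(sp)
        m <- Biostrings::matchPattern(pat, vseq, max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (length(m) == 0L) next
        mm <- Biostrings::neditAt(pat, vseq, at = Biostrings::start(m))
        i <- which.min(mm)
        cand <- list(mismatches = as.integer(mm[i]), strand = strand,
                     start = Biostrings::start(m)[i] - 1L,
                     end = Biostrings::end(m)[i])
        if (is.null(best) || cand$mismatches < best$mismatches) best <- cand
      }
      if (!is.null(best)) {
        hits[[length(hits) + 1L]] <- tibble(
          virus_id = vir$genome_id[v], host_id = spacers$host_id[s],
          signal = "crispr", mismatches = best$mismatches,
          strand = best$strand, start = best$start, end = best$end,
          spacer_id = spacers$spacer_id[s]
        )
      }
    }
  }
  if (length(hits) == 0L) {
    return(tibble(virus_id = character(), host_id = character(),
                  signal = character(), mismatches = integer(),
                  strand = character(), start = integer(), end = integer(),
                  spacer_id = character()))
  }
  bind_rows(hits) |>
    group_by(.data$virus_id, .data$host_id) |>
    arrange(.data$mismatches, .data$start, .by_group = TRUE) |>
    slice_head(n = 1L) |>
    ungroup()
}

#' Filter a similarity search table into association edges
#'
#' Keeps alignments with bit score >= `min_bitscore` and E-value <=
#' `max_evalue` (both boundaries inclusive) and collapses multiple rows per
#' (virus, host) pair to one edge, keeping the best-scoring row.
#'
#' @param alignment_table BLAST tabular (outfmt 6) dialect data frame with at
#'   least `qseqid`, `sseqid`, `evalue`, `bitscore` (viral contigs as
#'   queries).
#' @param min_bitscore Bit score threshold (default 50, inclusive).
#' @param max_evalue E-value threshold (default 0.001, inclusive).
#' @return A tibble of similarity association edges: `virus_id`, `host_id`,
#'   `signal = "similarity"`, `alignment_length`, `percent_identity`,
#'   `bitscore`, `evalue`.
#' @export
filter_similarity_links <- function(alignment_table, min_bitscore = 50,
                                    max_evalue = 0.001) {
  required <- c("qseqid", "sseqid", "evalue", "bitscore")
  missing <- setdiff(required, names(alignment_table))
  if (length(missing)) {
    abort(sprintf("alignment table missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(alignment_table$bitscore) | is.na(alignment_table$evalue))
  if (length(bad)) {
    abort(sprintf("unparseable alignment row at line %d", bad[1]))
  }
  alignment_table |>
    as_tibble() |>
    filter(.data$bitscore >= min_bitscore, .data$evalue <= max_evalue) |>
    group_by(.data$qseqid, .data$sseqid) |>
    arrange(desc(.data$bitscore), .data$evalue, .by_group = TRUE) |>
    slice_head(n = 1L) |>
    ungroup() |>
    transmute(
      virus_id = .data$qseqid, host_id = .data$sseqid,
      signal = "similarity",
      alignment_length = if ("length" %in% names(alignment_table))
        .data$length else NA_integer_,
      percent_identity = if ("pident" %in% names(alignment_table))
        .data$pident else NA_real_,
      bitscore = .data$bitscore, evalue = .data$evalue
    )
}

#' Read a BLAST tabular (outfmt 6) file
#' @param path Path to a 12-column tab-separated file with columns qseqid,
#'   sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#'   evalue, bitscore (no header).
#' @return A tibble with those columns.
#' @export
read_blast_tab <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore"),
    col_types = "ccdiiiiiiidd"
  )
}

#' Summarise virus-host edges as a family-by-class bipartite network
#'
#' Collapses association edges (from any of the three signals) to distinct
#' (virus, host) pairs, maps viruses to families and hosts to classes
#' (unmapped ids grouped as "unclassified"), and weights each
#' family-class network edge by the number of distinct underlying pairs.
#'
#' @param edges A data frame of association edges with `virus_id` and
#'   `host_id` columns (rows from [assign_by_composition()],
#'   [match_spacers()], and [filter_similarity_links()] can be
#'   `dplyr::bind_rows()`-ed together).
#' @param virus_taxonomy Named character vector or data frame
#'   (`virus_id`/`id`, `family`) mapping virus ids to families.
#' @param host_taxonomy Named character vector or data frame
#'   (`host_id`/`id`, `class`) mapping host ids to classes.
#' @return An object of class `vh_network`: a list with `edges` (tibble:
#'   `virus_family`, `host_class`, `weight`), `pairs` (the distinct
#'   virus-host pairs with their groups), `summary` (per-family host-class
#'   counts), and `graph` (a bipartite [igraph::graph_from_data_frame()]
#'   object). Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
build_network <- function(edges, virus_taxonomy = NULL, host_taxonomy = NULL) {
  lookup <- function(map, ids, value_col) {
    if (is.null(map)) return(rep("unclassified", length(ids)))
    if (is.data.frame(map)) {
      id_col <- intersect(c("virus_id", "host_id", "id", "genome_id"),
                          names(map))[1]
      map <- setNames(map[[value_col]], map[[id_col]])
    }
    out <- unname(map[ids])
    out[is.na(out)] <- "unclassified"
    out
  }
  pairs <- edges |>
    as_tibble() |>
    distinct(.data$virus_id, .data$host_id) |>
    mutate(
      virus_family = lookup(virus_taxonomy, .data$virus_id, "family"),
      host_class = lookup(host_taxonomy, .data$host_id, "class")
    )
  net_edges <- pairs |>
    count(.data$virus_family, .data$host_class, name = "weight") |>
    arrange(.data$virus_family, .data$host_class)
  summary <- net_edges |>
    group_by(.data$virus_family) |>
    summarise(n_host_classes = n_distinct(.data$host_class),
              n_pairs = sum(.data$weight), .groups = "drop")
  graph <- if (nrow(net_edges) > 0) {
    # prefix the two sides so a label shared between a virus family and a
    # host class (e.g. "unclassified") yields distinct vertices
    fams <- unique(net_edges$virus_family)
    clss <- unique(net_edges$host_class)
    g <- igraph::graph_from_data_frame(
      net_edges |>
        mutate(virus_family = paste0("virus:", .data$virus_family),
               host_class = paste0("host:", .data$host_class)),
      directed = FALSE,
      vertices = tibble(
        name = c(paste0("virus:", fams), paste0("host:", clss)),
        label = c(fams, clss),
        type = rep(c(TRUE, FALSE), c(length(fams), length(clss)))
      )
    )
    g
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }
  structure(
    list(edges = net_edges, pairs = pairs, summary = summary, graph = graph),
    class = "vh_network"
  )
}

#' @export
print.vh_network <- function(x, ...) {
  cat(sprintf(
    "<vh_network> %d virus families x %d host classes, %d network edges, %d virus-host pairs\n",
    n_distinct(x$edges$virus_family), n_distinct(x$edges$host_class),
    nrow(x$edges), sum(x$edges$weight)
  ))
  print(x$edges, ...)
  invisible(x)
}

#' Write a virus-host network as GraphML
#' @param network A `vh_network` from [build_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
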