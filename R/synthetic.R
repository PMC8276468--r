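#' Configuration for the synthetic-metagenome generator
#'
#' Builds and validates the configuration object consumed by every generator
#' in the synthetic module. Defaults describe a small benthic-style community:
#' five compositionally distinct host genomes of 50 kb, two integrated
#' prophages per host (5-10 kb), five CRISPR arrays whose 30 bp spacers copy
#' viral subsequences exactly, and a read-assignment table of 100,000 reads
#' drawn from a Dirichlet abundance vector with 10% of reads left
#' unclassified.
#'
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs from every generator.
#' @param n_hosts Number of host genomes.
#' @param host_length Host genome length in bp.
#' @param markov_order Order of the nucleotide chain used to generate host
#'   composition (default 3, i.e. tetranucleotide-scale structure).
#' @param markov_concentration Dirichlet concentration (total per transition
#'   row) controlling how strongly host transition rows are perturbed from
#'   uniform; smaller values give more distinct composition signatures.
#' @param n_prophages_per_host Prophages excised (copied) per host.
#' @param prophage_length_range Length range (bp) for prophage contigs,
#'   `c(low, high)` with `low <= high`.
#' @param n_decoys Decoy viral contigs generated from a chain fit to the
#'   pooled hosts: compositionally near the community but linked to no host.
#' @param n_spacer_arrays CRISPR arrays inserted across the hosts.
#' @param spacer_length Spacer length in bp.
#' @param spacer_mismatch_rate Per-position substitution probability applied
#'   when a spacer is copied from a virus.
#' @param n_reads Rows in the read-assignment table.
#' @param unassigned_fraction Fraction of reads left unassigned (carrying the
#'   `"unclassified"` sentinel lineage).
#' @param abundance_concentration Dirichlet concentration used to draw the
#'   ground-truth relative abundance vector over host taxa.
#' @return A validated list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1, n_hosts = 2, host_length = 6000,
#'                         n_reads = 100)
synthetic_config <- function(seed = 42L,
                             n_hosts = 5L,
                             host_length = 50000L,
                             markov_order = 3L,
                             markov_concentration = 4,
                             n_prophages_per_host = 2L,
                             prophage_length_range = c(5000L, 10000L),
                             n_decoys = 3L,
                             n_spacer_arrays = 5L,
                             spacer_length = 30L,
                             spacer_mismatch_rate = 0,
                             n_reads = 100000L,
                             unassigned_fraction = 0.1,
                             abundance_concentration = 5) {
  cfg <- list(
    seed = as.integer(check_number(seed, "seed", integer = TRUE)),
    n_hosts = as.integer(check_number(n_hosts, "n_hosts", min = 0, integer = TRUE)),
    host_length = as.integer(check_number(host_length, "host_length", min = 4, integer = TRUE)),
    markov_order = as.integer(check_number(markov_order, "markov_order", min = 0, integer = TRUE)),
    markov_concentration = check_number(markov_concentration, "markov_concentration", min = 1e-6),
    n_prophages_per_host = as.integer(check_number(n_prophages_per_host,
      "n_prophages_per_host", min = 0, integer = TRUE)),
    prophage_length_range = as.integer(prophage_length_range),
    n_decoys = as.integer(check_number(n_decoys, "n_decoys", min = 0, integer = TRUE)),
    n_spacer_arrays = as.integer(check_number(n_spacer_arrays, "n_spacer_arrays",
      min = 0, integer = TRUE)),
    spacer_length = as.integer(check_number(spacer_length, "spacer_length", min = 1, integer = TRUE)),
    spacer_mismatch_rate = check_number(spacer_mismatch_rate, "spacer_mismatch_rate",
      min = 0, max = 1),
    n_reads = as.integer(check_number(n_reads, "n_reads", min = 0, integer = TRUE)),
    unassigned_fraction = check_number(unassigned_fraction, "unassigned_fraction",
      min = 0, max = 1),
    abundance_concentration = check_number(abundance_concentration,
      "abundance_concentration", min = 1e-6)
  )
  if (length(cfg$prophage_length_range) != 2L ||
      anyNA(cfg$prophage_length_range) ||
      cfg$prophage_length_range[1] > cfg$prophage_length_range[2] ||
      cfg$prophage_length_range[1] < 1L) {
    abort("field `prophage_length_range` must be an ordered positive pair c(low, high)")
  }
  structure(cfg, class = "synthetic_config")
}

host_ids <- function(n) sprintf("host_%02d", seq_len(n))

host_lineages <- function(n) {
  sprintf(
    "sk__Bacteria;p__Phylum_%02d;c__Class_%02d;o__Order_%02d;f__Family_%02d;g__Genus_%02d;s__Species_%02d",
    seq_len(n), seq_len(n), seq_len(n), seq_len(n), seq_len(n), seq_len(n)
  )
}

# Dirichlet-perturbed transition table: 4^order rows, 4 columns.
random_transition_table <- function(order, concentration) {
  n_ctx <- 4L^order
  m <- matrix(rgamma(n_ctx * 4L, shape = concentration / 4), nrow = n_ctx)
  m / rowSums(m)
}

# Generate one sequence from an order-k chain given a row-stochastic table.
markov_sequence <- function(trans, order, length) {
  if (order == 0L) {
    probs <- trans[1L, ]
    return(paste(sample(DNA_BASES, length, replace = TRUE, prob = probs), collapse = ""))
  }
  cum <- t(apply(trans, 1L, cumsum))
  out <- integer(length)
  out[seq_len(order)] <- sample.int(4L, order, replace = TRUE)
  ctx <- 0L
  for (i in seq_len(order)) ctx <- ctx * 4L + (out[i] - 1L)
  ctx <- ctx + 1L
  mod <- 4L^(order - 1L)
  u <- runif(length)
  for (i in (order + 1L):length) {
    b <- findInterval(u[i], cum[ctx, ]) + 1L
    if (b > 4L) b <- 4L
    out[i] <- b
    ctx <- ((ctx - 1L) %% mod) * 4L + (b - 1L) + 1L
  }
  paste(DNA_BASES[out], collapse = "")
}

#' Generate compositionally distinct host genomes
#'
#' Each host is drawn from an independent, seeded order-`markov_order`
#' nucleotide chain whose transition rows are Dirichlet perturbations of a
#' uniform base, so hosts carry distinct tetranucleotide signatures while
#' subsequences of a host (e.g. prophages) stay compositionally close to it.
#'
#' @param config A [synthetic_config()].
#' @return A list with `genomes` (tibble: `genome_id`, `lineage`, `sequence`)
#'   and `composition_models` (named list of transition tables, recorded in
#'   the truth manifest).
#' @export
generate_host_genomes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_hosts < 1L) abort("field `n_hosts` must be >= 1")
  withr::with_seed(derive_seed(config$seed, "hosts"), {
    ids <- host_ids(config$n_hosts)
    models <- lapply(ids, function(i) {
      random_transition_table(config$markov_order, config$markov_concentration)
    })
    names(models) <- ids
    seqs <- map_chr(models, markov_sequence,
      order = config$markov_order, length = config$host_length
    )
    list(
      genomes = tibble(genome_id = ids, lineage = host_lineages(config$n_hosts),
                       sequence = unname(seqs)),
      composition_models = models
    )
  })
}

# Fit an order-k chain to pooled sequences (Laplace-smoothed transition counts).
fit_transition_table <- function(sequences, order) {
  dss <- Biostrings::DNAStringSet(sequences)
  counts <- colSums(Biostrings::oligonucleotideFrequency(dss, width = order + 1L))
  m <- matrix(counts, nrow = 4L^order, byrow = TRUE) + 1
  m / rowSums(m)
}

#' Plant prophage-derived viral contigs
#'
#' Copies verbatim subsequences out of each host genome (so every planted
#' virus carries both an exact similarity link and a small composition
#' distance to its source host) and additionally emits decoy viral contigs
#' generated from a chain fit to the pooled hosts: compositionally near the
#' community, but linked to no host.
#'
#' @param hosts The `genomes` tibble from [generate_host_genomes()].
#' @param config A [synthetic_config()].
#' @return A list with `viruses` (tibble: `virus_id`, `source`, `sequence`),
#'   `prophage_links` (tibble: `virus_id`, `host_id`, `host_start`,
#'   `host_end`; 0-based half-open coordinates on the pre-insertion host),
#'   and `decoy_ids`.
#' @export
plant_prophages <- function(hosts, config) {
  stopifnot(inherits(config, "synthetic_config"))
  lo <- config$prophage_length_range[1]
  hi <- config$prophage_length_range[2]
  if (config$n_prophages_per_host > 0L && any(nchar(hosts$sequence) < hi)) {
    abort("prophage length exceeds host length for at least one host")
  }
  withr::with_seed(derive_seed(config$seed, "prophages"), {
    links <- list()
    viruses <- list()
    for (h in seq_len(nrow(hosts))) {
      hseq <- hosts$sequence[h]
      hlen <- nchar(hseq)
      taken <- integer(0)
      for (p in seq_len(config$n_prophages_per_host)) {
        len <- if (lo == hi) lo else sample(lo:hi, 1L)
        # rejection-sample a start that does not overlap an earlier prophage,
        # so a CRISPR spacer window identifies exactly one planted virus
        for (try in 1:200) {
          start <- sample.int(hlen - len + 1L, 1L)
          if (!any(seq(start, start + len - 1L) %in% taken)) break
        }
        taken <- c(taken, seq(start, start + len - 1L))
        vid <- sprintf("vir_%s_%d", hosts$genome_id[h], p)
        viruses[[vid]] <- tibble(
          virus_id = vid, source = hosts$genome_id[h],
          sequence = substr(hseq, start, start + len - 1L)
        )
        links[[vid]] <- tibble(
          virus_id = vid, host_id = hosts$genome_id[h],
          host_start = start - 1L, host_end = start + len - 1L
        )
      }
    }
    decoys <- list()
    if (config$n_decoys > 0L) {
      pooled <- fit_transition_table(hosts$sequence, config$markov_order)
      dlen <- as.integer(round(mean(c(lo, hi))))
      for (d in seq_len(config$n_decoys)) {
        vid <- sprintf("vir_decoy_%d", d)
        decoys[[vid]] <- tibble(
          virus_id = vid, source = NA_character_,
          sequence = markov_sequence(pooled, config$markov_order, dlen)
        )
      }
    }
    list(
      viruses = bind_rows(c(viruses, decoys)),
      prophage_links = if (length(links)) bind_rows(links) else
        tibble(virus_id = character(), host_id = character(),
               host_start = integer(), host_end = integer()),
      decoy_ids = names(decoys)
    )
  })
}

CRISPR_REPEAT_LENGTH <- 28L
SPACERS_PER_ARRAY <- 2L

mutate_positions <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  list(seq = paste(chars, collapse = ""), n = length(hit))
}

#' Insert CRISPR repeat-spacer arrays into host genomes
#'
#' Each array is `repeat - spacer - repeat - spacer - repeat` (3 exact copies
#' of a random 28 bp repeat, 2 spacers). Every spacer is copied from a random
#' window of a planted (non-decoy) virus and mutated per position with
#' probability `spacer_mismatch_rate`; the realised mismatch count is
#' recorded in the returned links.
#'
#' @param hosts The `genomes` tibble (modified copies are returned).
#' @param viruses The `viruses` tibble from [plant_prophages()].
#' @param config A [synthetic_config()].
#' @return A list with `hosts` (sequences now containing the arrays) and
#'   `spacer_links` (tibble: `virus_id`, `host_id`, `spacer_seq`,
#'   `mismatches`).
#' @export
plant_crispr_arrays <- function(hosts, viruses, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_spacer_arrays == 0L) {
    return(list(hosts = hosts, spacer_links = tibble(
      virus_id = character(), host_id = character(),
      spacer_seq = character(), mismatches = integer()
    )))
  }
  sources <- viruses[is.na(viruses$source) == FALSE, , drop = FALSE]
  if (nrow(sources) == 0L) abort("no planted viruses available as spacer sources")
  if (config$spacer_length > min(nchar(sources$sequence))) {
    abort("field `spacer_length` exceeds the shortest virus length")
  }
  withr::with_seed(derive_seed(config$seed, "crispr"), {
    out_hosts <- hosts
    links <- list()
    for (a in seq_len(config$n_spacer_arrays)) {
      h <- ((a - 1L) %% nrow(hosts)) + 1L
      rep_seq <- paste(sample(DNA_BASES, CRISPR_REPEAT_LENGTH, replace = TRUE),
                       collapse = "")
      # resample spacer windows until neither the first nor the last spacer
      # bases coincide across the array, so the planted repeat is maximal (a
      # detector cannot extend it by a shared flanking base)
      for (try in 1:100) {
        spacers <- character(SPACERS_PER_ARRAY)
        arr_links <- vector("list", SPACERS_PER_ARRAY)
        for (s in seq_len(SPACERS_PER_ARRAY)) {
          v <- sources[sample.int(nrow(sources), 1L), ]
          start <- sample.int(nchar(v$sequence) - config$spacer_length + 1L, 1L)
          raw <- substr(v$sequence, start, start + config$spacer_length - 1L)
          mut <- mutate_positions(raw, config$spacer_mismatch_rate)
          spacers[s] <- mut$seq
          arr_links[[s]] <- tibble(
            virus_id = v$virus_id, host_id = out_hosts$genome_id[h],
            spacer_seq = mut$seq, mismatches = mut$n
          )
        }
        firsts <- substr(spacers, 1L, 1L)
        lasts <- substr(spacers, config$spacer_length, config$spacer_length)
        if (anyDuplicated(firsts) == 0L && anyDuplicated(lasts) == 0L) break
      }
      links <- c(links, arr_links)
      array <- paste0(rep_seq, paste0(spacers, rep_seq, collapse = ""))
      hseq <- out_hosts$sequence[h]
      ins <- sample.int(nchar(hseq) + 1L, 1L)
      out_hosts$sequence[h] <- paste0(
        substr(hseq, 1L, ins - 1L), array, substr(hseq, ins, nchar(hseq))
      )
    }
    list(hosts = out_hosts, spacer_links = bind_rows(links))
  })
}

#' Generate per-genome marker annotation tables with planted lifestyles
#'
#' For each synthetic genome a random subset of catalog pathways is planted
#' (each pathway independently with probability 1/2); the emitted table
#' contains exactly `min_markers_present` key genes for every planted
#' pathway, plus random non-marker noise genes. Expected lifestyle flags are
#' derived directly from the planted pathway categories, independently of
#' the classifier, so the round trip through [classify_traits()] is a real
#' check.
#'
#' @param pathway_catalog A pathway catalog tibble
#'   (see [read_pathway_catalog()]).
#' @param config A [synthetic_config()].
#' @return A list with `annotations` (tibble: `genome_id`, `gene_id`,
#'   `marker_label`) and `trait_labels` (tibble of expected flags).
#' @export
generate_annotation_tables <- function(pathway_catalog, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (nrow(pathway_catalog) == 0L) abort("pathway catalog is empty")
  if (anyDuplicated(pathway_catalog$name)) {
    abort("pathway catalog contains duplicate pathway names")
  }
  withr::with_seed(derive_seed(config$seed, "annotations"), {
    ids <- host_ids(config$n_hosts)
    ann <- list()
    labels <- list()
    for (g in ids) {
      planted <- pathway_catalog[runif(nrow(pathway_catalog)) < 0.5, , drop = FALSE]
      genes <- character(0)
      for (i in seq_len(nrow(planted))) {
        m <- planted$min_markers_present[i]
        genes <- c(genes, sample(planted$key_genes[[i]], m))
      }
      noise <- sprintf("nov_gene_%04d", sample.int(9999L, 5L))
      all_genes <- c(genes, noise)
      if (length(all_genes)) {
        ann[[g]] <- tibble(
          genome_id = g,
          gene_id = sprintf("%s_orf_%03d", g, seq_along(all_genes)),
          marker_label = all_genes
        )
      }
      grp <- category_group(planted$category)
      chemo_types <- category_subtype(planted$category[grp == "chemolithotrophy"])
      heterotroph <- any(grp %in% DEGRADATION_GROUPS)
      autotroph <- any(grp == "co2_fixation")
      aerobic <- any(grp == "aerobic_respiration")
      anaerobic <- any(grp == "anaerobic")
      labels[[g]] <- tibble(
        genome_id = g,
        heterotroph = heterotroph,
        autotroph_any = autotroph,
        mixotroph = heterotroph && autotroph,
        aerobic = aerobic,
        anaerobic = anaerobic,
        facultative = aerobic && anaerobic,
        chemolithotroph = length(chemo_types) > 0L,
        chemolithotroph_types = paste(sort(chemo_types), collapse = ",")
      )
    }
    list(annotations = bind_rows(ann), trait_labels = bind_rows(labels))
  })
}

#' Draw a ground-truth relative abundance vector over host taxa
#'
#' @param config A [synthetic_config()].
#' @param lineages Lineage strings naming the taxa (defaults to the host
#'   lineages implied by the config).
#' @return A named numeric vector summing to 1.
#' @export
generate_abundance_vector <- function(config, lineages = host_lineages(config$n_hosts)) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(derive_seed(config$seed, "abundance"), {
    w <- rgamma(length(lineages), shape = config$abundance_concentration)
    setNames(w / sum(w), lineages)
  })
}

#' Generate a per-read taxonomic assignment table
#'
#' Reads are assigned multinomially according to `abundance_vector`, except a
#' fixed `unassigned_fraction` that carries the `"unclassified"` sentinel
#' lineage (never an empty string).
#'
#' @param abundance_vector Named numeric vector of relative abundances
#'   (names are semicolon-delimited, rank-prefixed lineage strings); must sum
#'   to 1.
#' @param config A [synthetic_config()].
#' @return A tibble with `read_id` and `lineage` columns, `n_reads` rows.
#' @export
generate_read_assignments <- function(abundance_vector, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(abundance_vector < 0)) abort("abundance_vector has negative entries")
  if (length(abundance_vector) && abs(sum(abundance_vector) - 1) > 1e-9) {
    abort("abundance_vector must sum to 1")
  }
  if (config$n_reads == 0L) {
    return(tibble(read_id = character(), lineage = character()))
  }
  withr::with_seed(derive_seed(config$seed, "reads"), {
    n_un <- as.integer(round(config$n_reads * config$unassigned_fraction))
    n_as <- config$n_reads - n_un
    counts <- if (n_as > 0L) {
      as.vector(rmultinom(1L, n_as, prob = abundance_vector))
    } else {
      integer(length(abundance_vector))
    }
    lineage <- c(rep(names(abundance_vector), counts), rep("unclassified", n_un))
    lineage <- lineage[sample.int(length(lineage))]
    tibble(read_id = sprintf("read_%07d", seq_along(lineage)), lineage = lineage)
  })
}

# Synthetic MAG QC scores and viral ORF annotations round out the bundle so
# the full pipeline (including the QC and AMG stages) runs on generated data.
generate_qc_table <- function(config) {
  withr::with_seed(derive_seed(config$seed, "qc"), {
    n <- config$n_hosts
    tibble(
      genome_id = host_ids(n),
      completeness = round(runif(n, 40, 100), 2),
      contamination = round(runif(n, 0, 15), 2),
      lineage = host_lineages(n)
    )
  })
}

generate_viral_annotations <- function(viruses, config) {
  withr::with_seed(derive_seed(config$seed, "viral_ann"), {
    cogs <- c("L", "K", "T", "M", "J", "C", "E", NA_character_)
    rows <- list()
    for (i in seq_len(nrow(viruses))) {
      n_orf <- sample(3:6, 1L)
      for (o in seq_len(n_orf)) {
        rows[[length(rows) + 1L]] <- tibble(
          contig_id = viruses$virus_id[i],
          orf_id = sprintf("%s_orf_%02d", viruses$virus_id[i], o),
          cog_category = sample(cogs, 1L),
          cazy_family = NA_character_,
          ko_id = NA_character_,
          description = "hypothetical protein"
        )
      }
    }
    ann <- bind_rows(rows)
    # plant a few AMGs: CAZy families plus the two named N/S orthologs
    amg_rows <- sample.int(nrow(ann), min(6L, nrow(ann)))
    fams <- c("GH5", "GH13", "PL1", "GT2", "CBM13", "AA3")
    ann$cazy_family[amg_rows[1:4]] <- fams[1:4]
    if (length(amg_rows) >= 5L) ann$ko_id[amg_rows[5]] <- "K00368"
    if (length(amg_rows) >= 6L) ann$ko_id[amg_rows[6]] <- "K00956"
    ann
  })
}

# Exact-substring prophages imply perfect alignments; emit the corresponding
# similarity table (BLAST outfmt-6 dialect) from the recorded coordinates,
# plus sub-threshold decoy rows so the similarity filter has work to do.
similarity_table_from_truth <- function(links, viruses, decoy_ids) {
  if (nrow(links) == 0L) {
    return(empty_blast_tbl())
  }
  len <- nchar(viruses$sequence[match(links$virus_id, viruses$virus_id)])
  real <- tibble(
    qseqid = links$virus_id, sseqid = links$host_id,
    pident = 100, length = len, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = len,
    sstart = links$host_start + 1L, send = links$host_end,
    evalue = 0, bitscore = round(1.8 * len, 1)
  )
  decoy <- tibble(
    qseqid = decoy_ids, sseqid = links$host_id[seq_along(decoy_ids)],
    pident = 71.2, length = 40L, mismatch = 11L, gapopen = 1L,
    qstart = 10L, qend = 49L, sstart = 500L, send = 539L,
    evalue = 0.2, bitscore = 38.1
  )
  bind_rows(real, decoy)
}

empty_blast_tbl <- function() {
  tibble(
    qseqid = character(), sseqid = character(), pident = double(),
    length = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), evalue = double(), bitscore = double()
  )
}

#' Generate a complete synthetic metagenome bundle with ground truth
#'
#' Runs every generator in order and returns the inputs for all downstream
#' stages together with a truth manifest (prophage links, spacer links,
#' trait labels, abundance vector, composition models).
#'
#' @param config A [synthetic_config()].
#' @param pathway_catalog Pathway catalog for the annotation generator
#'   (default: the shipped prokaryote catalog).
#' @return A list of class `synthetic_bundle` with elements `hosts`,
#'   `viruses`, `annotations`, `viral_annotations`, `assignments`, `qc`,
#'   `similarity`, and `truth`.
#' @export
synthesize_metagenome <- function(config = synthetic_config(),
                                  pathway_catalog = default_pathway_catalog()) {
  hg <- generate_host_genomes(config)
  pp <- plant_prophages(hg$genomes, config)
  ca <- plant_crispr_arrays(hg$genomes, pp$viruses, config)
  an <- generate_annotation_tables(pathway_catalog, config)
  av <- generate_abundance_vector(config)
  reads <- generate_read_assignments(av, config)
  structure(list(
    hosts = ca$hosts,
    viruses = pp$viruses,
    annotations = an$annotations,
    viral_annotations = generate_viral_annotations(pp$viruses, config),
    assignments = reads,
    qc = generate_qc_table(config),
    similarity = similarity_table_from_truth(pp$prophage_links, pp$viruses,
                                             pp$decoy_ids),
    truth = list(
      prophage_links = pp$prophage_links,
      spacer_links = ca$spacer_links,
      trait_labels = an$trait_labels,
      abundance_vector = av,
      composition_models = hg$composition_models,
      decoy_ids = pp$decoy_ids
    ),
    config = config
  ), class = "synthetic_bundle")
}
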