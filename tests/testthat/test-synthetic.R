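test_that("config validation errors name the offending field", {
  expect_error(synthetic_config(spacer_mismatch_rate = 1.5), "spacer_mismatch_rate")
  expect_error(synthetic_config(n_hosts = -1), "n_hosts")
  expect_error(synthetic_config(unassigned_fraction = -0.1), "unassigned_fraction")
  expect_error(synthetic_config(prophage_length_range = c(500, 100)),
               "prophage_length_range")
  expect_error(synthetic_config(host_length = 2), "host_length")
})

test_that("host genomes honour length, alphabet and seeding contracts", {
  cfg <- synthetic_config(seed = 1, n_hosts = 3, host_length = 5000)
  hg <- generate_host_genomes(cfg)
  expect_equal(nrow(hg$genomes), 3L)
  expect_true(all(nchar(hg$genomes$sequence) == 5000L))
  expect_false(any(grepl("[^ACGT]", hg$genomes$sequence)))
  expect_length(hg$composition_models, 3L)
  # identical config + seed => identical output, different seed => different
  hg2 <- generate_host_genomes(cfg)
  expect_identical(hg$genomes, hg2$genomes)
  hg3 <- generate_host_genomes(synthetic_config(seed = 2, n_hosts = 3,
                                                host_length = 5000))
  expect_false(identical(hg$genomes$sequence, hg3$genomes$sequence))
})

test_that("hosts across seeds are compositionally farther apart than a host and its prophages", {
  cfg1 <- synthetic_config(seed = 1, n_hosts = 1, host_length = 20000,
                           prophage_length_range = c(5000, 5000),
                           n_prophages_per_host = 2, n_decoys = 0)
  cfg2 <- synthetic_config(seed = 2, n_hosts = 1, host_length = 20000)
  h1 <- generate_host_genomes(cfg1)$genomes
  h2 <- generate_host_genomes(cfg2)$genomes
  pp <- plant_prophages(h1, cfg1)
  v_h1 <- oracle_kmer_vector(h1$sequence[1])
  d_across <- oracle_mae(v_h1, oracle_kmer_vector(h2$sequence[1]))
  d_own <- sapply(pp$viruses$sequence,
                  function(s) oracle_mae(v_h1, oracle_kmer_vector(s)))
  expect_true(all(d_across > d_own))
})

test_that("prophages are verbatim host subsequences; decoys carry no links", {
  cfg <- small_config()
  hg <- generate_host_genomes(cfg)
  pp <- plant_prophages(hg$genomes, cfg)
  planted <- pp$viruses[!is.na(pp$viruses$source), ]
  for (i in seq_len(nrow(planted))) {
    host_seq <- hg$genomes$sequence[hg$genomes$genome_id == planted$source[i]]
    expect_true(grepl(planted$sequence[i], host_seq, fixed = TRUE))
  }
  expect_equal(nrow(pp$prophage_links),
               cfg$n_hosts * cfg$n_prophages_per_host)
  expect_false(any(pp$decoy_ids %in% pp$prophage_links$virus_id))
  # links use recorded coordinates consistently (0-based half-open)
  for (i in seq_len(nrow(pp$prophage_links))) {
    l <- pp$prophage_links[i, ]
    hseq <- hg$genomes$sequence[hg$genomes$genome_id == l$host_id]
    expect_identical(substr(hseq, l$host_start + 1, l$host_end),
                     pp$viruses$sequence[pp$viruses$virus_id == l$virus_id])
  }
})

test_that("zero prophages yields only decoys; oversized prophages error", {
  cfg <- small_config(n_prophages_per_host = 0L)
  hg <- generate_host_genomes(cfg)
  pp <- plant_prophages(hg$genomes, cfg)
  expect_equal(nrow(pp$prophage_links), 0L)
  expect_true(all(is.na(pp$viruses$source)))
  cfg_big <- small_config(prophage_length_range = c(20000L, 20000L))
  expect_error(plant_prophages(hg$genomes, cfg_big), "exceeds host length")
})

test_that("planted prophages are compositionally closest to their own host (brute-force)", {
  b <- default_bundle()
  hv <- lapply(split(b$hosts$sequence, b$hosts$genome_id), oracle_kmer_vector)
  links <- b$truth$prophage_links
  for (i in seq_len(nrow(links))) {
    vseq <- b$viruses$sequence[b$viruses$virus_id == links$virus_id[i]]
    d <- sapply(hv, oracle_mae, a = oracle_kmer_vector(vseq))
    expect_equal(names(which.min(d)), links$host_id[i])
  }
})

test_that("CRISPR planting contracts: exact copies at rate 0, identity at 0 arrays, Hamming-verified mismatches", {
  cfg <- small_config(spacer_mismatch_rate = 0)
  hg <- generate_host_genomes(cfg)
  pp <- plant_prophages(hg$genomes, cfg)
  ca <- plant_crispr_arrays(hg$genomes, pp$viruses, cfg)
  for (i in seq_len(nrow(ca$spacer_links))) {
    l <- ca$spacer_links[i, ]
    vseq <- pp$viruses$sequence[pp$viruses$virus_id == l$virus_id]
    expect_true(grepl(l$spacer_seq, vseq, fixed = TRUE))
    expect_equal(l$mismatches, 0L)
  }
  # no arrays: hosts byte-for-byte unchanged
  cfg0 <- small_config(n_spacer_arrays = 0L)
  ca0 <- plant_crispr_arrays(hg$genomes, pp$viruses, cfg0)
  expect_identical(ca0$hosts, hg$genomes)
  # with mutation: recorded mismatch counts match a direct Hamming scan
  cfg_mut <- small_config(seed = 21L, spacer_mismatch_rate = 0.05)
  hgm <- generate_host_genomes(cfg_mut)
  ppm <- plant_prophages(hgm$genomes, cfg_mut)
  cam <- plant_crispr_arrays(hgm$genomes, ppm$viruses, cfg_mut)
  expect_true(any(cam$spacer_links$mismatches > 0L))
  for (i in seq_len(nrow(cam$spacer_links))) {
    l <- cam$spacer_links[i, ]
    vseq <- ppm$viruses$sequence[ppm$viruses$virus_id == l$virus_id]
    expect_equal(oracle_spacer_scan(l$spacer_seq, vseq), l$mismatches)
  }
})

test_that("CRISPR planting validates spacer length and virus availability", {
  cfg <- small_config(spacer_length = 10000L)
  hg <- generate_host_genomes(cfg)
  pp <- plant_prophages(hg$genomes, cfg)
  expect_error(plant_crispr_arrays(hg$genomes, pp$viruses, cfg), "spacer_length")
  no_vir <- pp$viruses[0, ]
  expect_error(plant_crispr_arrays(hg$genomes, no_vir, small_config()),
               "no planted viruses")
})

test_that("annotation tables force the planted trait rules and round-trip through the classifier", {
  cfg <- small_config(n_hosts = 8L)
  catalog <- default_pathway_catalog()
  an <- generate_annotation_tables(catalog, cfg)
  aerobic_markers <- unlist(catalog$key_genes[catalog$category == "aerobic_respiration"])
  anaerobic_markers <- unlist(
    catalog$key_genes[startsWith(catalog$category, "anaerobic")]
  )
  for (g in an$trait_labels$genome_id[an$trait_labels$facultative]) {
    labels <- an$annotations$marker_label[an$annotations$genome_id == g]
    expect_true(any(labels %in% aerobic_markers))
    expect_true(any(labels %in% anaerobic_markers))
  }
  # genomes with no planted pathway carry no catalog marker
  all_markers <- unlist(catalog$key_genes)
  none <- an$trait_labels$genome_id[
    !(an$trait_labels$heterotroph | an$trait_labels$autotroph_any |
        an$trait_labels$aerobic | an$trait_labels$anaerobic |
        an$trait_labels$chemolithotroph)
  ]
  for (g in none) {
    labels <- an$annotations$marker_label[an$annotations$genome_id == g]
    expect_false(any(labels %in% all_markers))
  }
  # full round trip
  profiles <- suppressMessages(classify_traits(an$annotations, catalog))
  merged <- dplyr::inner_join(as.data.frame(profiles), an$trait_labels,
                              by = "genome_id", suffix = c("", ".truth"))
  expect_equal(nrow(merged), nrow(an$trait_labels))
  for (f in c("heterotroph", "autotroph_any", "mixotroph", "aerobic",
              "anaerobic", "facultative", "chemolithotroph",
              "chemolithotroph_types")) {
    expect_equal(merged[[f]], merged[[paste0(f, ".truth")]])
  }
  dup_cat <- dplyr::bind_rows(catalog, catalog[1, ])
  expect_error(generate_annotation_tables(dup_cat, cfg), "duplicate")
})

test_that("read assignments follow the abundance vector and sentinel contracts", {
  cfg <- small_config(n_reads = 50L, unassigned_fraction = 0)
  single <- c("sk__Bacteria;p__OnlyOne" = 1)
  reads <- generate_read_assignments(single, cfg)
  expect_equal(nrow(reads), 50L)
  expect_true(all(reads$lineage == names(single)))
  empty <- generate_read_assignments(single, small_config(n_reads = 0L))
  expect_equal(nrow(empty), 0L)
  expect_error(
    generate_read_assignments(c(a = -0.5, b = 1.5), cfg), "negative"
  )
  expect_error(
    generate_read_assignments(c(a = 0.4, b = 0.4), cfg), "sum to 1"
  )
  # unassigned reads carry the explicit sentinel, never an empty string
  cfg_un <- small_config(n_reads = 1000L, unassigned_fraction = 0.2)
  av <- generate_abundance_vector(cfg_un)
  r <- generate_read_assignments(av, cfg_un)
  expect_equal(sum(r$lineage == "unclassified"), 200L)
  expect_false(any(r$lineage == ""))
})

test_that("at 100k reads recovered abundances are within 1% absolute of the truth vector", {
  b <- default_bundle()
  tab <- summarize_abundance(b$assignments, "phylum")
  truth <- b$truth$abundance_vector
  names(truth) <- sub(".*p__([^;]+);.*", "\\1", names(truth))
  for (i in seq_len(nrow(tab))) {
    expect_lt(abs(tab$rel_abundance[i] - 100 * truth[[tab$taxon[i]]]), 1)
  }
})

test_that("bundle generation is deterministic and truth ids resolve to emitted records", {
  cfg <- small_config()
  b1 <- synthesize_metagenome(cfg)
  b2 <- synthesize_metagenome(cfg)
  expect_identical(b1$hosts, b2$hosts)
  expect_identical(b1$viruses, b2$viruses)
  expect_identical(b1$assignments, b2$assignments)
  expect_identical(b1$truth, b2$truth)
  # no orphan truth entries
  expect_true(all(b1$truth$prophage_links$virus_id %in% b1$viruses$virus_id))
  expect_true(all(b1$truth$prophage_links$host_id %in% b1$hosts$genome_id))
  expect_true(all(b1$truth$spacer_links$virus_id %in% b1$viruses$virus_id))
  expect_true(all(b1$truth$spacer_links$host_id %in% b1$hosts$genome_id))
  expect_true(all(b1$truth$trait_labels$genome_id %in% b1$hosts$genome_id))
  expect_equal(sum(b1$truth$abundance_vector), 1, tolerance = 1e-9)
  expect_setequal(names(b1$truth$composition_models), b1$hosts$genome_id)
})
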