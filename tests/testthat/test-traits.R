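ann_tbl <- function(genome_id, labels) {
  tibble::tibble(genome_id = genome_id,
                 gene_id = sprintf("%s_%03d", genome_id, seq_along(labels)),
                 marker_label = labels)
}

test_that("module completeness is the percentage of key genes encoded", {
  pw <- list(key_genes = c("cdhD", "acsB", "cooS", "acsE"))
  expect_equal(module_completeness(c("acsB"), pw), 25)
  expect_equal(module_completeness(c("cdhD", "acsB", "cooS", "acsE"), pw), 100)
  expect_equal(module_completeness(c("xyzQ"), pw), 0)
  # 2 of 3 rounds to two decimals
  expect_equal(module_completeness(c("a", "b"), list(key_genes = c("a", "b", "c"))),
               66.67)
})

test_that("lifestyle flags follow the marker rules", {
  catalog <- default_pathway_catalog()
  aero <- suppressMessages(classify_traits(ann_tbl("g1", "coxA"), catalog))
  expect_true(aero$aerobic)
  expect_false(aero$anaerobic)
  expect_false(aero$facultative)
  fac <- suppressMessages(classify_traits(ann_tbl("g1", c("coxA", "nirK")), catalog))
  expect_true(fac$facultative)
  # CAZy family + both Calvin-cycle markers => heterotroph and autotroph
  mix <- suppressMessages(
    classify_traits(ann_tbl("g1", c("GH5", "rbcS", "prkB")), catalog)
  )
  expect_true(mix$heterotroph)
  expect_true(mix$autotroph_any)
  expect_true(mix$mixotroph)
  # rbcS alone does not satisfy the two-marker Calvin-cycle requirement
  cbb1 <- suppressMessages(classify_traits(ann_tbl("g1", "rbcS"), catalog))
  expect_false(cbb1$autotroph_any)
  chemo <- suppressMessages(classify_traits(ann_tbl("g1", c("sqr", "cyc2")), catalog))
  expect_true(chemo$chemolithotroph)
  expect_equal(chemo$chemolithotroph_types, "iron_oxidation,sulfide_oxidation")
})

test_that("trait flag invariants hold: facultative and mixotroph imply their parts", {
  catalog <- default_pathway_catalog()
  all_markers <- unique(unlist(catalog$key_genes))
  set.seed(11)
  for (i in 1:20) {
    labels <- sample(all_markers, sample(1:10, 1))
    p <- suppressMessages(classify_traits(ann_tbl("g", labels), catalog))
    expect_true(!p$facultative || (p$aerobic && p$anaerobic))
    expect_true(!p$mixotroph || (p$heterotroph && p$autotroph_any))
  }
})

test_that("adding a gene never decreases completeness or turns a flag off", {
  catalog <- default_pathway_catalog()
  all_markers <- unique(unlist(catalog$key_genes))
  flag_cols <- c("heterotroph", "autotroph_any", "mixotroph", "aerobic",
                 "anaerobic", "facultative", "chemolithotroph")
  set.seed(5)
  for (i in 1:10) {
    base <- sample(all_markers, 4)
    extra <- c(base, sample(setdiff(all_markers, base), 1))
    p1 <- suppressMessages(classify_traits(ann_tbl("g", base), catalog))
    p2 <- suppressMessages(classify_traits(ann_tbl("g", extra), catalog))
    c1 <- attr(p1, "completeness")
    c2 <- attr(p2, "completeness")
    expect_true(all(c2$completeness >= c1$completeness))
    for (f in flag_cols) expect_true(p2[[f]] >= p1[[f]])
  }
})

test_that("the default catalogs validate and carry the expected markers", {
  catalog <- default_pathway_catalog()
  expect_false(anyDuplicated(catalog$name) > 0)
  expect_true(all(lengths(catalog$key_genes) > 0))
  named_markers <- c("rbcS", "prkB", "acsB", "cdhD", "cooS", "cooF", "acsE",
                     "nirB", "nirD", "nirK", "norC", "sat", "aprA", "aprB",
                     "dsrA", "dsrB", "amoA", "amoB", "amoC", "hao", "coxL",
                     "sqr", "fccB", "cyc2")
  all_genes <- unlist(catalog$key_genes)
  expect_true(all(named_markers %in% all_genes))
  # the Calvin-cycle entry requires both of its markers
  expect_equal(catalog$min_markers_present[catalog$name == "CBB"], 2L)
  fungal <- default_pathway_catalog("fungal")
  expect_true(all(c("NirK", "tauD", "ssuD", "SQOR") %in%
                    unlist(fungal$key_genes)))
  # same engine runs the fungal catalog
  fp <- suppressMessages(
    classify_traits(ann_tbl("f1", c("NirK", "tauD")), fungal)
  )
  expect_true(fp$anaerobic)
  expect_true(fp$chemolithotroph)
})

test_that("catalog validation rejects duplicates and empty marker sets", {
  catalog <- default_pathway_catalog()
  expect_error(hadalomics:::validate_pathway_catalog(dplyr::bind_rows(catalog, catalog[2, ])),
               "duplicate")
  broken <- catalog
  broken$key_genes[[1]] <- character(0)
  expect_error(hadalomics:::validate_pathway_catalog(broken), "empty key_genes")
})

test_that("annotation rows matching no marker are ignored with a message", {
  catalog <- default_pathway_catalog()
  expect_message(
    p <- classify_traits(ann_tbl("g1", c("coxA", "mystery_gene")), catalog),
    "1 annotation row"
  )
  expect_true(p$aerobic)
})

test_that("the trait matrix and community summary aggregate correctly", {
  catalog <- default_pathway_catalog()
  ann <- dplyr::bind_rows(ann_tbl("g1", c("coxA", "nirK")), ann_tbl("g2", "coxA"))
  profiles <- suppressMessages(classify_traits(ann, catalog))
  s <- trait_summary(profiles)
  expect_equal(s$n[s$flag == "facultative"], 1L)
  expect_equal(s$percent[s$flag == "facultative"], 50)
  expect_equal(s$n[s$flag == "aerobic"], 2L)
  m <- trait_matrix(attr(profiles, "completeness"))
  expect_equal(nrow(m), 2L)
  expect_equal(ncol(m), nrow(catalog) + 1L)
  one <- trait_matrix(attr(profiles, "completeness")[
    attr(profiles, "completeness")$genome_id == "g1", ])
  expect_equal(nrow(one), 1L)
})

test_that("summary counts equal a brute-force recount over random flag profiles", {
  set.seed(17)
  flags <- c("heterotroph", "autotroph_any", "mixotroph", "aerobic",
             "anaerobic", "facultative", "chemolithotroph")
  profiles <- tibble::as_tibble(
    setNames(as.data.frame(matrix(runif(100 * 7) < 0.5, ncol = 7)), flags)
  )
  profiles$genome_id <- sprintf("g%03d", 1:100)
  s <- trait_summary(profiles)
  for (f in flags) {
    manual <- sum(profiles[[f]])
    expect_equal(s$n[s$flag == f], manual)
    expect_equal(s$percent[s$flag == f], round(100 * manual / 100, 2))
  }
})

test_that("tidy and glance expose the completeness table and community counts", {
  ann <- ann_tbl("g1", c("coxA", "nirK"))
  p <- suppressMessages(classify_traits(ann))
  td <- generics::tidy(p)
  expect_true(all(c("genome_id", "pathway", "completeness", "present") %in%
                    names(td)))
  g <- generics::glance(p)
  expect_equal(g$n_genomes, 1L)
  expect_equal(g$n_facultative, 1L)
})
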