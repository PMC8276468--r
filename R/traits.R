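DEGRADATION_GROUPS <- c("carbohydrate_degradation", "hydrocarbon_degradation",
                        "aromatic_degradation")

category_group <- function(category) sub(":.*$", "", category)
category_subtype <- function(category) {
  ifelse(grepl(":", category, fixed = TRUE), sub("^[^:]*:", "", category),
         category)
}

#' Read and validate a pathway catalog
#'
#' Catalogs are YAML lists of entries with fields `name`, `category`
#' (`<group>` or `<group>:<subtype>`), `key_genes`, and optional
#' `min_markers_present` (default 1). Pathway names must be unique and every
#' key-gene set non-empty.
#'
#' @param path YAML file path.
#' @return A tibble with columns `name`, `category`, `key_genes` (list
#'   column), and `min_markers_present`.
#' @export
read_pathway_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  cat <- tibble(
    name = map_chr(raw, "name"),
    category = map_chr(raw, "category"),
    key_genes = map(raw, function(e) as.character(e$key_genes)),
    min_markers_present = map_int(raw, function(e) {
      as.integer(e$min_markers_present %||% 1L)
    })
  )
  validate_pathway_catalog(cat)
}

validate_pathway_catalog <- function(cat) {
  if (anyDuplicated(cat$name)) {
    abort(sprintf("duplicate pathway name(s) in catalog: %s",
                  paste(unique(cat$name[duplicated(cat$name)]), collapse = ", ")))
  }
  empty <- lengths(cat$key_genes) == 0L
  if (any(empty)) {
    abort(sprintf("pathway '%s' has an empty key_genes set", cat$name[which(empty)[1]]))
  }
  if (any(cat$min_markers_present < 1L |
          cat$min_markers_present > lengths(cat$key_genes))) {
    abort("min_markers_present must be between 1 and the number of key genes")
  }
  cat
}

#' Load a shipped default pathway catalog
#'
#' @param which `"prokaryote"` (carbon fixation, respiration, degradation,
#'   and chemolithotrophy pathways) or `"fungal"` (nitrogen/sulfur pathways
#'   of sediment fungi; same engine, different marker sets).
#' @return A pathway catalog tibble.
#' @export
default_pathway_catalog <- function(which = c("prokaryote", "fungal")) {
  which <- match.arg(which)
  read_pathway_catalog(system.file(
    "extdata", paste0(which, "_pathways.yml"), package = "hadalomics",
    mustWork = TRUE
  ))
}

# CAZyme class codes act as prefix markers: key gene "GH" matches an
# annotation label "GH5". All other markers match exactly.
marker_matches <- function(key, labels) {
  if (grepl("^[A-Z]{2,3}$", key)) {
    any(labels == key | grepl(paste0("^", key, "[0-9]"), labels))
  } else {
    any(labels == key)
  }
}

#' Pathway module completeness
#'
#' The module completeness of a pathway in a genome is the percentage of the
#' pathway's key genes that are encoded: `100 * |present & key| / |key|`,
#' rounded to two decimals. A genome encoding one of a pathway's four key
#' genes scores 25.
#'
#' @param genes_present Character vector of marker labels detected in the
#'   genome.
#' @param pathway One catalog entry: a one-row tibble or a list with at least
#'   `key_genes`.
#' @return Completeness percent in `[0, 100]`.
#' @export
#' @examples
#' pw <- list(key_genes = c("cdhD", "acsB", "cooS", "acsE"))
#' module_completeness(c("acsB", "xyzA"), pw)  # 25
module_completeness <- function(genes_present, pathway) {
  key <- if (is.data.frame(pathway)) pathway$key_genes[[1]] else
    unlist(pathway$key_genes %||% pathway["key_genes"], use.names = FALSE)
  if (length(key) == 0L) abort("pathway has no key genes")
  hit <- map_lgl(key, marker_matches, labels = genes_present)
  round(100 * sum(hit) / length(key), 2)
}

#' Per-genome, per-pathway completeness and presence
#'
#' @param annotations Data frame with columns `genome_id` and `marker_label`
#'   (one row per annotated gene; non-marker rows are ignored and counted in
#'   a message).
#' @param catalog Pathway catalog tibble (see [read_pathway_catalog()]).
#' @return A tibble with one row per genome x pathway: `genome_id`,
#'   `pathway`, `category`, `n_key`, `n_present`, `completeness`, `present`.
#' @export
pathway_completeness <- function(annotations, catalog) {
  stopifnot(is.data.frame(annotations),
            all(c("genome_id", "marker_label") %in% names(annotations)))
  validate_pathway_catalog(catalog)
  all_keys <- unique(unlist(catalog$key_genes))
  known <- map_lgl(annotations$marker_label, function(l) {
    any(map_lgl(all_keys, marker_matches, labels = l))
  })
  n_unknown <- sum(!known)
  if (n_unknown > 0L) {
    inform(sprintf("%d annotation row(s) reference no catalog marker; ignored",
                   n_unknown))
  }
  by_genome <- split(annotations$marker_label, annotations$genome_id)
  rows <- imap(by_genome, function(labels, gid) {
    tibble(
      genome_id = gid,
      pathway = catalog$name,
      category = catalog$category,
      n_key = lengths(catalog$key_genes),
      n_present = map_int(seq_len(nrow(catalog)), function(i) {
        sum(map_lgl(catalog$key_genes[[i]], marker_matches, labels = labels))
      }),
      min_markers_present = catalog$min_markers_present
    )
  })
  bind_rows(rows) |>
    mutate(
      completeness = round(100 * .data$n_present / .data$n_key, 2),
      present = .data$n_present >= .data$min_markers_present
    ) |>
    select(-"min_markers_present")
}

#' Classify metabolic lifestyle flags per genome
#'
#' A pathway counts as present when at least its `min_markers_present` key
#' genes are detected. Lifestyle flags then follow from the pathway
#' categories: heterotroph (any degradation pathway), autotroph (any CO2
#' fixation pathway), mixotroph (both), aerobic (aerobic respiration),
#' anaerobic (any anaerobic respiration pathway), facultative (both), and
#' per-subtype chemolithotrophy flags.
#'
#' @inheritParams pathway_completeness
#' @return A tibble of class `trait_profiles`: one row per genome with
#'   logical flags `heterotroph`, `autotroph_any`, `mixotroph`, `aerobic`,
#'   `anaerobic`, `facultative`, `chemolithotroph`, a comma-separated
#'   `chemolithotroph_types` column, and the long completeness table as the
#'   `"completeness"` attribute.
#' @export
#' @examples
#' ann <- tibble::tibble(genome_id = "g1",
#'                       marker_label = c("coxA", "nirK", "GH5"))
#' classify_traits(ann, default_pathway_catalog())
classify_traits <- function(annotations, catalog = default_pathway_catalog()) {
  pc <- pathway_completeness(annotations, catalog)
  flags <- pc |>
    mutate(group = category_group(.data$category),
           subtype = category_subtype(.data$category)) |>
    group_by(.data$genome_id) |>
    summarise(
      heterotroph = any(.data$present & .data$group %in% DEGRADATION_GROUPS),
      autotroph_any = any(.data$present & .data$group == "co2_fixation"),
      aerobic = any(.data$present & .data$group == "aerobic_respiration"),
      anaerobic = any(.data$present & .data$group == "anaerobic"),
      chemolithotroph = any(.data$present & .data$group == "chemolithotrophy"),
      chemolithotroph_types = paste(
        sort(unique(.data$subtype[.data$present &
                                    .data$group == "chemolithotrophy"])),
        collapse = ","
      ),
      .groups = "drop"
    ) |>
    mutate(
      mixotroph = .data$heterotroph & .data$autotroph_any,
      facultative = .data$aerobic & .data$anaerobic
    ) |>
    select("genome_id", "heterotroph", "autotroph_any", "mixotroph",
           "aerobic", "anaerobic", "facultative", "chemolithotroph",
           "chemolithotroph_types")
  structure(flags, completeness = pc,
            class = c("trait_profiles", class(flags)))
}

#' Genome-by-pathway completeness matrix
#'
#' @param completeness Long completeness tibble from [pathway_completeness()]
#'   (or the `"completeness"` attribute of [classify_traits()] output).
#' @param taxonomy Optional data frame (`genome_id`, `lineage`) used to order
#'   rows by taxonomy before genome id.
#' @return A wide tibble, one row per genome, one column per pathway.
#' @export
trait_matrix <- function(completeness, taxonomy = NULL) {
  stopifnot(nrow(completeness) >= 1L)
  wide <- completeness |>
    select("genome_id", "pathway", "completeness") |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "completeness")
  if (!is.null(taxonomy)) {
    wide <- wide |>
      left_join(taxonomy, by = "genome_id") |>
      arrange(.data$lineage, .data$genome_id) |>
      select(-"lineage")
  } else {
    wide <- arrange(wide, .data$genome_id)
  }
  wide
}

#' Community-level lifestyle summary counts
#'
#' Counts and percentages of genomes per lifestyle flag (the "N MAGs (~x%)"
#' community summary numbers).
#'
#' @param profiles A `trait_profiles` tibble from [classify_traits()].
#' @return A tibble with `flag`, `n`, and `percent` columns.
#' @export
trait_summary <- function(profiles) {
  flags <- c("heterotroph", "autotroph_any", "mixotroph", "aerobic",
             "anaerobic", "facultative", "chemolithotroph")
  n_tot <- nrow(profiles)
  counts <- map_int(flags, function(f) sum(profiles[[f]]))
  tibble(flag = flags, n = counts, percent = round(100 * counts / n_tot, 2))
}
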