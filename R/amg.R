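CAZY_CLASSES <- c("GH", "PL", "CE", "GT", "AA", "CBM")

#' Read a nitrogen/sulfur ortholog catalog
#'
#' @param path YAML file mapping orthology ids (or gene symbols) to
#'   `"nitrogen"` or `"sulfur"`.
#' @return A named character vector.
#' @export
read_ns_ko_catalog <- function(path) {
  raw <- unlist(yaml::read_yaml(path))
  bad <- !raw %in% c("nitrogen", "sulfur")
  if (any(bad)) {
    abort(sprintf("catalog entry '%s' maps to '%s' (expected nitrogen/sulfur)",
                  names(raw)[bad][1], raw[bad][1]))
  }
  raw
}

#' The shipped minimal nitrogen/sulfur AMG catalog
#' @return Named character vector mapping ids to `"nitrogen"`/`"sulfur"`.
#' @export
default_ns_ko_catalog <- function() {
  read_ns_ko_catalog(system.file("extdata", "amg_ns_kos.yml",
                                 package = "hadalomics", mustWork = TRUE))
}

#' Flag auxiliary metabolic genes (AMGs) on viral contigs
#'
#' A viral ORF annotated with a CAZyme family is flagged as a carbohydrate
#' AMG; an ORF whose orthology id appears in the nitrogen/sulfur catalog is
#' flagged as a nitrogen or sulfur AMG. An ORF with both kinds of evidence yields two
#' records, and every record carries the triggering family or id as
#' verifiable evidence.
#'
#' @param annotations Data frame of viral ORF annotations with columns
#'   `orf_id` and any of `contig_id`, `cazy_family`, `ko_id`.
#' @param ns_ko_catalog Named character vector mapping orthology ids to
#'   `"nitrogen"`/`"sulfur"` (default: the shipped minimal catalog).
#' @return A tibble of AMG records: `contig_id`, `orf_id`, `amg_class`
#'   (carbohydrate/nitrogen/sulfur), `evidence`.
#' @export
flag_amgs <- function(annotations, ns_ko_catalog = default_ns_ko_catalog()) {
  stopifnot(is.data.frame(annotations), "orf_id" %in% names(annotations))
  ann <- as_tibble(annotations)
  if (!"contig_id" %in% names(ann)) ann$contig_id <- NA_character_
  if (!"cazy_family" %in% names(ann)) ann$cazy_family <- NA_character_
  if (!"ko_id" %in% names(ann)) ann$ko_id <- NA_character_
  carb <- ann |>
    filter(!is.na(.data$cazy_family) & .data$cazy_family != "") |>
    transmute(contig_id = .data$contig_id, orf_id = .data$orf_id,
              amg_class = "carbohydrate", evidence = .data$cazy_family)
  ns <- ann |>
    filter(!is.na(.data$ko_id) & .data$ko_id %in% names(ns_ko_catalog)) |>
    transmute(contig_id = .data$contig_id, orf_id = .data$orf_id,
              amg_class = unname(ns_ko_catalog[.data$ko_id]),
              evidence = .data$ko_id)
  bind_rows(carb, ns) |> arrange(.data$orf_id, .data$amg_class)
}

#' Count carbohydrate AMGs per CAZyme class
#'
#' Classifies carbohydrate AMG records by the family prefix before the first
#' digit (GH5 -> GH, CBM13 -> CBM) into the six CAZyme classes; unrecognised
#' prefixes are counted under `"other"` with a message.
#'
#' @param amg_records AMG tibble from [flag_amgs()] (only rows with
#'   `amg_class == "carbohydrate"` are used).
#' @return A tibble with `class` and `n` columns covering all six classes
#'   (zero-filled), plus an `other` row when needed.
#' @export
cazy_class_breakdown <- function(amg_records) {
  fams <- amg_records$evidence[amg_records$amg_class == "carbohydrate"]
  prefix <- stringr::str_extract(fams, "^[A-Za-z]+")
  cls <- ifelse(prefix %in% CAZY_CLASSES, prefix, "other")
  if (any(cls == "other")) {
    inform(sprintf("%d CAZy famil(ies) with unrecognised class prefix counted as 'other'",
                   sum(cls == "other")))
  }
  counts <- table(factor(cls, levels = c(CAZY_CLASSES, "other")))
  out <- tibble(class = names(counts), n = as.integer(counts))
  if (out$n[out$class == "other"] == 0L) out <- filter(out, .data$class != "other")
  out
}

#' Summarise COG functional categories over viral ORFs
#'
#' Counts ORFs per single-letter COG category; a multi-letter assignment
#' (e.g. "KL") counts once under each letter. ORFs with no category are
#' counted under `"unknown function"`.
#'
#' @param annotations Data frame with `orf_id` and `cog_category` columns.
#' @return A tibble with `category` and `n_orfs`, sorted by descending count.
#' @export
cog_category_summary <- function(annotations) {
  stopifnot(is.data.frame(annotations), "orf_id" %in% names(annotations))
  cat <- annotations$cog_category %||% rep(NA_character_, nrow(annotations))
  known <- !is.na(cat) & cat != "" & cat != "-"
  letters_tbl <- tibble(
    category = as.character(unlist(strsplit(cat[known], "", fixed = TRUE)))
  ) |>
    count(.data$category, name = "n_orfs")
  unk <- sum(!known)
  if (unk > 0L) {
    letters_tbl <- bind_rows(letters_tbl,
                             tibble(category = "unknown function", n_orfs = unk))
  }
  arrange(letters_tbl, desc(.data$n_orfs), .data$category)
}

#' Read a viral ORF annotation TSV (eggNOG-style export)
#' @param path TSV with header columns `orf_id` and optionally `contig_id`,
#'   `cog_category`, `cazy_family`, `ko_id`, `description`.
#' @return A tibble.
#' @export
read_viral_annotations_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}
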