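#' Filter MAGs by completeness and contamination
#'
#' Applies the standard draft-genome quality cutoff (50% completeness, 10%
#' contamination by default). Boundaries are inclusive (`completeness >=
#' min_completeness`, `contamination <= max_contamination`), matching the
#' tool-style cutoff phrasing; set `strict = TRUE` for strict inequalities.
#'
#' @param records Data frame with columns `genome_id`, `completeness`
#'   (percent, 0-100) and `contamination` (percent, >= 0); extra columns are
#'   carried through.
#' @param min_completeness Completeness cutoff in percent (default 50).
#' @param max_contamination Contamination cutoff in percent (default 10).
#' @param strict Use strict inequalities at both boundaries.
#' @return The input tibble with added columns `kept` (logical) and `reason`
#'   (`NA` when kept, otherwise the failed criteria, comma-separated).
#' @export
#' @examples
#' qc <- tibble::tibble(genome_id = c("a", "b"),
#'                      completeness = c(50, 49.9),
#'                      contamination = c(10, 0))
#' filter_mags(qc)
filter_mags <- function(records, min_completeness = 50, max_contamination = 10,
                        strict = FALSE) {
  stopifnot(is.data.frame(records))
  required <- c("genome_id", "completeness", "contamination")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    abort(sprintf("records is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  check_number(min_completeness, "min_completeness", min = 0, max = 100)
  check_number(max_contamination, "max_contamination", min = 0)
  bad <- which(is.na(records$completeness) | is.na(records$contamination) |
                 records$completeness < 0 | records$completeness > 100 |
                 records$contamination < 0)
  if (length(bad)) {
    abort(sprintf("malformed QC record in row %d (genome '%s')",
                  bad[1], records$genome_id[bad[1]]))
  }
  comp_ok <- if (strict) records$completeness > min_completeness else
    records$completeness >= min_completeness
  cont_ok <- if (strict) records$contamination < max_contamination else
    records$contamination <= max_contamination
  reason <- dplyr::case_when(
    !comp_ok & !cont_ok ~ "completeness,contamination",
    !comp_ok ~ "completeness",
    !cont_ok ~ "contamination",
    TRUE ~ NA_character_
  )
  records |>
    as_tibble() |>
    mutate(kept = comp_ok & cont_ok, reason = reason)
}

#' Count MAG quality tiers
#'
#' Tiers the retained MAGs by completeness with strict thresholds: the number
#' at or above medium quality (all records given, assumed pre-filtered), the
#' number above 70% completeness, and the number above 90%.
#'
#' @param records Data frame with a `completeness` column (typically the kept
#'   rows from [filter_mags()]).
#' @return A one-row tibble with `n_total`, `n_over70`, and `n_over90`.
#' @export
quality_tiers <- function(records) {
  stopifnot(is.data.frame(records))
  comp <- records$completeness %||% numeric(0)
  tibble(
    n_total = length(comp),
    n_over70 = sum(comp > 70),
    n_over90 = sum(comp > 90)
  )
}

#' Read a MAG QC report TSV
#' @param path TSV with header columns `genome_id`, `completeness`,
#'   `contamination`, and optionally `lineage`.
#' @return A tibble.
#' @export
read_qc_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    genome_id = readr::col_character(),
    completeness = readr::col_double(),
    contamination = readr::col_double(),
    .default = readr::col_character()
  ))
}
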