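TAXONOMIC_RANKS <- c("superkingdom", "phylum", "class", "order",
                     "family", "genus", "species")
RANK_PREFIXES <- c(superkingdom = "sk", phylum = "p", class = "c", order = "o",
                   family = "f", genus = "g", species = "s")
UNCLASSIFIED <- "unclassified"

#' Parse rank-prefixed lineage strings
#'
#' Lineages are semicolon-delimited, rank-prefixed fields such as
#' `"sk__Bacteria;p__Proteobacteria;c__Gammaproteobacteria"`. Truncated
#' lineages are allowed; fields with unrecognised prefixes are tolerated and
#' skipped. The sentinel `"unclassified"` (or `NA`) marks an unassigned read.
#'
#' @param lineage Character vector of lineage strings.
#' @return A tibble with one column per rank (NA where unresolved) plus an
#'   `assigned` logical column.
#' @export
parse_lineage <- function(lineage) {
  assigned <- !is.na(lineage) & lineage != "" & lineage != UNCLASSIFIED
  fields <- stringr::str_split(ifelse(assigned, lineage, ""), ";")
  out <- matrix(NA_character_, nrow = length(lineage),
                ncol = length(TAXONOMIC_RANKS),
                dimnames = list(NULL, TAXONOMIC_RANKS))
  prefix_of <- setNames(names(RANK_PREFIXES), RANK_PREFIXES)
  for (i in which(assigned)) {
    f <- fields[[i]]
    f <- f[f != ""]
    pre <- sub("__.*$", "", f)
    val <- sub("^[^_]*__", "", f)
    known <- pre %in% names(prefix_of)
    out[i, prefix_of[pre[known]]] <- val[known]
  }
  res <- as_tibble(out)
  res$assigned <- assigned
  res
}

format_lineage <- function(rank_values) {
  ranks <- intersect(TAXONOMIC_RANKS, names(rank_values))
  paste(sprintf("%s__%s", RANK_PREFIXES[ranks], unlist(rank_values[ranks])),
        collapse = ";")
}

#' Aggregate read assignments into a relative-abundance table
#'
#' Counts assigned reads per taxon at the requested rank and reports the
#' relative abundance as `100 * count / (total assigned reads)`. Unassigned
#' reads are excluded from the denominator; reads assigned but unresolved at
#' the requested rank stay in the denominator without gaining a row, so the
#' column of percentages may sum to less than 100.
#'
#' @param assignments Data frame with columns `read_id` and `lineage`
#'   (rank-prefixed, semicolon-delimited; `"unclassified"` marks unassigned
#'   reads).
#' @param rank One of superkingdom, phylum, class, order, family, genus,
#'   species.
#' @param within Optional taxon name: restricts both the rows and the
#'   denominator to reads whose lineage contains this taxon at any rank
#'   (e.g. percentages within total eukaryotes).
#' @param renormalize If `TRUE`, the denominator is instead the number of
#'   reads resolved at `rank` (per-rank renormalisation; off by default).
#' @return A tibble of class `abund_table` with columns `taxon`, `reads`, and
#'   `rel_abundance` (percent), sorted by descending abundance then taxon
#'   name; attributes `rank` and `denominator`.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   read_id = paste0("r", 1:10),
#'   lineage = c(rep("sk__Bacteria;p__A", 8), rep("sk__Bacteria;p__B", 2))
#' )
#' summarize_abundance(x, "phylum")
summarize_abundance <- function(assignments, rank, within = NULL,
                                renormalize = FALSE) {
  if (!rank %in% TAXONOMIC_RANKS) {
    abort(sprintf("unknown rank '%s' (expected one of: %s)", rank,
                  paste(TAXONOMIC_RANKS, collapse = ", ")))
  }
  stopifnot(is.data.frame(assignments), "lineage" %in% names(assignments))
  parsed <- parse_lineage(assignments$lineage)
  keep <- parsed$assigned
  if (!is.null(within)) {
    in_clade <- apply(as.matrix(parsed[TAXONOMIC_RANKS]) == within, 1L, any,
                      na.rm = TRUE)
    keep <- keep & in_clade
  }
  taxa <- parsed[[rank]][keep]
  denominator <- if (renormalize) sum(!is.na(taxa)) else sum(keep)
  rows <- tibble(taxon = taxa[!is.na(taxa)]) |>
    count(.data$taxon, name = "reads") |>
    mutate(rel_abundance = if (denominator > 0) 100 * .data$reads / denominator
           else numeric(length(.data$reads))) |>
    arrange(desc(.data$rel_abundance), .data$taxon)
  structure(rows, rank = rank, denominator = denominator,
            class = c("abund_table", class(rows)))
}

#' Rank and truncate an abundance table
#'
#' Orders rows by descending relative abundance (alphabetical on ties) and
#' keeps the `top_n` most abundant taxa, as in a "top 30 dominant groups"
#' report.
#'
#' @param table An abundance table from [summarize_abundance()] (or any
#'   data frame with `taxon` and `rel_abundance` columns).
#' @param top_n Number of rows to keep (>= 1).
#' @return The truncated, ordered tibble.
#' @export
rank_abundance_report <- function(table, top_n) {
  check_number(top_n, "top_n", min = 1, integer = TRUE)
  table |>
    arrange(desc(.data$rel_abundance), .data$taxon) |>
    slice_head(n = as.integer(top_n))
}

#' Read a read-assignment TSV (read_id, lineage)
#' @param path TSV path with header columns `read_id` and `lineage`.
#' @return A tibble.
#' @export
read_assignments_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}
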