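#' Filter marker-gene hits (e.g. TerL searches)
#'
#' Keeps hits passing all three thresholds (E-value <= `max_evalue`, percent
#' identity >= `min_identity`, coverage >= `min_coverage`; all inclusive) and
#' retains the best hit per query (lowest E-value, then highest bit score if
#' present, then highest identity).
#'
#' @param hits Data frame with columns `query_id`, `evalue`,
#'   `percent_identity`, and `query_coverage` (and/or `subject_coverage`);
#'   optional `bitscore` and `marker_name` are carried through.
#' @param max_evalue E-value threshold (default 1e-5).
#' @param min_identity Identity threshold in percent (default 50).
#' @param min_coverage Coverage threshold in percent (default 30).
#' @param coverage Which coverage column the threshold applies to: the
#'   fraction of the query ORF aligned (`"query"`, default) or of the subject
#'   (`"subject"`).
#' @return The kept hits, one row per query.
#' @export
filter_marker_hits <- function(hits, max_evalue = 1e-5, min_identity = 50,
                               min_coverage = 30,
                               coverage = c("query", "subject")) {
  coverage <- match.arg(coverage)
  cov_col <- paste0(coverage, "_coverage")
  required <- c("query_id", "evalue", "percent_identity", cov_col)
  missing <- setdiff(required, names(hits))
  if (length(missing)) {
    abort(sprintf("hits table missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(hits$evalue) | hits$evalue < 0 |
                 is.na(hits$percent_identity) | is.na(hits[[cov_col]]))
  if (length(bad)) abort(sprintf("malformed hit row %d", bad[1]))
  kept <- hits |>
    as_tibble() |>
    filter(.data$evalue <= max_evalue,
           .data$percent_identity >= min_identity,
           .data[[cov_col]] >= min_coverage)
  if (!"bitscore" %in% names(kept)) {
    kept <- arrange(kept, .data$evalue, desc(.data$percent_identity))
  } else {
    kept <- arrange(kept, .data$evalue, desc(.data$bitscore))
  }
  kept |>
    group_by(.data$query_id) |>
    slice_head(n = 1L) |>
    ungroup()
}

as_alignment <- function(x, arg = "matrix") {
  if (inherits(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a non-empty named character vector or XStringSet of aligned rows", arg))
  }
  if (length(unique(nchar(x))) != 1L) {
    abort(sprintf("`%s` rows differ in length; not an alignment", arg))
  }
  x
}

column_occupancy <- function(aln) {
  rows <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  colMeans(rows != "-" & rows != ".")
}

#' Trim alignment columns by gap occupancy
#'
#' Keeps columns whose non-gap occupancy is at least `gap_threshold`. If
#' fewer than `conserve` percent of the original columns would survive, the
#' `conserve` percent highest-occupancy columns are kept instead (ties broken
#' left-most), so badly gapped alignments never collapse entirely. Relative
#' column order is always preserved. This fixed behaviour mirrors a
#' gap-threshold-plus-conservation trimming contract; note the conservation
#' fallback is by construction not idempotent, while the plain occupancy
#' filter is.
#'
#' @param matrix A named character vector of equal-length aligned rows (or an
#'   `XStringSet`); gaps are `-` or `.`.
#' @param gap_threshold Minimum fraction of non-gap residues per kept column
#'   (default 0.95).
#' @param conserve Minimum percentage of original columns to conserve
#'   (default 50).
#' @return The trimmed alignment (same type/names), with the 1-based indices
#'   of the kept columns in attribute `kept_columns`.
#' @export
trim_alignment <- function(matrix, gap_threshold = 0.95, conserve = 50) {
  aln <- as_alignment(matrix)
  check_number(gap_threshold, "gap_threshold", min = 0, max = 1)
  check_number(conserve, "conserve", min = 0, max = 100)
  occ <- column_occupancy(aln)
  keep <- which(occ >= gap_threshold)
  n_min <- ceiling(conserve / 100 * length(occ))
  if (length(keep) < n_min) {
    # order() is stable, so equal-occupancy ties resolve to left-most columns
    keep <- sort(order(-occ)[seq_len(n_min)])
  }
  trimmed <- map_chr(strsplit(aln, "", fixed = TRUE), function(chars) {
    paste(chars[keep], collapse = "")
  })
  structure(setNames(trimmed, names(aln)), kept_columns = keep)
}

#' Concatenate per-marker alignments into a supermatrix
#'
#' Rows are aligned on a genome roster; genomes missing from a marker
#' alignment receive an all-gap block of that marker's width. The partition
#' table records each marker's column range in 0-based half-open
#' coordinates.
#'
#' @param matrices Named list of per-marker alignments (named character
#'   vectors keyed by genome id).
#' @param roster Character vector of genome ids defining the row set and
#'   order.
#' @return A list with `alignment` (named character vector over the roster)
#'   and `partitions` (tibble: `marker`, `start`, `end`).
#' @export
concatenate_alignments <- function(matrices, roster) {
  stopifnot(length(matrices) > 0L, length(roster) > 0L)
  if (is.null(names(matrices))) {
    names(matrices) <- sprintf("marker_%d", seq_along(matrices))
  }
  blocks <- matrix("", nrow = length(roster), ncol = length(matrices),
                   dimnames = list(roster, names(matrices)))
  widths <- integer(length(matrices))
  for (m in seq_along(matrices)) {
    aln <- as_alignment(matrices[[m]], names(matrices)[m])
    if (anyDuplicated(names(aln))) {
      abort(sprintf("duplicate genome id in marker '%s'", names(matrices)[m]))
    }
    extra <- setdiff(names(aln), roster)
    if (length(extra)) {
      abort(sprintf("marker '%s' has rows not in the roster: %s",
                    names(matrices)[m], paste(extra, collapse = ", ")))
    }
    widths[m] <- nchar(aln[[1]])
    gap <- strrep("-", widths[m])
    blocks[, m] <- ifelse(roster %in% names(aln), aln[roster], gap)
  }
  ends <- cumsum(widths)
  list(
    alignment = setNames(apply(blocks, 1L, paste, collapse = ""), roster),
    partitions = tibble(marker = names(matrices),
                        start = ends - widths, end = ends)
  )
}

#' Write a partition table in a RAxML-style plain-text dialect
#' @param partitions Tibble from [concatenate_alignments()] (0-based
#'   half-open ranges; written 1-based inclusive).
#' @param path Output path.
#' @param model Substitution model label written for every partition.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path, model = "AUTO") {
  lines <- sprintf("%s, %s = %d-%d", model, partitions$marker,
                   partitions$start + 1L, partitions$end)
  writeLines(lines, path)
  invisible(path)
}
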